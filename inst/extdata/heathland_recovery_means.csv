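year,compartment,recovery_mean,recovery_se
2007,current_year_shoots,1.69,0.41
2007,shoots_1_2yr,0.89,0.21
2007,litter_current,0.56,0.21
2007,moss,66.38,10.30
2007,O_horizon,17.80,2.98
2007,A_horizon,5.01,1.36
2007,B_horizon,0.43,0.24
2008,current_year_shoots,0.96,0.14
2008,shoots_1_2yr,0.44,0.08
2008,litter_current,0.62,0.14
2008,moss,42.08,5.92
2008,O_horizon,22.08,3.41
2008,A_horizon,7.05,1.46
2008,B_horizon,0.89,0.18
2009,current_year_shoots,0.74,0.08
2009,shoots_1_2yr,0.40,0.05
2009,litter_current,0.74,0.16
2009,moss,32.48,5.42
2009,O_horizon,22.55,3.10
2009,A_horizon,6.28,1.66
2009,B_horizon,0.96,0.29
2010,current_year_shoots,1.04,0.14
2010,shoots_1_2yr,0.48,0.07
2010,litter_current,0.88,0.17
2010,moss,24.44,2.73
2010,O_horizon,17.11,2.74
2010,A_horizon,8.08,2.68
2010,B_horizon,1.62,0.59
2011,current_year_shoots,0.94,0.10
2011,shoots_1_2yr,0.54,0.06
2011,litter_current,1.25,0.22
2011,moss,14.42,1.37
2011,O_horizon,24.27,2.59
2011,A_horizon,6.91,1.93
2011,B_horizon,0.94,0.19
2012,current_year_shoots,1.24,0.14
2012,shoots_1_2yr,0.62,0.09
2012,litter_current,0.94,0.16
2012,moss,10.76,1.35
2012,O_horizon,30.05,3.63
2012,A_horizon,8.43,1.94
2012,B_horizon,1.95,0.48
2013,current_year_shoots,0.91,0.10
2013,shoots_1_2yr,0.42,0.06
2013,litter_current,1.04,0.20
2013,moss,8.85,0.81
2013,O_horizon,24.52,3.14
2013,A_horizon,12.73,2.55
2013,B_horizon,1.63,0.37
2014,current_year_shoots,0.74,0.10
2014,shoots_1_2yr,0.33,0.05
2014,calluna_old,2.49,0.25
2014,calluna_roots,3.60,0.57
2014,litter_current,0.80,0.14
2014,moss,3.97,0.52
2014,O_horizon,36.11,6.02
2014,A_horizon,11.02,2.99
2014,B_horizon,1.39,0.58
2015,current_year_shoots,0.83,0.13
2015,shoots_1_2yr,0.41,0.07
2015,calluna_old,2.59,0.54
2015,calluna_roots,4.86,0.77
2015,litter_current,0.93,0.15
2015,moss,2.91,0.46
2015,O_horizon,39.89,4.89
2015,A_horizon,6.61,1.46
2015,B_horizon,2.08,0.55
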