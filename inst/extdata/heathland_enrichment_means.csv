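year,compartment,enrichment_mean,enrichment_se
2007,current_year_shoots,135.72,25.42
2007,shoots_1_2yr,117.00,23.10
2007,litter_current,61.27,25.18
2007,moss,746.60,106.95
2007,O_horizon,24.38,4.03
2007,A_horizon,2.81,0.34
2007,B_horizon,0.46,0.22
2008,current_year_shoots,72.03,10.72
2008,shoots_1_2yr,62.69,11.54
2008,litter_current,43.21,10.10
2008,moss,544.87,56.34
2008,O_horizon,33.55,5.98
2008,A_horizon,5.15,1.00
2008,B_horizon,1.74,0.64
2009,current_year_shoots,54.44,5.91
2009,shoots_1_2yr,49.63,6.92
2009,litter_current,48.18,11.67
2009,moss,442.26,64.83
2009,O_horizon,35.61,5.78
2009,A_horizon,3.99,0.50
2009,B_horizon,1.66,0.62
2010,current_year_shoots,62.54,8.17
2010,shoots_1_2yr,54.18,6.62
2010,litter_current,46.51,9.01
2010,moss,346.97,33.39
2010,O_horizon,22.59,3.58
2010,A_horizon,4.72,1.11
2010,B_horizon,2.19,0.63
2011,current_year_shoots,57.85,5.64
2011,shoots_1_2yr,55.23,5.48
2011,litter_current,44.63,7.62
2011,moss,185.41,19.09
2011,O_horizon,29.86,2.47
2011,A_horizon,4.55,1.01
2011,B_horizon,1.57,0.43
2012,current_year_shoots,73.48,9.11
2012,shoots_1_2yr,67.00,7.97
2012,litter_current,38.03,6.85
2012,moss,149.50,13.27
2012,O_horizon,42.43,7.18
2012,A_horizon,6.39,1.05
2012,B_horizon,2.64,0.68
2013,current_year_shoots,56.05,6.37
2013,shoots_1_2yr,48.56,5.36
2013,litter_current,36.45,6.44
2013,moss,117.21,10.07
2013,O_horizon,33.12,3.44
2013,A_horizon,6.98,0.44
2013,B_horizon,2.02,0.58
2014,current_year_shoots,42.47,5.88
2014,shoots_1_2yr,38.91,4.97
2014,calluna_old,45.77,5.16
2014,calluna_roots,66.47,10.69
2014,litter_current,31.09,5.76
2014,moss,57.55,7.35
2014,O_horizon,50.61,7.69
2014,A_horizon,7.24,1.10
2014,B_horizon,1.89,0.43
2015,current_year_shoots,40.26,6.61
2015,shoots_1_2yr,39.47,5.64
2015,calluna_old,41.81,6.21
2015,calluna_roots,67.49,5.73
2015,litter_current,27.18,
2015,moss,46.97,7.11
2015,O_horizon,63.35,6.40
2015,A_horizon,5.19,1.07
2015,B_horizon,3.34,0.78
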