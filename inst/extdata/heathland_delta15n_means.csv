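year,compartment,role,delta15n_mean,delta15n_se
2007,current_year_shoots,reference,-5.67,0.51
2007,current_year_shoots,labelled,129.30,25.56
2007,shoots_1_2yr,reference,-5.92,0.47
2007,shoots_1_2yr,labelled,110.42,23.28
2007,litter_current,reference,-6.24,0.16
2007,litter_current,labelled,54.66,25.18
2007,moss,reference,-6.19,0.22
2007,moss,labelled,735.74,106.17
2007,O_horizon,reference,-4.53,0.35
2007,O_horizon,labelled,19.74,4.22
2007,A_horizon,reference,5.33,0.40
2007,A_horizon,labelled,8.16,0.48
2007,B_horizon,reference,8.71,0.43
2007,B_horizon,labelled,8.74,0.69
2008,current_year_shoots,reference,-6.54,0.69
2008,current_year_shoots,labelled,65.00,10.43
2008,shoots_1_2yr,reference,-7.67,0.63
2008,shoots_1_2yr,labelled,54.54,11.40
2008,litter_current,reference,-5.40,0.80
2008,litter_current,labelled,37.55,9.70
2008,moss,reference,-5.93,0.38
2008,moss,labelled,535.65,55.71
2008,O_horizon,reference,-4.79,0.44
2008,O_horizon,labelled,28.60,6.03
2008,A_horizon,reference,4.26,1.11
2008,A_horizon,labelled,9.43,0.81
2008,B_horizon,reference,7.16,1.32
2008,B_horizon,labelled,8.90,0.76
2009,current_year_shoots,reference,-6.90,0.52
2009,current_year_shoots,labelled,47.15,5.53
2009,shoots_1_2yr,reference,-7.68,0.57
2009,shoots_1_2yr,labelled,41.55,6.46
2009,litter_current,reference,-7.66,0.61
2009,litter_current,labelled,40.14,11.39
2009,moss,reference,-6.60,0.31
2009,moss,labelled,432.63,63.96
2009,O_horizon,reference,-4.85,0.48
2009,O_horizon,labelled,30.62,4.92
2009,A_horizon,reference,4.49,1.23
2009,A_horizon,labelled,8.50,0.95
2009,B_horizon,reference,6.73,1.36
2009,B_horizon,labelled,8.30,1.00
2010,current_year_shoots,reference,-6.85,0.56
2010,current_year_shoots,labelled,55.23,7.56
2010,shoots_1_2yr,reference,-7.96,0.51
2010,shoots_1_2yr,labelled,45.77,6.13
2010,litter_current,reference,-8.02,0.48
2010,litter_current,labelled,38.11,8.71
2010,moss,reference,-6.11,0.34
2010,moss,labelled,338.70,32.94
2010,O_horizon,reference,-3.99,0.59
2010,O_horizon,labelled,18.57,2.91
2010,A_horizon,reference,4.76,1.02
2010,A_horizon,labelled,9.26,1.39
2010,B_horizon,reference,7.68,1.11
2010,B_horizon,labelled,9.82,1.03
2011,current_year_shoots,reference,-6.02,0.46
2011,current_year_shoots,labelled,51.47,5.23
2011,shoots_1_2yr,reference,-7.50,0.42
2011,shoots_1_2yr,labelled,47.30,5.14
2011,litter_current,reference,-7.60,0.47
2011,litter_current,labelled,36.68,7.32
2011,moss,reference,-6.32,0.49
2011,moss,labelled,177.92,18.88
2011,O_horizon,reference,-4.50,0.42
2011,O_horizon,labelled,25.12,2.17
2011,A_horizon,reference,4.69,1.12
2011,A_horizon,labelled,9.26,0.64
2011,B_horizon,reference,7.21,1.25
2011,B_horizon,labelled,8.78,1.01
2012,current_year_shoots,reference,-6.30,0.51
2012,current_year_shoots,labelled,66.69,8.60
2012,shoots_1_2yr,reference,-7.07,0.46
2012,shoots_1_2yr,labelled,59.44,7.55
2012,litter_current,reference,-6.64,0.64
2012,litter_current,labelled,31.11,6.29
2012,moss,reference,-6.79,0.18
2012,moss,labelled,141.69,13.06
2012,O_horizon,reference,-3.52,0.53
2012,O_horizon,labelled,38.77,7.28
2012,A_horizon,reference,4.14,1.18
2012,A_horizon,labelled,10.55,0.25
2012,B_horizon,reference,6.62,1.28
2012,B_horizon,labelled,10.24,0.46
2013,current_year_shoots,reference,-6.55,0.50
2013,current_year_shoots,labelled,49.12,6.05
2013,shoots_1_2yr,reference,-7.58,0.44
2013,shoots_1_2yr,labelled,40.61,5.05
2013,litter_current,reference,-6.62,0.52
2013,litter_current,labelled,29.57,5.95
2013,moss,reference,-6.75,0.35
2013,moss,labelled,109.67,9.92
2013,O_horizon,reference,-3.58,0.63
2013,O_horizon,labelled,29.41,2.84
2013,A_horizon,reference,3.91,1.14
2013,A_horizon,labelled,13.97,2.08
2013,B_horizon,reference,7.14,1.10
2013,B_horizon,labelled,10.22,0.30
2014,current_year_shoots,reference,-6.06,0.56
2014,current_year_shoots,labelled,36.13,5.51
2014,shoots_1_2yr,reference,-6.72,0.50
2014,shoots_1_2yr,labelled,31.92,4.72
2014,calluna_old,reference,-7.00,0.46
2014,calluna_old,labelled,38.44,4.85
2014,calluna_roots,reference,-5.34,0.61
2014,calluna_roots,labelled,60.77,10.48
2014,litter_current,reference,-6.78,0.43
2014,litter_current,labelled,24.09,5.36
2014,moss,reference,-6.74,0.21
2014,moss,labelled,50.42,7.22
2014,O_horizon,reference,-3.82,0.53
2014,O_horizon,labelled,46.60,7.72
2014,A_horizon,reference,3.53,1.01
2014,A_horizon,labelled,15.63,3.97
2014,B_horizon,reference,6.52,1.26
2014,B_horizon,labelled,10.35,0.90
2015,current_year_shoots,reference,-6.30,0.53
2015,current_year_shoots,labelled,33.70,6.35
2015,shoots_1_2yr,reference,-7.28,0.41
2015,shoots_1_2yr,labelled,31.90,5.41
2015,calluna_old,reference,-7.40,0.47
2015,calluna_old,labelled,34.10,5.90
2015,calluna_roots,reference,-5.39,0.52
2015,calluna_roots,labelled,61.74,5.87
2015,litter_current,reference,-8.60,0.39
2015,litter_current,labelled,18.33,4.69
2015,moss,reference,-6.63,0.24
2015,moss,labelled,40.02,6.87
2015,O_horizon,reference,-3.78,0.55
2015,O_horizon,labelled,59.32,6.17
2015,A_horizon,reference,5.17,1.43
2015,A_horizon,labelled,10.38,0.54
2015,B_horizon,reference,6.13,1.08
2015,B_horizon,labelled,9.48,0.47
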