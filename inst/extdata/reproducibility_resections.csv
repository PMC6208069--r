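case,operator,run,variable,value
case1,A,1,lat_condyle,6.5
case1,A,2,lat_condyle,6.2
case1,B,1,lat_condyle,6.1
case1,B,2,lat_condyle,6.8
case1,C,1,lat_condyle,6.2
case1,C,2,lat_condyle,6.4
case1,A,1,med_condyle,6
case1,A,2,med_condyle,5.7
case1,B,1,med_condyle,5.4
case1,B,2,med_condyle,6.1
case1,C,1,med_condyle,5.7
case1,C,2,med_condyle,6
case1,A,1,post_lat_condyle,10
case1,A,2,post_lat_condyle,10
case1,B,1,post_lat_condyle,10.2
case1,B,2,post_lat_condyle,10.2
case1,C,1,post_lat_condyle,9.5
case1,C,2,post_lat_condyle,9.9
case1,A,1,post_med_condyle,10.3
case1,A,2,post_med_condyle,10.7
case1,B,1,post_med_condyle,11.1
case1,B,2,post_med_condyle,10.6
case1,C,1,post_med_condyle,10.7
case1,C,2,post_med_condyle,10.3
case1,A,1,lat_plateau,11.2
case1,A,2,lat_plateau,10.3
case1,B,1,lat_plateau,10.5
case1,B,2,lat_plateau,11.1
case1,C,1,lat_plateau,10.7
case1,C,2,lat_plateau,11.1
case1,A,1,med_plateau,10
case1,A,2,med_plateau,9
case1,B,1,med_plateau,9.3
case1,B,2,med_plateau,9.8
case1,C,1,med_plateau,9.6
case1,C,2,med_plateau,9.9
case2,A,1,lat_condyle,6
case2,A,2,lat_condyle,6.2
case2,B,1,lat_condyle,6.1
case2,B,2,lat_condyle,6.1
case2,C,1,lat_condyle,5.9
case2,C,2,lat_condyle,6
case2,A,1,med_condyle,7.4
case2,A,2,med_condyle,7.8
case2,B,1,med_condyle,7.7
case2,B,2,med_condyle,7.6
case2,C,1,med_condyle,7.5
case2,C,2,med_condyle,7.4
case2,A,1,post_lat_condyle,10.9
case2,A,2,post_lat_condyle,10.8
case2,B,1,post_lat_condyle,10.6
case2,B,2,post_lat_condyle,10.8
case2,C,1,post_lat_condyle,11
case2,C,2,post_lat_condyle,10.9
case2,A,1,post_med_condyle,10.3
case2,A,2,post_med_condyle,10.3
case2,B,1,post_med_condyle,10.2
case2,B,2,post_med_condyle,9.9
case2,C,1,post_med_condyle,10.6
case2,C,2,post_med_condyle,10.4
case2,A,1,lat_plateau,11
case2,A,2,lat_plateau,11.1
case2,B,1,lat_plateau,10.9
case2,B,2,lat_plateau,11.2
case2,C,1,lat_plateau,11
case2,C,2,lat_plateau,10.9
case2,A,1,med_plateau,6.7
case2,A,2,med_plateau,7
case2,B,1,med_plateau,6.7
case2,B,2,med_plateau,6.9
case2,C,1,med_plateau,6.3
case2,C,2,med_plateau,6.6
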