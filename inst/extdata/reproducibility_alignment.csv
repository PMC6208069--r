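case,operator,run,variable,value
case1,A,1,femoral_FE,1.1
case1,A,2,femoral_FE,1
case1,B,1,femoral_FE,1
case1,B,2,femoral_FE,0.8
case1,C,1,femoral_FE,1.1
case1,C,2,femoral_FE,1.1
case1,A,1,femoral_VV,-0.6
case1,A,2,femoral_VV,-0.5
case1,B,1,femoral_VV,-0.8
case1,B,2,femoral_VV,-0.7
case1,C,1,femoral_VV,-0.6
case1,C,2,femoral_VV,-0.4
case1,A,1,femoral_IE,-0.8
case1,A,2,femoral_IE,-1.2
case1,B,1,femoral_IE,-1.5
case1,B,2,femoral_IE,-0.8
case1,C,1,femoral_IE,-1.8
case1,C,2,femoral_IE,-1
case1,A,1,tibial_FE,7.1
case1,A,2,tibial_FE,7
case1,B,1,tibial_FE,7
case1,B,2,tibial_FE,7.4
case1,C,1,tibial_FE,6.9
case1,C,2,tibial_FE,7.2
case1,A,1,tibial_VV,0.6
case1,A,2,tibial_VV,0.4
case1,B,1,tibial_VV,0.5
case1,B,2,tibial_VV,0.4
case1,C,1,tibial_VV,0.8
case1,C,2,tibial_VV,0.6
case1,A,1,tibial_IE,5.9
case1,A,2,tibial_IE,6.2
case1,B,1,tibial_IE,4.5
case1,B,2,tibial_IE,4.7
case1,C,1,tibial_IE,5.5
case1,C,2,tibial_IE,5.9
case2,A,1,femoral_FE,1.9
case2,A,2,femoral_FE,2.3
case2,B,1,femoral_FE,2.3
case2,B,2,femoral_FE,2.1
case2,C,1,femoral_FE,2
case2,C,2,femoral_FE,1.8
case2,A,1,femoral_VV,-0.9
case2,A,2,femoral_VV,-0.8
case2,B,1,femoral_VV,-0.7
case2,B,2,femoral_VV,-0.8
case2,C,1,femoral_VV,-0.7
case2,C,2,femoral_VV,-0.8
case2,A,1,femoral_IE,0.1
case2,A,2,femoral_IE,-0.1
case2,B,1,femoral_IE,-0.2
case2,B,2,femoral_IE,0.4
case2,C,1,femoral_IE,-0.2
case2,C,2,femoral_IE,0
case2,A,1,tibial_FE,8.2
case2,A,2,tibial_FE,7.7
case2,B,1,tibial_FE,7.9
case2,B,2,tibial_FE,8.4
case2,C,1,tibial_FE,7.9
case2,C,2,tibial_FE,8.4
case2,A,1,tibial_VV,1.5
case2,A,2,tibial_VV,1.8
case2,B,1,tibial_VV,1.7
case2,B,2,tibial_VV,1.4
case2,C,1,tibial_VV,1
case2,C,2,tibial_VV,1.5
case2,A,1,tibial_IE,3
case2,A,2,tibial_IE,2.7
case2,B,1,tibial_IE,1.7
case2,B,2,tibial_IE,2.8
case2,C,1,tibial_IE,2.3
case2,C,2,tibial_IE,2.8
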