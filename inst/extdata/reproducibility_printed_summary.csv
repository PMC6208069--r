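table,case,variable,printed_max_abs_dev,printed_ci95,computed_max_abs_dev,computed_ci95,max_regenerable,ci_regenerable
alignment,case1,femoral_FE,0.2,0.1,0.2,0.1,TRUE,TRUE
alignment,case1,femoral_VV,0.2,0.1,0.2,0.1,TRUE,TRUE
alignment,case1,femoral_IE,0.5,0.3,0.6,0.3,FALSE,TRUE
alignment,case1,tibial_FE,0.3,0.1,0.3,0.1,TRUE,TRUE
alignment,case1,tibial_VV,0.2,0.1,0.3,0.1,FALSE,TRUE
alignment,case1,tibial_IE,0.9,0.6,1,0.6,FALSE,TRUE
alignment,case2,femoral_FE,0.3,0.2,0.3,0.2,TRUE,TRUE
alignment,case2,femoral_VV,0.1,0.1,0.1,0.1,TRUE,TRUE
alignment,case2,femoral_IE,0.3,0.2,0.4,0.2,FALSE,TRUE
alignment,case2,tibial_FE,0.3,0.2,0.4,0.2,FALSE,TRUE
alignment,case2,tibial_VV,0.4,0.2,0.5,0.2,FALSE,TRUE
alignment,case2,tibial_IE,0.7,0.4,0.8,0.4,FALSE,TRUE
resections,case1,lat_condyle,0.3,0.2,0.4,0.2,FALSE,TRUE
resections,case1,med_condyle,0.4,0.2,0.4,0.2,TRUE,TRUE
resections,case1,post_lat_condyle,0.4,0.2,0.5,0.2,FALSE,TRUE
resections,case1,post_med_condyle,0.4,0.2,0.5,0.2,FALSE,TRUE
resections,case1,lat_plateau,0.4,0.2,0.5,0.3,FALSE,FALSE
resections,case1,med_plateau,0.5,0.3,0.6,0.3,FALSE,TRUE
resections,case2,lat_condyle,0.2,0.1,0.2,0.1,TRUE,TRUE
resections,case2,med_condyle,0.2,0.1,0.2,0.1,TRUE,TRUE
resections,case2,post_lat_condyle,0.2,0.1,0.2,0.1,TRUE,TRUE
resections,case2,post_med_condyle,0.2,0.1,0.4,0.2,FALSE,FALSE
resections,case2,lat_plateau,0.2,0.1,0.2,0.1,TRUE,TRUE
resections,case2,med_plateau,0.3,0.2,0.4,0.2,FALSE,TRUE
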