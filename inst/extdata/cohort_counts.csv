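characteristic,group,numerator,denominator,printed_pct
sex_male,bvAD,17,29,59
sex_male,CN,22,34,65
apoe_e4_positive,bvAD,11,18,61
apoe_e4_positive,bvFTD,3,27,11
apoe_e4_positive,CN,6,34,18
field_1p5T,bvAD,17,29,59
field_1p5T,tAD,22,28,79
field_1p5T,bvFTD,14,28,50
field_1p5T,CN,22,34,65
field_3T,bvAD,12,29,41
field_3T,tAD,6,28,21
field_3T,bvFTD,14,28,50
field_3T,CN,12,34,35
behavioral_dysexecutive_overlap,all,9,75,12
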