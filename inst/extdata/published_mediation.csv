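model,effect,estimate,se,z,std_estimate,pct_of_total
model1,direct,5.111,1.294,3.950,0.127,41
model1,indirect:MMDs,4.381,0.631,6.943,0.109,35
model1,indirect:Nausea,1.108,0.337,3.283,0.027,9
model1,indirect:Severe_migraine,1.259,0.353,3.561,0.031,10
model1,indirect:Pulsating_throbbing,0.286,0.165,1.732,0.007,2
model1,indirect:Light_sensitivity,0.437,0.226,1.930,0.011,3
model1,indirect_total,7.470,0.858,8.710,0.185,NA
model1,total,12.581,1.438,8.749,0.312,NA
model2,direct,1.667,1.224,1.362,0.041,NA
model2,indirect:PI_MBS,8.686,0.915,9.488,0.216,69
model2,indirect:MMDs,2.175,0.470,4.629,0.054,17
model2,indirect_total,10.860,1.016,10.689,0.270,NA
model2,total,12.527,1.430,8.757,0.312,NA
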