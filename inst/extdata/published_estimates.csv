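model,lhs,op,rhs,estimate,se,z,p_value,std_estimate
model1,HRQoL,=~,MSQ_EF,1.000,0.000,NA,NA,0.784
model1,HRQoL,=~,MSQ_RP,1.012,0.036,27.881,<0.001,0.878
model1,HRQoL,=~,MSQ_RR,1.057,0.037,28.865,<0.001,0.921
model1,HRQoL,~,MMDs,-1.446,0.135,-10.716,<0.001,-0.361
model1,HRQoL,~,Nausea,-9.728,2.410,-4.036,<0.001,-0.143
model1,HRQoL,~,Severe_migraine,-0.113,0.026,-4.389,<0.001,-0.151
model1,HRQoL,~,Pulsating_throbbing,-5.869,2.803,-2.094,0.036,-0.067
model1,HRQoL,~,Light_sensitivity,-5.592,2.600,-2.151,0.031,-0.072
model1,HRQoL,~,Treatment,5.111,1.294,3.950,<0.001,0.127
model1,MMDs,~,Treatment,-3.030,0.332,-9.116,<0.001,-0.301
model1,Nausea,~,Treatment,-0.114,0.020,-5.643,<0.001,-0.192
model1,Severe_migraine,~,Treatment,-11.117,1.826,-6.089,<0.001,-0.206
model1,Pulsating_throbbing,~,Treatment,-0.049,0.016,-3.081,0.002,-0.106
model1,Light_sensitivity,~,Treatment,-0.078,0.018,-4.378,<0.001,-0.150
model2,HRQoL,=~,MSQ_EF,1.000,0.000,NA,NA,0.781
model2,HRQoL,=~,MSQ_RP,1.005,0.036,27.579,<0.001,0.869
model2,HRQoL,=~,MSQ_RR,1.072,0.037,29.193,<0.001,0.931
model2,HRQoL,~,PI_MBS,-9.322,0.650,-14.350,<0.001,-0.538
model2,HRQoL,~,MMDs,-0.718,0.134,-5.373,<0.001,-0.180
model2,HRQoL,~,Treatment,1.667,1.224,1.362,0.173,0.041
model2,PI_MBS,~,Treatment,-0.932,0.074,-12.646,<0.001,-0.401
model2,MMDs,~,Treatment,-3.030,0.332,-9.116,<0.001,-0.301
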