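model,bias,evidence,k,G2,AIC,W
BurstIE,Burst,Increasing,14,43,71,0.47
SustIE,Sustained,Increasing,14,60,88,0.0001
BurstSE,Burst,Stationary,13,69,95,0
SustSE,Sustained,Stationary,13,89,115,0
UnbiasedUrgency,Burst,Increasing,17,54,88,0.0001
UrgencyOnly,None,Increasing,11,362,384,0
DDM,None,Stationary,14,606,634,0
ConstraintsSwap1,Burst,Increasing,14,272,300,0
ConstraintsSwap2,Burst,Increasing,14,122,150,0
BurstIE+driftboost,Burst,Increasing,15,42,72,0.22
BurstIE+sZ,Burst,Increasing,15,42,72,0.31
SustIE+sZ,Sustained,Increasing,15,59,89,0
BurstSE+sZ,Burst,Stationary,14,69,97,0
SustSE+sZ,Sustained,Stationary,14,92,120,0
BurstSE+sTev,Burst,Stationary,14,64,92,0
SustSE+sTev,Sustained,Stationary,14,92,120,0
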