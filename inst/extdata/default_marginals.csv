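parameter,group,mean,sd,lower,upper
VD,metastatic,0.482,0.073,0,1
Dmax,metastatic,6.272,1.626,0,Inf
Dmean,metastatic,2.229,0.589,0,Inf
Dstd,metastatic,2.063,0.537,0,Inf
FWVD,metastatic,1.784,0.592,0,Inf
FD,metastatic,1.678,0.070,0,2
Vmean,metastatic,25.758,3.397,0,Inf
Vmax,metastatic,48.949,7.694,0,Inf
Vmin,metastatic,2.572,2.200,0,Inf
VelVar,metastatic,149.761,33.210,0,Inf
VelEntropy,metastatic,0.922,0.092,0,1
DirVar,metastatic,4391.301,1094.492,0,32400
DirEntropy,metastatic,0.730,0.077,0,1
PI,metastatic,12.617,2.563,0,Inf
VD,reactive,0.405,0.168,0,1
Dmax,reactive,6.054,1.480,0,Inf
Dmean,reactive,2.109,0.614,0,Inf
Dstd,reactive,2.013,0.478,0,Inf
FWVD,reactive,1.495,0.813,0,Inf
FD,reactive,1.626,0.098,0,2
Vmean,reactive,25.486,4.393,0,Inf
Vmax,reactive,49.472,5.778,0,Inf
Vmin,reactive,2.645,2.800,0,Inf
VelVar,reactive,147.115,53.164,0,Inf
VelEntropy,reactive,0.796,0.199,0,1
DirVar,reactive,4383.695,1355.021,0,32400
DirEntropy,reactive,0.639,0.122,0,1
PI,reactive,10.369,5.006,0,Inf
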