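"","VD","Dmax","Dmean","Dstd","FWVD","FD","Vmean","Vmax","Vmin","VelVar","VelEntropy","DirVar","DirEntropy","PI"
"VD",1,0.1,0.1,0.1,0.6,0.5,0,0,0,0,0.05,0,0.2,0.3
"Dmax",0.1,1,0.6,0.65,0,0.15,0,0,0,0,0,0,0,0
"Dmean",0.1,0.6,1,0.45,0,0.1,0,0,0,0,0,0,0,0
"Dstd",0.1,0.65,0.45,1,0,0,0,0,0,0,0,0,0,0
"FWVD",0.6,0,0,0,1,0.35,0.15,0,0,0,0,0,0,0.45
"FD",0.5,0.15,0.1,0,0.35,1,0,0,0,0,0,0,0.25,0.3
"Vmean",0,0,0,0,0.15,0,1,0.55,0.35,0.25,0,0,0,0.45
"Vmax",0,0,0,0,0,0,0.55,1,0,0.55,0,0,0,0.2
"Vmin",0,0,0,0,0,0,0.35,0,1,-0.2,-0.1,0,0,0.15
"VelVar",0,0,0,0,0,0,0.25,0.55,-0.2,1,0.6,0,0,0
"VelEntropy",0.05,0,0,0,0,0,0,0,-0.1,0.6,1,0,0.35,0.05
"DirVar",0,0,0,0,0,0,0,0,0,0,0,1,0.5,0
"DirEntropy",0.2,0,0,0,0,0.25,0,0,0,0,0.35,0.5,1,0
"PI",0.3,0,0,0,0.45,0.3,0.45,0.2,0.15,0,0.05,0,0,1
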