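drug,channel,ic50_nM,hill,cmax_nM
quinidine,INa,14600,1,3237
quinidine,INaL,9417,1,3237
quinidine,ICaL,51500,1,3237
quinidine,IKs,4899,1,3237
quinidine,IK1,39700,1,3237
quinidine,Ito,3487,1,3237
bepridil,INa,2929,1,33
bepridil,INaL,1813,1,33
bepridil,ICaL,2808,1,33
bepridil,IKs,28628,1,33
bepridil,Ito,8594,1,33
dofetilide,Ito,18800,1,2
sotalol,ICaL,7061000,1,14690
sotalol,INaL,1140000,1,14690
cisapride,ICaL,11970,1,2.6
terfenadine,INa,983,1,4
terfenadine,INaL,20560,1,4
terfenadine,ICaL,700,1,4
ondansetron,INa,57800,1,139
ondansetron,INaL,19180,1,139
ondansetron,ICaL,22550,1,139
ondansetron,Ito,1023000,1,139
chlorpromazine,INa,4560,1,38
chlorpromazine,INaL,4559,1,38
chlorpromazine,ICaL,3400,1,38
chlorpromazine,IK1,9270,1,38
verapamil,INaL,7028,1,81
verapamil,ICaL,202,1,81
ranolazine,INa,68774,1,1948
ranolazine,INaL,7884,1,1948
mexiletine,INa,43000,1,4129
mexiletine,INaL,8519,1,4129
mexiletine,ICaL,40000,1,4129
diltiazem,INa,22600,1,122
diltiazem,INaL,21868,1,122
diltiazem,ICaL,112,1,122
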