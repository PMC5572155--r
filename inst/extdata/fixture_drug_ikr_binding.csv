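drug,Kmax,Ku,n,halfmax,Vhalf,ikr_ic50_nM,cmax_nM
quinidine,1e6,5e-3,0.8,2.496e8,-84,992,3237
bepridil,1e6,3e-5,0.9,9.03e7,-5,149,33
dofetilide,1e6,1e-5,0.9,4.157e6,-1,4.87,2
sotalol,1e6,8e-3,0.8,1.0884e10,-55,111000,14690
cisapride,1e6,1e-3,0.89,7.831e6,-66,10.1,2.6
terfenadine,1e6,5e-5,0.6,6.562e6,-41,23,4
ondansetron,1e6,2e-3,0.9,6.435e8,-82,1320,139
chlorpromazine,1e6,2e-5,0.8,2.368e8,10,929,38
verapamil,1e6,8e-3,1,2.88e8,-86,288,81
ranolazine,1e6,1e-2,0.9,3.356e9,-94,8270,1948
mexiletine,1e6,1e-2,1,1.01e11,-87,101000,4129
diltiazem,1e6,5e-3,0.9,5.113e9,-91,13200,122
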