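state,value
V,-88.0151717781942
nai,6.43816415878393
nass,6.43822373879062
ki,145.524935304596
kss,145.524918566762
cai,7.46679624935321e-05
cass,7.31744181496514e-05
cansr,1.38230882494055
cajsr,1.3827731300748
m,0.00733432778604082
hf,0.698566661920263
hs,0.698566568107384
j,0.698565933632834
hsp,0.455554791260941
jp,0.698565430828476
mL,0.000187787859366267
hL,0.513408967286997
hLp,0.307374428193917
a,0.00100019782576938
iF,0.999555267148976
iS,0.869031890583935
ap,0.000509627564580695
iFp,0.999555267192688
iSp,0.902835193113709
d,2.33342880318525e-09
ff,0.999999990909252
fs,0.969044941484043
fcaf,0.999999990909252
fcas,0.999999975288869
jca,0.999999990839906
nca,0.00154959798818475
ffp,0.999999990909233
fcafp,0.999999990909235
xs1,0.139370815267724
xs2,0.000192501894284733
xk1,0.996755880261334
Jrelnp,1.48192190474078e-07
Jrelp,1.85239043692911e-07
CaMKt,0.00329420961760923
kr_c,0.583472611962036
kr_o,0.00250079742066285
kr_i,0.00176696862408781
kr_ci,0.412259621604301
kr_ob,0
kr_ib,0
kr_cb,0
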