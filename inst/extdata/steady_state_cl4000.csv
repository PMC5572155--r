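state,value
V,-88.1099072416676
nai,5.5955238264818
nass,5.59556822257699
ki,146.401537869121
kss,146.401529067396
cai,6.80769013423434e-05
cass,6.68456555721786e-05
cansr,1.21740423010963
cajsr,1.2184374813863
m,0.00726478328023907
hf,0.701834276388242
hs,0.701834228442083
j,0.701834000877084
hsp,0.459418376468342
jp,0.701833879823992
mL,0.000184439114814695
hL,0.516682607756827
hLp,0.318064520939622
a,0.000993830869056796
iF,0.999562580591067
iS,0.98728311274044
ap,0.000506381846787415
iFp,0.999562580611043
iSp,0.993122159538385
d,2.28174990453712e-09
ff,0.999999991139309
fs,0.995831262949718
fcaf,0.999999991139309
fcas,0.999999991139254
jca,0.999999991139268
nca,0.00109290542494518
ffp,0.999999991139302
fcafp,0.999999991139303
xs1,0.0453717007909591
xs2,0.000190471108719809
xk1,0.996730847866565
Jrelnp,6.80609442581622e-08
Jrelp,8.50779739788032e-08
CaMKt,0.000880854364495148
kr_c,0.586322450976554
kr_o,8.71060273829755e-06
kr_i,6.14551154467753e-06
kr_ci,0.413662693574323
kr_ob,0
kr_ib,0
kr_cb,0
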