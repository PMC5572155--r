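state,value
V,-87.917227894914
nai,7.5082037417228
nass,7.50829399715624
ki,144.401407640403
kss,144.401377292384
cai,8.70079093656468e-05
cass,8.58634538046736e-05
cansr,1.65328900465547
cajsr,1.6054662743952
m,0.00740692324831459
hf,0.695166933297696
hs,0.695156014374185
j,0.695094949713944
hsp,0.451525923795961
jp,0.695054022204517
mL,0.000191313985253541
hL,0.498594599910364
hLp,0.26732141249719
a,0.00100682631546902
iF,0.999547541078115
iS,0.583577213124398
ap,0.000513006627011839
iFp,0.999547545891131
iSp,0.635244173751826
d,2.38810994584201e-09
ff,0.999999990663979
fs,0.901489984052002
fcaf,0.99999999066402
fcas,0.999772456052976
jca,0.999970991053337
nca,0.00286682676080571
ffp,0.999999990662092
fcafp,0.999999990662205
xs1,0.287371604061938
xs2,0.000194662710773352
xk1,0.996781795169187
Jrelnp,2.73114805229921e-07
Jrelp,3.41228700343842e-07
CaMKt,0.0132598787824832
kr_c,0.528391863358561
kr_o,0.0572109956925125
kr_i,0.040484899756595
kr_ci,0.373912241193025
kr_ob,0
kr_ib,0
kr_cb,0
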