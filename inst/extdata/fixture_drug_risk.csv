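drug,risk_category
quinidine,3
bepridil,3
dofetilide,3
sotalol,3
cisapride,2
terfenadine,2
ondansetron,2
chlorpromazine,2
verapamil,1
ranolazine,1
mexiletine,1
diltiazem,1
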