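metabolite,kJ_per_mol
lcts(e),-1500
gal(e),-800
glc(e),-800
fuc(e),-750
lac(e),-520
ac(e),-370
12ppd(e),-320
but(e),-360
ppa(e),-330
succ(e),-600
co2(e),-394
h2(e),0
h2o(e),-157
o2(e),0
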