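metabolite,C,H,O
lcts,12,22,11
2fl,18,32,15
fuc,6,12,5
gal,6,12,6
glc,6,12,6
gos_dp3,18,32,16
gos_dp4,24,42,21
gos_dp5,30,52,26
lac,3,6,3
ac,2,4,2
12ppd,3,8,2
but,4,8,2
ppa,3,6,2
succ,4,6,4
co2,1,0,2
h2,0,2,0
h2o,0,2,1
o2,0,0,2
atp,0,0,0
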