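kBT: 369.745155
Jcc: 5.9784248
Jcm: 10.015139
lambda: 1.0
G: 7.0992
k: 0.1000459
tau0_mean: 225.0
tau0_sd: 5.625
As_mean: 1377.0
As_sd: 34.425
papo_max: 0.0015
rho_half: 0.0010904
alpha: 1332.936
box_area: 2203200.0
seed: 1
t_max: 2250
apoptosis_enabled: yes
record_every: 57
crowding_floor: 13.5967856
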