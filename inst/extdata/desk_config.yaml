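kBT: 1.95
Jcc: 0.117
Jcm: 0.196
lambda: 1.0
G: 2.9
k: 18.97
tau0_mean: 40.0
tau0_sd: 1.0
As_mean: 100.0
As_sd: 2.5
papo_max: 0.0015
rho_half: 0.015015
alpha: 96.8
box_area: 10000.0
seed: 1
t_max: 1600
apoptosis_enabled: yes
record_every: 10
crowding_floor: 0.9874209
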