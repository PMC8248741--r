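f_c: 0.01
f_ER: 0.025
gamma: 9.0
J_INleak: 0.15
v_PMCA: 30.0
k_PMCA: 0.45
v_SERCA: 22.5
k_SERCA: 0.105
v_ERleak: 0.03
d1: 0.13
d2: 1.049
d3: 0.9434
d5: 0.08234
a2: 0.2
v_IP3R: 15.0
g_X7: 2.5e-08
E: 0.0
V_mem: -0.06
k1: 0.3
k2: 1265.0
k3: 2.4
k4: 1581.0
k5: 1.58
k6: 221.0
k7: 316.0
L1: 0.0001
L2: 0.004
L3: 0.3
H1: 0.001
H2_C2: 0.01
H2_Q1: 0.05
H2_Q2: 0.8
f_Ca: 0.046
V_osteo: 6.5e-12
z: 2.0
F: 96485.0
alpha_ATP: 0.03
k_ATP: 1.0
delta: 0.01
use_multiplicity: no
desensitized_ladder: yes
g_X7_raw_units: no
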