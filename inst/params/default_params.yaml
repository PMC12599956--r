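P_A: 0.1
V_A: 1.3
K_A: 0.7
n_A: 4.0
G_A: 1.0
V_T: 1.0
K_T: 1.2
n_T: 4.0
G_T: 0.2
P_C: 0.03
theta_CS: 0.5
theta_CD: 1.0
theta_T: 0.6
E0: 1.0
c0: 0.3
k_radial: 0.0066
k_axial: 0.0132
dt: 0.1
t_end: 135.0
t_select: 55.0
n_rings: 2.0
dilute_timer: no
eps_floor: 1.0
min_div_area: 0.3
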