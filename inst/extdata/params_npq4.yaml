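k1_plus: 250.0
k1_minus: 100.0
k2: 114.285714285713993
k3: 0.01
k4: 0.001
k5: 11.1066767941617
k6: 8.0
k9: 5.0e-05
k10: 0.004
KQ_VDE: 1.0
KQ_PsbS: 1.0
n_VDE: 6.0
n_PsbS: 4.0
Zea_max: 0.3
PsbS_max: 0.3
a: 0.09202
phi_II_max: 0.83
PQ_tot: 7.0
nu_e: 2.0
A_tot: 10.0
sigma_II: 0.781485496786867
sigma_I: 0.8
beta_H: 0.001
n_H: 1.0
k_leak: 0.005897435897436
H_0: 0.1
allow_atpase_reversal: no
genotype: npq4
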