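variant: main
innervation:
  name: denervated
  innervated_mask:
  - false
  - false
  - false
  - false
  - false
  - false
  - false
  - false
  - false
  - false
  - false
  - false
  - false
  - false
  - false
  K_NEpn_stim: 0.0
G_ij: 5.0
transport:
  'N': 15
  bf_normal: 2.25
  bf: 2.25
  s: 75.0
  pressure_fold: 1.0
systemic:
  G_ref: 2.0
  tau_glu: 1.30000000000000004
  km_glu: 1.30000000000000004
  n_glu: 2.0
  tau_ins: 0.90000000000000002
  km_ins: 0.90000000000000002
  n_ins: 2.0
  Km_symp: 500.0
  G_symp: 4500.0
  v_Epn: 0.5
  v_NEpn: 1.5
  X_Epn: 6.0
  X_NEpn: 14.0
  adrenal_amplification: 1.39999999999999991
  catechol_scale: 0.45000000000000001
  G_au_scale: 2500.0
  k_clear_ins: 0.005
  k_clear_glu: 0.0
  k_clear_cat: 0.14999999999999999
  u_G_basal: .na.real
  u_basal_factor: 0.58750000000000002
  exercise_multiplier: 3.5
  v_glu_alt: 0.10000000000000001
  km_glu_alt: 0.10000000000000001
  Glu_B0: 0.80000000000000004
  Ins_B0: 0.08
  GB0: 5000.0
calcium:
  'N': 15
  A: 0.20000000000000001
  B: 0.082
  D: 0.80000000000000004
  E: 1.0
  F: 0.01
  k1: 1.0
  k2: 0.14999999999999999
  k3: 1.0
  k_cat: 0.45000000000000001
  k_d: 0.34000000000000002
  k_Hr: 1.0
  L: 0.00015
  k_r_i:
  - 0.5
  - 0.5357142857142857
  - 0.5714285714285714
  - 0.6071428571428571
  - 0.64285714285714279
  - 0.6785714285714286
  - 0.7142857142857143
  - 0.75
  - 0.7857142857142857
  - 0.8214285714285714
  - 0.8571428571428571
  - 0.89285714285714279
  - 0.9285714285714286
  - 0.96428571428571419
  - 1.0
  k_IP3_i:
  - 0.5
  - 0.50714285714285712
  - 0.51428571428571423
  - 0.52142857142857146
  - 0.52857142857142858
  - 0.5357142857142857
  - 0.54285714285714282
  - 0.55000000000000004
  - 0.55714285714285716
  - 0.56428571428571428
  - 0.5714285714285714
  - 0.57857142857142851
  - 0.58571428571428563
  - 0.59285714285714286
  - 0.59999999999999998
  CaT0: 500.19999999999998863
metabolism:
  'N': 15
  CaI_GPK: 0.44
  K_CaI_GPK: 3.0
  v0: 0.05
  v_brk: 5.0
  Km_Glyc: 100.0
  Km_Phos: 4000.0
  n_brk: 4.0
  v_CaI_max: 3.0
  Km_CaI: 0.59999999999999998
  use_Km_CaI: true
  k_LP: 45.0
  k_IP: 26.66000000000000014
  Phos: 4000.0
  zonation_weight_i:
  - 1.0
  - 0.96428571428571419
  - 0.9285714285714286
  - 0.89285714285714279
  - 0.8571428571428571
  - 0.8214285714285714
  - 0.7857142857142857
  - 0.75
  - 0.7142857142857143
  - 0.6785714285714286
  - 0.64285714285714279
  - 0.6071428571428571
  - 0.5714285714285714
  - 0.5357142857142857
  - 0.5
  k_export: 0.10000000000000001
  Glyc0: 300.0
exercise: true
exercise_start: 500.0
exercise_duration: 3600.0
t_end: 4100.0
stimulus_enabled: true
label: denervated_1.4x
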