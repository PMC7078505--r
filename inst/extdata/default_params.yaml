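# Reference physiological and nanoparticle parameters for a 200 g rat.
# Organ keys: liver, kidneys, lungs, spleen, brain, heart, gi, muscle, others.
# f_WT: fractional body weight; f_v: vascular fraction of the organ volume;
# f_CO: fraction of cardiac output delivered arterially (liver entry is the
# hepatic-artery contribution only; portal inflow from gi and spleen is added
# at assembly); r_pore_nm: vessel-wall fenestration radius; A_mac: area
# fraction of the microvascular wall occupied by phagocytes (MPS organs only).
version: 1
body:
  BW_g: 200.0
  CO_ml_h: 4217.0
  GFR_ml_h: 78.6
  urine_ml_h: 2.0833
  bile_ml_h: 0.9375
  hematocrit: 0.45
  lymph_ratio: 0.002          # lymph flow = plasma flow / 500
  lymph_node_wt_frac: 0.002
  plasma_wt_frac: 0.0589
  blood:
    mu_cP: 4.0
    beta_um: 3.6
  capillary:
    R_um: 5.0
    l_um: 1000.0
    l_g_nm: 100.0
    u_um_s: 553.0
    gamma_dot_s: 116.0
    Q_cap_nl_min: 2.58
    f_cap: 0.55
  phagocyte:
    p_W: 1.0e-17
    gamma_mN_m: 0.06
    r_mac_um: 15.0
  organs:
    liver:   {f_WT: 0.05,  f_v: 0.21, f_CO: 0.021, r_pore_nm: 140.0,  A_mac: 0.5}
    kidneys: {f_WT: 0.015, f_v: 0.16, f_CO: 0.141, r_pore_nm: 4.0,    A_mac: 0.0}
    lungs:   {f_WT: 0.01,  f_v: 0.36, f_CO: 1.0,   r_pore_nm: 2.5,    A_mac: 0.0}
    spleen:  {f_WT: 0.01,  f_v: 0.22, f_CO: 0.02,  r_pore_nm: 2500.0, A_mac: 0.1}
    brain:   {f_WT: 0.03,  f_v: 0.04, f_CO: 0.02,  r_pore_nm: 0.5,    A_mac: 0.0}
    heart:   {f_WT: 0.01,  f_v: 0.26, f_CO: 0.051, r_pore_nm: 2.5,    A_mac: 0.0}
    gi:      {f_WT: 0.04,  f_v: 0.2,  f_CO: 0.133, r_pore_nm: 2.5,    A_mac: 0.0}
    muscle:  {f_WT: 0.3,   f_v: 0.04, f_CO: 0.278, r_pore_nm: 2.5,    A_mac: 0.0}
    others:  {f_WT: 0.03,  f_v: 0.01, f_CO: 0.01,  r_pore_nm: 2.5,    A_mac: 0.0}
constants:
  k_B: 1.38e-23
  T_K: 310.0
  g_m_s2: 9.8
  rho_plasma_g_cm3: 1.0
tumor:
  radius_mm: 5.0
  Q_specific_ml_g_min: 0.1
  mu_cP: 7.42
  f_v: 0.1
  r_pore_nm: 850.0
  phi: 0.001
  l_w_um: 5.0
nanoparticle:
  diameter_nm: 100.0
  density_g_cm3: 2.0
  k_deg_per_h: 0.01
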