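# Population-median parameters of a typical cell, by background
# concentration of aspartate. Swimming and kinase-noise parameters depend
# only weakly on background; the values measured at c0 = 1 uM are carried
# for all three backgrounds. The arrival-rate gain G_r (tabulated as
# kD * G_r) varies strongly with background and is listed per c0.
# kD is carried at its conventional rounded value 1.2e5 s^-1 uM^-1
# (4*D*l with D = 800 um^2/s, l = 0.06 um gives 1.156e5).
constants:
  D_um2_per_s: 800.0
  l_um: 0.06
  kD: 1.2e+5
mwc:
  G_inf: 3.5
  K_i: 0.81
backgrounds:
  - c0_uM: 0.1
    sigma_v2: 146.0        # (um/s)^2
    tau_v: 1.19            # s
    P_run: 0.86
    G_r_times_kD: 3.2      # dimensionless
    tau_1: 0.0             # s (delta-function fast lobe)
    tau_2: 7.4             # s
    D_n: 8.1e-4            # 1/s
    tau_n: 8.7             # s
    a0: 0.3
    g_per_mm: 0.0
  - c0_uM: 1.0
    sigma_v2: 146.0
    tau_v: 1.19
    P_run: 0.86
    G_r_times_kD: 2.28
    tau_1: 0.0
    tau_2: 7.4
    D_n: 8.1e-4
    tau_n: 8.7
    a0: 0.3
    g_per_mm: 0.0
  - c0_uM: 10.0
    sigma_v2: 146.0
    tau_v: 1.19
    P_run: 0.86
    G_r_times_kD: 0.251
    tau_1: 0.0
    tau_2: 7.4
    D_n: 8.1e-4
    tau_n: 8.7
    a0: 0.3
    g_per_mm: 0.0
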