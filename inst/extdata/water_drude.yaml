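# Drude oscillator parameterization of the liquid-water energy-loss
# function used by microlineal.  Five ionization shells (1b1, 3a1, 1b2,
# 2a1, 1a1) and five discrete excitation channels (A1B1, B1A1, Rydberg
# A+B, Rydberg C+D, diffuse band).  The coefficient set is the package's
# own calibration of the standard optical-data Drude family against three
# integral constraints of unit-density liquid water: the f-sum rule
# (10 electrons per molecule), the dipole mean excitation energy
# (I = 78 eV) and the position of the collective optical resonance
# (21-22 eV).  An alternative parameterization is a config swap, not a
# code change.
dielectric:
  molecular_density_per_cm3: 3.343e+22
  sum_rule_tolerance: 0.10
  excitation_q_cut_eV: 100.0
  channels:
    - {kind: excitation, label: A1B1,    threshold_eV: 8.22,  amplitude: 0.030, width_eV: 2.0, resonance_eV: 8.22}
    - {kind: excitation, label: B1A1,    threshold_eV: 10.00, amplitude: 0.045, width_eV: 2.2, resonance_eV: 10.00}
    - {kind: excitation, label: RydAB,   threshold_eV: 11.24, amplitude: 0.060, width_eV: 2.5, resonance_eV: 11.24}
    - {kind: excitation, label: RydCD,   threshold_eV: 12.61, amplitude: 0.065, width_eV: 2.8, resonance_eV: 12.61}
    - {kind: excitation, label: diffuse, threshold_eV: 13.77, amplitude: 0.090, width_eV: 3.2, resonance_eV: 13.77}
    - {kind: ionization, label: 1b1,     threshold_eV: 10.79, amplitude: 3.9947, width_eV: 6.5,   resonance_eV: 21.4}
    - {kind: ionization, label: 3a1,     threshold_eV: 13.39, amplitude: 0.6000, width_eV: 11.0,  resonance_eV: 26.5}
    - {kind: ionization, label: 1b2,     threshold_eV: 16.05, amplitude: 2.4891, width_eV: 26.0,  resonance_eV: 42.0}
    - {kind: ionization, label: 2a1,     threshold_eV: 32.30, amplitude: 1.1979, width_eV: 90.0,  resonance_eV: 130.0}
    - {kind: ionization, label: 1a1,     threshold_eV: 539.0, amplitude: 1.9000, width_eV: 350.0, resonance_eV: 650.0}
targets:
  - {diameter_nm: 10,   delta_keV: 0.180}
  - {diameter_nm: 100,  delta_keV: 1.37}
  - {diameter_nm: 1000, delta_keV: 5.56}
variance:
  Vs: 0.125
  Vlet: 0.0
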