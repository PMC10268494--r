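# Example run configuration.  Any block may be omitted; omitted blocks and
# options fall back to the package defaults.
rnf_atp_per_fd: 0.5
allow_nadh_to_h2: false
tukey_k: 3
ch4_threshold_ppm: 4
baseline_semesters: []
baseline_ppm: 1
quantile_type: 7
dG_atp: 70
seed: 1
species:
  - {name: glucose, formula: C6H12O6, charge: 0, phase: aqueous}
  - {name: butyrate, formula: C4H7O2, charge: -1, phase: aqueous}
  - {name: acetate, formula: C2H3O2, charge: -1, phase: aqueous}
  - {name: lactate, formula: C3H5O3, charge: -1, phase: aqueous}
  - {name: formate, formula: CHO2, charge: -1, phase: aqueous}
  - {name: CO2, formula: CO2, charge: 0, phase: gas}
  - {name: H2, formula: H2, charge: 0, phase: gas}
  - {name: CH4, formula: CH4, charge: 0, phase: gas}
  - {name: H2O, formula: H2O, charge: 0, phase: aqueous}
  - {name: "H+", formula: H, charge: 1, phase: aqueous}
thermo:
  - {name: glucose, dfG0_kJ: -917.22, note: compilation}
  - {name: butyrate, dfG0_kJ: -352.63, note: compilation}
  - {name: acetate, dfG0_kJ: -369.41, note: compilation}
  - {name: lactate, dfG0_kJ: -517.18, note: compilation}
  - {name: formate, dfG0_kJ: -351.04, note: compilation}
  - {name: CO2, dfG0_kJ: -394.36, note: gas}
  - {name: H2, dfG0_kJ: 0, note: gas}
  - {name: CH4, dfG0_kJ: -50.75, note: gas}
  - {name: H2O, dfG0_kJ: -237.18, note: liquid}
  - {name: "H+", dfG0_kJ: 0, note: convention}
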