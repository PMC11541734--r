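{
  "version": "1.0",
  "note": "Temperature kinetics of C3 leaf biochemistry. Reference constants at 25 degC and standard pressure, with Arrhenius activation energies. Gammastar/Kc/Ko after Bernacchi et al. (2001, Plant Cell Environ 24:253-259); Vcmax/Jmax energies after Kattge & Knorr (2007); Rd energy after Bernacchi et al. (2001).",
  "reference_temperature_c": 25,
  "reference_pressure_pa": 101325,
  "rgas_j_mol_k": 8.3145,
  "gammastar25_pa": 4.332,
  "dha_gammastar_j_mol": 37830,
  "kc25_pa": 39.97,
  "dha_kc_j_mol": 79430,
  "ko25_pa": 27480,
  "dha_ko_j_mol": 36380,
  "dha_vcmax_j_mol": 65330,
  "dha_jmax_j_mol": 43900,
  "dha_rd_j_mol": 46390
}
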