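{
  "labels": {
    "solute": "piperine",
    "cosolvent": "Transcutol-HP",
    "water": "water"
  },
  "molar_masses": {
    "solute": 285.34,
    "cosolvent": 134.17,
    "water": 18.07
  },
  "fusion": {
    "T_fus": 404.88,
    "dH_fus": 32690,
    "dC_p": 80.74
  },
  "hsp_total": {
    "solute": 22.30,
    "cosolvent": 21.40,
    "water": 47.80
  }
}
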