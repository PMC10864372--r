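{
  "comment": "Model constants for the serine/tyrosine oxyradical - hydrated Mg radical pairs: dominant proton hyperfine couplings from DFT, Mg isotope table at natural abundance, control and exposure field strengths.",
  "g": 2.00232,
  "B0_mT": 0.15,
  "Bexp_mT": 100,
  "pathways": {
    "Ser": { "a_A_mT": 7.45, "spin_A": 0.5 },
    "Tyr": { "a_A_mT": 1.86, "spin_A": 0.5 }
  },
  "mg_isotopes": [
    { "isotope": "24/26Mg", "weight": 0.9, "spin": 0.0, "a_mT": 0.0 },
    { "isotope": "25Mg", "weight": 0.1, "spin": 2.5, "a_mT": -11.22 }
  ]
}
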