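{
  "k": {
    "k1": 66.601905208744,
    "k2": 4.91560095136491,
    "k3": 0.575466432735123,
    "k4": 0.001,
    "k5": 4.96760214783656,
    "k6": 0.0053055612479752,
    "k7": 0.260528304603732,
    "k8": 0.666776244452445,
    "k9": 0.835632530706493,
    "k10": 0.0835278841701895
  },
  "H": {
    "H1": 1.17987473475098,
    "H2": 1.02250208674908,
    "H3": 9.28742766306999,
    "H4": 0.01,
    "H5": 1.77927790364504,
    "H6": 6.8222149378316,
    "H7": 0.211066139527745,
    "H8": 0.0552840360529265,
    "H9": 0.30417576227337,
    "H10": 1.6728744331234
  },
  "d": {
    "d1": 1.3049021000761,
    "d2": 1.25111293689921,
    "d3": 0.00734847463674821,
    "d4": 0.833469349953791,
    "d5": 0.001,
    "d6": 0.227306971958925,
    "d7": 0.001
  },
  "calib": {
    "x_sat": 1.01366007716667,
    "baseline_pa": 400,
    "max_pa": 530,
    "sdf1_rel_per_nM": 0.178260620210066
  }
}
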