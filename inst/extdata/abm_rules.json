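{
  "mic": {
    "p_apop0": 0.001,
    "div_pmax": 0.0385,
    "div_H": 300,
    "div_n": 2,
    "selfrenew_pmax": 0.75,
    "selfrenew_H": 200,
    "selfrenew_n": 2,
    "p_mig": 0.5,
    "cycle_h": 24
  },
  "mm": {
    "p_apop0": 0.002,
    "btz_pmax": 0.09,
    "btz_H": 1,
    "div_pmax": 0.06,
    "div_H": 300,
    "div_n": 2,
    "p_mig": 0.5,
    "cycle_h": 24,
    "lgn": 5
  },
  "cd8": {
    "p_div0": 0.01,
    "tgfb_H": 4,
    "tgfb_n": 1,
    "treg_K": 2,
    "len_pmax": 0.00709,
    "len_H": 1.7,
    "p_die": 0.001,
    "p_lysis": 0.04,
    "attach_protection": 0.3,
    "p_mig": 0.8,
    "cycle_h": 12,
    "sense_radius": 5
  },
  "treg": {
    "p_div_pmax": 0.02,
    "tgfb_H": 1.5,
    "tgfb_n": 1,
    "len_supp_max": 0.3,
    "len_supp_H": 3,
    "p_die": 0.005,
    "p_suppress": 0.04,
    "arrest_frac": 0.5,
    "p_mig": 0.8,
    "cycle_h": 12,
    "sense_radius": 5
  },
  "bmsc": {
    "thal_emax": 0.85,
    "thal_H": 2,
    "ecm_floor_pa": 100
  }
}
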