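{
  "k": {
    "k1": 1.53522959584306,
    "k2": 0.001,
    "k3": 0.412611837848722,
    "k4": 0.154131663326838,
    "k5": 0.00908907483703335,
    "k6": 0.00956671656288292,
    "k7": 0.227804000287587,
    "k8": 0.289072261643335,
    "k9": 0.0638285316796396,
    "k10": 0.18331636877319,
    "k11": 0.0452807014042945
  },
  "H": {
    "H1": 1.45718841837705,
    "H2": 0.230781569328773,
    "H3": 0.0758957326345838,
    "H4": 10,
    "H5": 0.0641381250886714,
    "H6": 0.540894513240853,
    "H7": 0.034210594958406,
    "H8": 1.27568716678896,
    "H9": 0.252716077686915,
    "H10": 0.0305562972436069,
    "H11": 0.0827401912744598
  },
  "d": {
    "d1": 0.570785601518802,
    "d2": 0.701678847680585,
    "d3": 0.559757379038918,
    "d4": 0.632629555514525,
    "d5": 0.4986878639395,
    "d6": 0.59251645319368,
    "d7": 0.586410662459364,
    "d8": 0.237123097638738,
    "d9": 0.0193438781805646
  },
  "drug": {
    "K_BTZ": 0.0248255539781483,
    "H_BTZ": 2.5
  },
  "calib": {
    "adhesion_floor": 0.2
  }
}
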