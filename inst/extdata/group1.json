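{
  "A": 0.05, "g": 0.6, "eta": 0.05, "p": 0.2, "beta": 0.5,
  "gamma": 0.2, "alpha": 0.1, "epsilon": 0.1, "k": 0.65, "theta": 0.14
}
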