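{
  "A": 0.5, "g": 0.8, "eta": 0.1, "p": 0.6, "beta": 0.9,
  "gamma": 0.3, "alpha": 0.2, "epsilon": 0.15, "k": 0.7, "theta": 0.1
}
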