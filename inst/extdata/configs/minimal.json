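{
  "version": 1,
  "populations": [
    {"name": "drive", "n": 1, "model": "source",
     "stimulus": {"type": "poisson", "rate": 20, "start": 0, "stop": 1000}}
  ],
  "projections": [],
  "runtime": {"duration_ms": 1000, "seed": 1}
}
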