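{
  "version": 1,
  "populations": [
    {"name": "inputs", "n": 20, "model": "source",
     "stimulus": {"type": "poisson", "rate": 20, "start": 0, "stop": 2000}},
    {"name": "output", "n": 1, "model": "lif",
     "params": {"tau_m": 20, "tau_syn": 5, "v_rest": -65, "v_reset": -65,
                "v_thresh": -50, "r_m": 1, "t_refrac": 2}}
  ],
  "projections": [
    {"source": "inputs", "target": "output",
     "connectivity": {"type": "all_to_all"},
     "weight": {"type": "uniform", "min": 1.5, "max": 3},
     "delay": 1, "receptor": "exc", "plastic": true,
     "rule": {"name": "stdp_trace",
              "params": {"a_plus": 0.02, "a_minus": 0.021,
                         "tau_plus": 20, "tau_minus": 20,
                         "w_min": 0, "w_max": 4}}}
  ],
  "runtime": {"duration_ms": 2000, "seed": 1, "window_ms": 128, "bin_ms": 2,
              "snapshots": "boundaries"}
}
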