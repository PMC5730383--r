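# Desk-scale van der Pol configuration: full-scale tuning statistics,
# reduced population. Load with load_config().
system: vanderpol
n_neurons: 1000
scheme: intercept_maxrate
eta: 2.0e-4
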