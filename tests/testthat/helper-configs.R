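# small, fast configurations shared across tests; all inside the model's
# stated convergence region except where a test deliberately probes it
fast_cfg <- function(n = 500L, d = 0.005, ms = 0.6)
  simulation_config(n_walls = n, d_eps = d, max_strain = ms)

fit_cfg <- function() simulation_config(n_walls = 2000L, d_eps = 0.005)

young_moduli <- function() tissue_moduli(4.36, 0.114)
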