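# Shared fixtures: coarse simulation grids keep the suite fast while the
# package defaults stay at production resolution.

quick_config <- function(t_end = 1000, n_uniform = 120) {
  sim_config(t_end = t_end,
             times = unique(c(0, 10^seq(-3, 0, length.out = 31),
                              seq(1, t_end, length.out = n_uniform))))
}

reference_np <- function() nanoparticle(diameter_nm = 100)

tumor_blood <- function() blood_env(mu_cP = 7.42)
tumor_pore <- function() pore_geometry(850, l_w_um = 5, phi = 0.001)
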