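# Shared fixtures: heavyweight simulations are computed once per test run and
# cached; everything is generated in code from the shipped parameter set.

.mf_test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .mf_test_cache)) {
    assign(name, force(expr), envir = .mf_test_cache)
  }
  get(name, envir = .mf_test_cache)
}

test_params <- function() cached("params", default_params())

test_grid <- function() cached("grid", {
  p <- test_params()
  discretize(build_granule_cell(p$geometry, p$passive),
             discretization_rule(p$sim$max_seg_um))
})

# Fig-2 style EPreSP propagation run (subthreshold dendritic input)
epresp_run <- function() cached("epresp", {
  simulate_epresp(test_params(), grid = test_grid())
})

# Fig-3 style paired experiment (control AP vs AP preceded by an EPreSP)
epresp_pair <- function() cached("epresp_pair", {
  simulate_epresp_plus_ap(test_params(), grid = test_grid())
})

# Fig-4 style paired experiment (high-chloride depolarizing GABA-EPreSP)
gaba_pair <- function() cached("gaba_pair", {
  simulate_gaba_epresp_plus_ap(test_params(), e_gaba = -52, grid = test_grid())
})

# control AP + presynaptic Ca2+ current at bouton 1
ap_ca_run <- function(dt = NULL, ca_scale = 1) {
  key <- paste0("ap_ca_", dt %||% "d", "_", ca_scale)
  cached(key, {
    p <- test_params()
    if (!is.null(dt)) p$sim$dt_ms <- dt
    grid <- test_grid()
    mech <- build_mechanisms(grid, p, ca_density_scale = ca_scale)
    simulate_ap_ca(p, grid = grid, mech = mech)
  })
}

channel_table <- function(channel) {
  cached(paste0("char_", channel), characterize_channel(channel, test_params()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
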