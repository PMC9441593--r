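# Simulation engine: mechanism placement, the implicit cable solver wrapper,
# ideal voltage clamp, steady-state initialization, and the membrane current
# audit.

#' Simulation configuration
#'
#' @param duration total simulated time, ms.
#' @param dt time step, ms (default 0.05; clamp characterization uses 0.005
#'   to resolve sub-millisecond time constants).
#' @param v_init initial (and holding) potential, mV.
#' @param method `"cn"` (Crank-Nicolson, default) or `"be"` (backward Euler).
#' @param record landmarks at which to record.
#' @param settle_ms unstimulated settling time integrated before t = 0 so
#'   that runs start from the model's true resting fixed point (the leak
#'   reversal of -81 mV pulls the quiescent membrane slightly below the
#'   nominal -80 mV initialization).
#' @return a list of class `mf_config`.
#' @export
sim_config <- function(duration, dt = 0.05, v_init = -80, method = c("cn", "be"),
                       record = "soma", settle_ms = 0) {
  if (dt <= 0 || duration <= 0) stop("dt and duration must be positive")
  method <- match.arg(method)
  structure(list(duration = duration, dt = dt, v_init = v_init,
                 method = method, theta = if (method == "cn") 0.5 else 1.0,
                 record = record, settle_ms = settle_ms),
            class = "mf_config")
}

#' Place membrane mechanisms on a compartment grid
#'
#' Maps channel densities to compartments by section kind: axonal Na+ density
#' on axon, boutons, filopodia and collaterals; somatic Na+ density on soma
#' and dendrites; K+ and leak everywhere; Ca2+ channels (P/Q, N, R mix) on
#' main and collateral boutons.
#'
#' @param grid an `mf_grid`.
#' @param params full parameter set ([default_params()]).
#' @param active include voltage-gated Na+/K+ channels (FALSE gives a purely
#'   passive membrane).
#' @param calcium include the Markov Ca2+ channels.
#' @param ca_density_scale scalar multiplying every Ca2+ permeability
#'   (ratio metrics are invariant to it).
#' @return a list of class `mf_mechanisms` with per-compartment conductances.
#' @export
build_mechanisms <- function(grid, params = default_params(), active = TRUE,
                             calcium = TRUE, ca_density_scale = 1) {
  comp <- grid$comp
  n <- nrow(comp)
  area <- comp$area_cm2
  pv <- grid$passive

  axonal <- comp$kind %in% c("axon", "bouton", "filopodium", "collateral",
                             "collateral_bouton")
  dend <- startsWith(comp$kind, "dendrite")
  # mS/cm2 * cm2 = mS = 1e3 uS
  g_leak <- (1 / pv$rm_kohm_cm2) * area * 1e3
  g_na <- g_k <- numeric(n)
  if (active) {
    dens <- ifelse(axonal, params$na$gbar_axon_ms_cm2,
                   ifelse(dend, params$na$gbar_dend_ms_cm2,
                          params$na$gbar_soma_ms_cm2))
    g_na <- dens * area * 1e3
    g_k <- params$k$gbar_ms_cm2 * area * 1e3
  }

  ca_comp <- integer(0)
  ca_pa <- matrix(0, 0, 3)
  if (calcium) {
    ca_comp <- which(comp$kind %in% c("bouton", "collateral_bouton"))
    pb <- vapply(params$ca$subtypes[c("pq", "n", "r")],
                 function(s) s$pbar_cm_s, numeric(1))
    ca_pa <- outer(area[ca_comp], pb * ca_density_scale)  # cm^3/s
  }

  structure(list(
    cm_nf = pv$cm_uf_cm2 * area * 1e3,
    g_leak_us = g_leak, e_leak = pv$e_leak_mv,
    g_na_us = g_na, e_na = params$na$e_rev_mv,
    g_k_us = g_k, e_k = params$k$e_rev_mv,
    gates = gate_matrix(params),
    ca_comp = ca_comp, ca_pa = ca_pa,
    ca_rates = ca_rate_matrix(params),
    cao = params$ca$cao_mm, cai = params$ca$cai_mm,
    temp = params$ca$temp_k
  ), class = "mf_mechanisms")
}

# protocol -> 0-based stimulus matrices for the solver
.protocol_matrices <- function(grid, proto) {
  inj <- matrix(0, 0, 4)
  if (!is.null(proto$inj) && nrow(proto$inj)) {
    p <- proto$inj
    if (is.null(p$pos)) p$pos <- 0.5
    comp <- mapply(function(s, x) landmark_comp(grid, s, x), p$site, p$pos)
    inj <- cbind(comp - 1L, p$onset, p$dur, p$amp_na)
  }
  syn <- matrix(0, 0, 6)
  if (!is.null(proto$syn) && nrow(proto$syn)) {
    p <- proto$syn
    if (is.null(p$pos)) p$pos <- 0.5
    comp <- mapply(function(s, x) landmark_comp(grid, s, x), p$site, p$pos)
    # nS -> uS
    syn <- cbind(comp - 1L, p$gmax_ns * 1e-3, p$tau_rise, p$tau_decay,
                 p$onset, p$e_rev)
  }
  list(inj = inj, syn = syn)
}

#' Run a simulation
#'
#' Integrates the branched cable equation with all placed mechanisms under a
#' stimulus protocol.  Voltage is solved implicitly on the tree each step
#' (tree-ordered Hines elimination); HH gates advance by exponential
#' (Rush-Larsen) updates; Markov occupancies advance by backward Euler on the
#' master equation with a renormalization guard; the Ca2+ current enters the
#' voltage equation explicitly (it is a negligible feedback at these
#' densities -- a tested property).
#'
#' @param grid an `mf_grid`.
#' @param mech an `mf_mechanisms` (from [build_mechanisms()]).
#' @param proto list with optional data.frames `inj` (columns `site`, `pos`,
#'   `onset`, `dur`, `amp_na`) and `syn` (columns `site`, `pos`, `gmax_ns`,
#'   `tau_rise`, `tau_decay`, `onset`, `e_rev`).
#' @param config an `mf_config` ([sim_config()]).
#' @return an `mf_traces` data.frame: `time_ms`, one `v_<site>` column (mV)
#'   per recorded landmark, `ina_<site>`/`ik_<site>` (pA) where those
#'   channels are present, and `ica_pq_/ica_n_/ica_r_/ica_<site>` (pA) for
#'   recorded sites carrying Ca2+ channels.  Attributes: `resid_max`
#'   (solver residual), `occ_err_max` (Markov conservation error), `occ`
#'   (state occupancies at the first Ca2+ recording site), `v_final`.
#' @export
run_sim <- function(grid, mech, proto = list(), config) {
  stim <- .protocol_matrices(grid, proto)
  rec_comp <- vapply(config$record, function(s) landmark_comp(grid, s),
                     integer(1))
  rec_ca_rows <- match(rec_comp, mech$ca_comp)  # NA where no Ca channels
  ca_rec <- which(!is.na(rec_ca_rows))
  nstep <- as.integer(round(config$duration / config$dt))

  out <- engine_run_cpp(
    parent = as.integer(ifelse(is.na(grid$comp$parent), -1L,
                               grid$comp$parent - 1L)),
    ga_us = grid$comp$ga_us, cm_nf = mech$cm_nf,
    g_leak_us = mech$g_leak_us, e_leak = mech$e_leak,
    g_na_us = mech$g_na_us, e_na = mech$e_na,
    g_k_us = mech$g_k_us, e_k = mech$e_k,
    gates = mech$gates,
    ca_comp = as.integer(mech$ca_comp - 1L), ca_pa = mech$ca_pa,
    ca_rates = mech$ca_rates,
    cao = mech$cao, cai = mech$cai, temp = mech$temp,
    inj = stim$inj, syn = stim$syn,
    dt = config$dt, nstep = nstep, v_init = config$v_init,
    theta = config$theta,
    clamped = rep(FALSE, nrow(grid$comp)), clamp_v = numeric(0),
    rec_idx = as.integer(rec_comp - 1L),
    rec_ca_rows = as.integer(rec_ca_rows[ca_rec] - 1L),
    settle_steps = as.integer(round((config$settle_ms %||% 0) / config$dt)))

  .assemble_traces(out, config, ca_rec, mech)
}

.assemble_traces <- function(out, config, ca_rec, mech) {
  sites <- config$record
  df <- data.frame(time_ms = out$t)
  for (r in seq_along(sites)) df[[paste0("v_", sites[r])]] <- out$v[, r]
  active <- any(mech$g_na_us > 0) || any(mech$g_k_us > 0)
  if (active) {
    for (r in seq_along(sites)) {
      df[[paste0("ina_", sites[r])]] <- out$ina[, r] * 1e3
      df[[paste0("ik_", sites[r])]] <- out$ik[, r] * 1e3
    }
  }
  if (length(ca_rec)) {
    for (j in seq_along(ca_rec)) {
      s <- sites[ca_rec[j]]
      icam <- out$ica[[j]]
      df[[paste0("ica_pq_", s)]] <- icam[, 1] * 1e3
      df[[paste0("ica_n_", s)]] <- icam[, 2] * 1e3
      df[[paste0("ica_r_", s)]] <- icam[, 3] * 1e3
      df[[paste0("ica_", s)]] <- icam[, 4] * 1e3
    }
  }
  structure(df, class = c("mf_traces", "data.frame"),
            config = config, resid_max = out$resid_max,
            occ_err_max = out$occ_err_max, occ = out$occ,
            v_final = out$v_final)
}

#' Single-compartment ideal voltage clamp of one channel
#'
#' The command potential is imposed exactly (no series resistance); only the
#' selected channel is present and only its current is reported.
#'
#' @param channel one of `"na"`, `"k"`, `"ca_pq"`, `"ca_n"`, `"ca_r"`.
#' @param levels data.frame with columns `v_mv`, `dur_ms`: the piecewise
#'   constant command.
#' @param params parameter set.
#' @param dt time step, ms.
#' @param diam_um sphere diameter (default the 10 um characterization
#'   sphere).
#' @param method integration method, as in [sim_config()].
#' @return `mf_traces` data.frame with `time_ms`, `v_mv` (command) and
#'   `i_pa` (channel current, inward negative); attribute `occ` holds Markov
#'   occupancies for Ca2+ channels.
#' @export
run_voltage_clamp <- function(channel = c("na", "k", "ca_pq", "ca_n", "ca_r"),
                              levels, params = default_params(),
                              dt = params$sim$dt_fine_ms, diam_um = 10,
                              method = "cn") {
  channel <- match.arg(channel)
  grid <- sphere_grid(diam_um, params$passive)
  area <- grid$comp$area_cm2
  mech <- build_mechanisms(grid, params, active = FALSE, calcium = FALSE)
  mech$g_leak_us <- 0 * mech$g_leak_us   # channel current only
  sub_idx <- c(ca_pq = 1L, ca_n = 2L, ca_r = 3L)
  if (channel == "na") {
    mech$g_na_us <- params$na$gbar_axon_ms_cm2 * area * 1e3
  } else if (channel == "k") {
    mech$g_k_us <- params$k$gbar_ms_cm2 * area * 1e3
  } else {
    s <- sub_idx[[channel]]
    pb <- params$ca$subtypes[[c("pq", "n", "r")[s]]]$pbar_cm_s
    mech$ca_comp <- 1L
    pa <- matrix(0, 1, 3)
    pa[1, s] <- pb * area
    mech$ca_pa <- pa
  }

  nstep <- as.integer(round(sum(levels$dur_ms) / dt))
  edges <- cumsum(levels$dur_ms)
  tgrid <- (0:nstep) * dt
  seg <- findInterval(tgrid, c(0, edges), left.open = TRUE,
                      rightmost.closed = TRUE)
  seg[1] <- 1L
  seg <- pmin(seg, nrow(levels))
  cmd <- levels$v_mv[seg]

  out <- engine_run_cpp(
    parent = -1L, ga_us = 0, cm_nf = mech$cm_nf,
    g_leak_us = mech$g_leak_us, e_leak = mech$e_leak,
    g_na_us = mech$g_na_us, e_na = mech$e_na,
    g_k_us = mech$g_k_us, e_k = mech$e_k,
    gates = mech$gates,
    ca_comp = as.integer(mech$ca_comp - 1L), ca_pa = mech$ca_pa,
    ca_rates = mech$ca_rates,
    cao = mech$cao, cai = mech$cai, temp = mech$temp,
    inj = matrix(0, 0, 4), syn = matrix(0, 0, 6),
    dt = dt, nstep = nstep, v_init = cmd[1],
    theta = if (method == "cn") 0.5 else 1.0,
    clamped = TRUE, clamp_v = cmd,
    rec_idx = 0L,
    rec_ca_rows = if (length(mech$ca_comp)) 0L else integer(0),
    settle_steps = 0L)

  i_na <- switch(channel,
                 na = out$ina[, 1],
                 k = out$ik[, 1],
                 out$ica[[1]][, 4])
  structure(data.frame(time_ms = out$t, v_mv = cmd, i_pa = i_na * 1e3),
            class = c("mf_traces", "data.frame"),
            occ = out$occ, occ_err_max = out$occ_err_max, channel = channel)
}

#' Steady state of all gating variables at a fixed voltage
#'
#' Gates at `x_inf(V)`; Markov occupancies at the stationary distribution of
#' the generator at `V`.
#' @param params parameter set.
#' @param v membrane potential, mV.
#' @return list with `gates` (named vector m, h, n, hk) and `occ`
#'   (6 x 3 matrix of occupancies, columns P/Q, N, R).
#' @export
steady_state <- function(params, v) {
  g <- list(m = params$na$m, h = params$na$h, n = params$k$n, hk = params$k$hk)
  gates <- vapply(g, function(x) gate_dynamics(x, v)$inf, numeric(1))
  occ <- sapply(params$ca$subtypes[c("pq", "n", "r")],
                function(s) markov_stationary(s, v))
  list(gates = gates, occ = occ)
}

#' Membrane current audit for a single-compartment trace
#'
#' Residual of `Cm dV/dt + I_ion - I_inj` evaluated from a recorded voltage
#' trace by central differences; for a correct trajectory the residual
#' converges to zero as the step is refined (first order for backward Euler,
#' second order for Crank-Nicolson).
#'
#' @param t,v time (ms) and voltage (mV) vectors.
#' @param cm_nf membrane capacitance, nF.
#' @param g_leak_us,e_leak leak conductance (uS) and reversal (mV).
#' @param i_inj injected current at the sample times, nA.
#' @param i_ion additional recorded ionic current, nA (e.g. Na+ plus K+).
#' @return residual per interior sample, nA.
#' @export
membrane_current_audit <- function(t, v, cm_nf, g_leak_us, e_leak,
                                   i_inj = 0, i_ion = 0) {
  n <- length(t)
  if (length(i_inj) == 1) i_inj <- rep(i_inj, n)
  if (length(i_ion) == 1) i_ion <- rep(i_ion, n)
  core <- 2:(n - 1)
  dvdt <- (v[core + 1] - v[core - 1]) / (t[core + 1] - t[core - 1])
  cm_nf * dvdt + g_leak_us * (v[core] - e_leak) + i_ion[core] - i_inj[core]
}
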