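# Protocols: the characterization and modulation experiments, encoded as
# reproducible procedures over the engine.

#' Voltage-clamp characterization of one channel
#'
#' Runs the standard single-compartment (10 um sphere) clamp families and
#' fits activation, inactivation and deactivation kinetics:
#' * Na+: hold -80 mV (10 ms), pre-pulse -120 mV (30 ms), test steps
#'   -70..+70 mV in 10 mV increments (20 ms).
#' * K+: hold -80 mV (10 ms), test steps -70..+50 mV in 20 mV increments
#'   (150 ms, long enough to resolve slow inactivation).
#' * Ca2+ subtypes: hold -80 mV (10 ms), test steps -70..+40 mV in 10 mV
#'   increments (20 ms), step back to -80 mV (10 ms) for tail currents.
#'
#' Activation time constants come from a mono-exponential fit of the rising
#' phase between 10% of the peak and the peak; decay time constants from a
#' single-exponential fit (with offset) of the current after the peak; tail
#' (deactivation) time constants from a single-exponential fit of the tail
#' current after repolarization.  A failed fit at one potential flags that
#' entry `NA` and is not fatal.
#'
#' @param channel `"na"`, `"k"`, `"ca_pq"`, `"ca_n"` or `"ca_r"`.
#' @param params parameter set.
#' @param dt clamp time step, ms.
#' @return data.frame with one row per test potential: `v_test`,
#'   `i_peak_pa` (signed peak of the test-pulse current), `tau_act_ms`,
#'   and `tau_inact_ms` (Na+/K+) or `tau_deact_ms` (Ca2+).
#' @export
characterize_channel <- function(channel = c("na", "k", "ca_pq", "ca_n",
                                             "ca_r"),
                                 params = default_params(),
                                 dt = params$sim$dt_fine_ms) {
  channel <- match.arg(channel)
  is_ca <- startsWith(channel, "ca")
  v_tests <- switch(channel,
                    na = seq(-70, 70, by = 10),
                    k = seq(-70, 50, by = 20),
                    seq(-70, 40, by = 10))
  rows <- lapply(v_tests, function(vt) {
    lev <- switch(channel,
                  na = data.frame(v_mv = c(-80, -120, vt),
                                  dur_ms = c(10, 30, 20)),
                  k = data.frame(v_mv = c(-80, vt), dur_ms = c(10, 150)),
                  data.frame(v_mv = c(-80, vt, -80), dur_ms = c(10, 20, 10)))
    tr <- run_voltage_clamp(channel, lev, params, dt = dt)
    t_on <- switch(channel, na = 40, k = 10, 10)
    t_off <- switch(channel, na = 60, k = 160, 30)
    .fit_clamp_step(tr, t_on, t_off, vt, is_ca)
  })
  out <- do.call(rbind, rows)
  attr(out, "channel") <- channel
  out
}

# fit activation/decay (and tail for Ca) on one clamp sweep
.fit_clamp_step <- function(tr, t_on, t_off, v_test, is_ca) {
  eps <- 1e-9
  sel <- tr$time_ms > t_on + eps & tr$time_ms <= t_off + eps
  tt <- tr$time_ms[sel]
  ii <- tr$i_pa[sel]
  mag <- abs(ii)
  pk <- which.max(mag)
  i_peak <- ii[pk]
  tau_act <- NA_real_
  tau_dec <- NA_real_
  if (max(mag) > 0.05) {
    i10 <- which(mag >= 0.10 * mag[pk])
    i10 <- i10[i10 <= pk]
    if (length(i10) >= 3) {
      f <- fit_exp_rise(tt[i10[1]:pk], mag[i10[1]:pk])
      if (f$ok) tau_act <- f$tau
    }
    if (pk < length(tt) - 10) {
      f <- fit_single_exponential(tt, ii, window = c(tt[pk], max(tt)),
                                  with_offset = TRUE)
      if (f$ok) tau_dec <- f$tau
    }
  }
  if (is_ca) {
    tail_sel <- tr$time_ms > t_off + eps
    tau_tail <- NA_real_
    if (sum(tail_sel) > 10) {
      f <- fit_single_exponential(tr$time_ms[tail_sel], tr$i_pa[tail_sel],
                                  with_offset = FALSE)
      if (f$ok) tau_tail <- f$tau
    }
    data.frame(v_test = v_test, i_peak_pa = i_peak, tau_act_ms = tau_act,
               tau_deact_ms = tau_tail)
  } else {
    data.frame(v_test = v_test, i_peak_pa = i_peak, tau_act_ms = tau_act,
               tau_inact_ms = tau_dec)
  }
}

# default dendritic input: a lumped glutamatergic conductance at the midpoint
# of the dendritic trunk (the EPreSP waveform entering the axon is set by the
# somatic EPSP; a single proximal source keeps its time course independent of
# the unmeasured distal dendrite dimensions)
.glu_synapses <- function(params, gmax_total_ns, onset) {
  data.frame(site = "dend_trunk", pos = 0.5, gmax_ns = gmax_total_ns,
             tau_rise = params$syn_glu$tau_rise_ms,
             tau_decay = params$syn_glu$tau_decay_ms,
             onset = onset, e_rev = params$syn_glu$e_rev_mv)
}

# GABA-A point sources: n_per_cylinder sources evenly spaced along every
# inter-bouton axonal cylinder (uniform axonal density)
.gaba_synapses <- function(params, e_rev, onset,
                           g_per_source = params$gaba$gmax_per_source_ns) {
  ncyl <- params$geometry$axon$n_cylinders
  nsrc <- params$gaba$n_per_cylinder
  pos <- (seq_len(nsrc) - 0.5) / nsrc
  data.frame(site = rep(paste0("axon_", seq_len(ncyl)), each = nsrc),
             pos = rep(pos, ncyl), gmax_ns = g_per_source,
             tau_rise = params$gaba$tau_rise_ms,
             tau_decay = params$gaba$tau_decay_ms,
             onset = onset, e_rev = e_rev)
}

.model_grid <- function(params) {
  m <- build_granule_cell(params$geometry, params$passive)
  discretize(m, discretization_rule(params$sim$max_seg_um))
}

#' Simulate EPreSP propagation along the axon
#'
#' Applies subthreshold dendritic synaptic input (calibrated to a ~20 mV
#' somatic EPSP by default) to the full active model and measures the
#' excitatory presynaptic potential (EPreSP) peak at every main-axon bouton.
#' Fits `A * exp(-x/lambda)` to peak amplitude versus path distance from the
#' soma.
#'
#' @param params parameter set.
#' @param gmax_total_ns total dendritic synaptic conductance, nS.
#' @param onset synaptic onset, ms.
#' @param duration simulated time, ms.
#' @param grid optionally a prebuilt grid (rebuilt from `params` otherwise).
#' @return list: `peaks` (data.frame bouton, distance_um, peak_mv,
#'   t_peak_ms), `fit` (the length-constant `mf_fit`), `soma_peak_mv`,
#'   `traces`.
#' @export
simulate_epresp <- function(params = default_params(),
                            gmax_total_ns = params$syn_glu$gmax_total_ns,
                            onset = 5, duration = 100, grid = NULL) {
  if (is.null(grid)) grid <- .model_grid(params)
  mech <- build_mechanisms(grid, params)
  boutons <- paste0("bouton_", seq_len(params$geometry$bouton$count))
  cfg <- sim_config(duration = duration, dt = params$sim$dt_ms,
                    v_init = params$passive$v_rest_mv,
                    record = c("soma", boutons), settle_ms = 300)
  proto <- list(syn = .glu_synapses(params, gmax_total_ns, onset))
  tr <- run_sim(grid, mech, proto, cfg)

  peak_of <- function(site) {
    v <- tr[[paste0("v_", site)]]
    i0 <- which(tr$time_ms >= onset)[1]
    c(peak = max(v[i0:length(v)]) - v[i0],
      t_peak = tr$time_ms[i0 - 1 + which.max(v[i0:length(v)])])
  }
  pk <- vapply(c("soma", boutons), peak_of, numeric(2))
  if (gmax_total_ns > 0 && any(pk["peak", ] + params$passive$v_rest_mv > -20)) {
    stop("suprathreshold input: EPreSP protocol triggered a spike")
  }
  m <- grid$morphology
  dist <- vapply(boutons, function(b) path_distance(m, "soma", b), numeric(1))
  peaks <- data.frame(bouton = seq_along(boutons), distance_um = dist,
                      peak_mv = pk["peak", boutons],
                      t_peak_ms = pk["t_peak", boutons])
  fit <- fit_distance_constant(peaks$distance_um, peaks$peak_mv)
  list(peaks = peaks, fit = fit, soma_peak_mv = unname(pk["peak", "soma"]),
       traces = tr)
}

#' Action-potential-evoked presynaptic Ca2+ current
#'
#' Evokes an action potential (default: somatic injection, 2 ms, 0.2 nA),
#' records membrane potential and the presynaptic Ca2+ current (total and
#' per subtype) at a bouton, and computes peak/charge metrics over the AP
#' window.
#'
#' @param params parameter set.
#' @param stim list: `site`, `onset`, `dur`, `amp_na`.
#' @param measure landmark of the recorded bouton.
#' @param duration simulated time, ms.
#' @param window_len metric window after stimulus onset, ms.
#' @param grid,mech optionally prebuilt grid/mechanisms.
#' @param extra_syn optional additional synapse data.frame (internal use).
#' @return list: `metrics` (`mf_ca_metrics` of the total Ca2+ current),
#'   `ap_peak_mv`, `ap_t_peak_ms`, `traces`.
#' @export
simulate_ap_ca <- function(params = default_params(),
                           stim = list(site = "soma", onset = 5, dur = 2,
                                       amp_na = 0.2),
                           measure = "bouton_1", duration = NULL,
                           window_len = 10, grid = NULL, mech = NULL,
                           extra_syn = NULL, require_ap = TRUE) {
  if (is.null(grid)) grid <- .model_grid(params)
  if (is.null(mech)) mech <- build_mechanisms(grid, params)
  if (is.null(duration)) duration <- stim$onset + window_len + 5
  cfg <- sim_config(duration = duration, dt = params$sim$dt_ms,
                    v_init = params$passive$v_rest_mv,
                    record = c("soma", measure), settle_ms = 300)
  proto <- list(inj = data.frame(site = stim$site, pos = 0.5,
                                 onset = stim$onset, dur = stim$dur,
                                 amp_na = stim$amp_na),
                syn = extra_syn)
  tr <- run_sim(grid, mech, proto, cfg)
  v <- tr[[paste0("v_", measure)]]
  ap_peak <- max(v)
  if (require_ap && ap_peak < 0) {
    stop("no action potential generated at ", measure)
  }
  metrics <- peak_and_charge(tr$time_ms, tr[[paste0("ica_", measure)]],
                             stim_onset = stim$onset,
                             window_len = window_len)
  list(metrics = metrics, ap_peak_mv = ap_peak,
       ap_t_peak_ms = tr$time_ms[which.max(v)], traces = tr)
}

# Shared paired-run machinery for the EPreSP and GABA-EPreSP modulation
# experiments.  The conditioning input (a synapse set) precedes a somatic AP
# timed so the spike reaches the measured bouton at the local peak of the
# conditioning depolarization; control and conditioned runs use identical
# timing and discretization.
.paired_modulation <- function(params, make_syn, measure = "bouton_1",
                               dt_lag = NULL, syn_onset = 10,
                               window_len = 10, grid = NULL) {
  if (is.null(grid)) grid <- .model_grid(params)
  mech <- build_mechanisms(grid, params)
  stim0 <- list(site = "soma", onset = 5, dur = 2, amp_na = 0.2)

  # conditioning input alone: local peak time at the measured bouton
  cfg <- sim_config(duration = syn_onset + 60, dt = params$sim$dt_ms,
                    v_init = params$passive$v_rest_mv,
                    record = c("soma", measure), settle_ms = 300)
  solo <- run_sim(grid, mech, list(syn = make_syn(syn_onset)), cfg)
  v <- solo[[paste0("v_", measure)]]
  if (max(v) > -20) stop("suprathreshold input: conditioning input spiked")
  i0 <- which(solo$time_ms >= syn_onset)[1]
  t_peak_cond <- solo$time_ms[i0 - 1 + which.max(v[i0:length(v)])]
  sub_ica <- peak_and_charge(solo$time_ms, solo[[paste0("ica_", measure)]],
                             stim_onset = syn_onset,
                             window_len = min(window_len + 20,
                                              syn_onset + 50 - syn_onset))

  # AP latency from stimulus onset to spike peak at the measured bouton
  probe <- simulate_ap_ca(params, stim0, measure, grid = grid, mech = mech,
                          window_len = window_len)
  lat <- probe$ap_t_peak_ms - stim0$onset

  if (is.null(dt_lag)) dt_lag <- (t_peak_cond - syn_onset) - lat
  t_ap <- syn_onset + dt_lag
  dur <- t_ap + window_len + 5
  stim <- list(site = "soma", onset = t_ap, dur = 2, amp_na = 0.2)

  control <- simulate_ap_ca(params, stim, measure, duration = dur,
                            window_len = window_len, grid = grid,
                            mech = mech)
  cond <- simulate_ap_ca(params, stim, measure, duration = dur,
                         window_len = window_len, grid = grid, mech = mech,
                         extra_syn = make_syn(syn_onset), require_ap = FALSE)

  list(peak_ratio_pct = 100 * cond$metrics$peak_pa / control$metrics$peak_pa,
       charge_ratio_pct = 100 * cond$metrics$charge_fc /
         control$metrics$charge_fc,
       control = control, conditioned = cond,
       ap_peak_control_mv = control$ap_peak_mv,
       ap_peak_cond_mv = cond$ap_peak_mv,
       dt_lag_ms = dt_lag, t_peak_cond_ms = t_peak_cond,
       subthreshold_ica = sub_ica, solo_traces = solo)
}

#' Modulation of AP-evoked Ca2+ current by a preceding EPreSP
#'
#' Paired experiment: a somatic action potential alone (control) versus the
#' same action potential preceded by subthreshold dendritic input whose
#' EPreSP reaches the measured bouton at the moment of spike arrival.
#' Reports the conditioned/control percentage ratios of the
#' baseline-subtracted peak and charge of the presynaptic Ca2+ current.
#'
#' @param params parameter set.
#' @param gmax_total_ns total dendritic conductance (default calibrated to a
#'   ~20 mV somatic EPSP).
#' @param dt_lag lag from synaptic onset to the somatic stimulus, ms
#'   (default: spike arrives at the bouton at the local EPreSP peak).
#' @param measure recorded bouton.
#' @param grid optionally a prebuilt grid.
#' @return list with `peak_ratio_pct`, `charge_ratio_pct`, AP peaks for both
#'   conditions, the subthreshold EPreSP-evoked Ca2+ metrics
#'   (`subthreshold_ica`), and the full condition results.
#' @export
simulate_epresp_plus_ap <- function(params = default_params(),
                                    gmax_total_ns =
                                      params$syn_glu$gmax_total_ns,
                                    dt_lag = NULL, measure = "bouton_1",
                                    grid = NULL) {
  .paired_modulation(params,
                     function(onset) .glu_synapses(params, gmax_total_ns,
                                                   onset),
                     measure = measure, dt_lag = dt_lag, grid = grid)
}

#' Modulation of AP-evoked Ca2+ current by a preceding GABA-EPreSP
#'
#' As [simulate_epresp_plus_ap()], but the conditioning input is the set of
#' axonal GABA-A point conductances (slow spillover-like waveform).  With a
#' chloride reversal above rest the GABA-EPreSP is depolarizing; at
#' `e_gaba = -78` mV the effect is a nearly pure shunt.
#'
#' @param params parameter set.
#' @param e_gaba GABA-A reversal potential, mV (presets -78 / -65 / -52).
#' @param g_per_source peak conductance per point source, nS.
#' @param dt_lag,measure,grid as in [simulate_epresp_plus_ap()].
#' @return as [simulate_epresp_plus_ap()].
#' @export
simulate_gaba_epresp_plus_ap <- function(params = default_params(),
                                         e_gaba = -52,
                                         g_per_source =
                                           params$gaba$gmax_per_source_ns,
                                         dt_lag = NULL, measure = "bouton_1",
                                         grid = NULL) {
  .paired_modulation(params,
                     function(onset) .gaba_synapses(params, e_gaba, onset,
                                                    g_per_source),
                     measure = measure, dt_lag = dt_lag, grid = grid)
}

#' Paired-pulse test of the Ca2+ channel model
#'
#' Single-compartment clamp: two 1 ms depolarizations to 0 mV separated by
#' `interval_ms`, from a holding potential of -80 mV.  Returns the ratio of
#' the second to the first peak Ca2+ current; the Markov scheme carries no
#' slow state, so the model shows no paired-pulse facilitation.
#'
#' @param params parameter set.
#' @param interval_ms inter-pulse interval, ms.
#' @param subtype `"all"` (sum of the three subtypes) or one of
#'   `"pq"`, `"n"`, `"r"`.
#' @return list: `ratio` (I2/I1), `i1_pa`, `i2_pa`, `overlap` (TRUE when the
#'   interval is shorter than five deactivation time constants, so the
#'   second pulse rides on the tail of the first).
#' @export
paired_pulse_ca_test <- function(params = default_params(), interval_ms = 50,
                                 subtype = "all") {
  lev <- data.frame(v_mv = c(-80, 0, -80, 0, -80),
                    dur_ms = c(10, 1, interval_ms, 1, 5))
  chans <- if (subtype == "all") c("ca_pq", "ca_n", "ca_r")
           else paste0("ca_", subtype)
  i_tot <- NULL
  for (ch in chans) {
    tr <- run_voltage_clamp(ch, lev, params)
    i_tot <- if (is.null(i_tot)) tr$i_pa else i_tot + tr$i_pa
  }
  t <- tr$time_ms
  p1 <- t >= 10 & t < 11 + 0.5
  p2 <- t >= 11 + interval_ms & t < 12 + interval_ms + 0.5
  i1 <- max(-i_tot[p1])
  i2 <- max(-i_tot[p2])
  koff_min <- min(vapply(params$ca$subtypes, function(s) s$koff, numeric(1)))
  list(ratio = i2 / i1, i1_pa = i1, i2_pa = i2,
       overlap = interval_ms < 5 / koff_min)
}

#' Calibrate the dendritic conductance to a target somatic EPSP
#'
#' Root-finds the total glutamatergic conductance so the somatic EPSP peak
#' equals `target_mv` (default 20 mV) in the full active model.
#'
#' @param params parameter set.
#' @param target_mv somatic EPSP peak, mV.
#' @param bracket search interval for the total conductance, nS.
#' @param tol absolute tolerance on the EPSP peak, mV.
#' @return calibrated total conductance, nS.
#' @export
calibrate_epsp_conductance <- function(params = default_params(),
                                       target_mv = 20,
                                       bracket = c(1, 60), tol = 0.05) {
  grid <- .model_grid(params)
  f <- function(g) {
    peak <- tryCatch(
      simulate_epresp(params, gmax_total_ns = g, duration = 40,
                      grid = grid)$soma_peak_mv,
      error = function(e) 80)   # spiking counts as far above target
    peak - target_mv
  }
  uniroot(f, bracket, tol = tol)$root
}

#' Calibrate the GABA-A source conductance to a target peak-current ratio
#'
#' Root-finds the per-source GABA-A conductance so the conditioned/control
#' peak ratio of the AP-evoked Ca2+ current equals `target_pct` at
#' `e_gaba` (default: the high-chloride depolarizing condition).
#'
#' @param params parameter set.
#' @param target_pct target peak ratio, percent.
#' @param e_gaba GABA-A reversal, mV.
#' @param bracket search interval for the per-source conductance, nS.
#' @return calibrated per-source conductance, nS.
#' @export
calibrate_gaba_conductance <- function(params = default_params(),
                                       target_pct = 51.7, e_gaba = -52,
                                       bracket = c(0.02, 0.09)) {
  grid <- .model_grid(params)
  f <- function(g) {
    tryCatch(
      simulate_gaba_epresp_plus_ap(params, e_gaba = e_gaba, g_per_source = g,
                                   grid = grid)$peak_ratio_pct - target_pct,
      # an ectopically spiking conditioning run marks over-strong input
      error = function(e) -60)
  }
  uniroot(f, bracket, tol = 1e-4)$root
}
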