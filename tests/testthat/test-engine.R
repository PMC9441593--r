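test_that("a single passive compartment charges with tau = Rm*Cm = 60 ms", {
  p <- test_params()
  sg <- sphere_grid(20, p$passive)
  mech <- build_mechanisms(sg, p, active = FALSE, calcium = FALSE)
  cfg <- sim_config(duration = 400, dt = 0.05, v_init = -81,
                    record = "sphere")
  tr <- run_sim(sg, mech, list(inj = data.frame(site = "sphere", pos = 0.5,
                                                onset = 0, dur = 400,
                                                amp_na = 0.01)), cfg)
  f <- fit_single_exponential(tr$time_ms, tr$v_sphere, window = c(0.5, 400),
                              with_offset = TRUE)
  expect_true(f$ok)
  expect_lt(abs(f$tau / 60 - 1), 0.01)
  # steady-state depolarization equals I * Rm / area
  expect_equal(f$offset + 81, 0.01 / mech$g_leak_us, tolerance = 1e-4)
})

test_that("the resting model is stable for 500 ms at every compartment", {
  p <- test_params()
  grid <- test_grid()
  mech <- build_mechanisms(grid, p)
  cfg <- sim_config(duration = 500, dt = 0.05, v_init = -80, record = "soma")
  tr <- run_sim(grid, mech, list(), cfg)
  expect_lt(max(abs(attr(tr, "v_final") + 80)), 2)
})

test_that("somatic stimulation evokes an AP at every bouton", {
  p <- test_params()
  grid <- test_grid()
  mech <- build_mechanisms(grid, p)
  boutons <- paste0("bouton_", 1:10)
  cfg <- sim_config(duration = 20, dt = p$sim$dt_ms, v_init = -80,
                    record = boutons, settle_ms = 300)
  tr <- run_sim(grid, mech,
                list(inj = data.frame(site = "soma", pos = 0.5, onset = 5,
                                      dur = 2, amp_na = 0.2)), cfg)
  peaks <- vapply(boutons, function(b) max(tr[[paste0("v_", b)]]), numeric(1))
  expect_true(all(peaks > 0))
})

test_that("clamp traces match a high-accuracy segment-wise ODE oracle", {
  p <- test_params()
  area <- pi * 10^2 * 1e-8
  gna <- p$na$gbar_axon_ms_cm2 * area * 1e3
  segs <- data.frame(v = c(-80, -120, -40), t0 = c(0, 10, 40),
                     t1 = c(10, 40, 60))
  y <- c(gate_dynamics(p$na$m, -80)$inf, gate_dynamics(p$na$h, -80)$inf)
  tt <- c(); mm <- c(); hh <- c(); vv <- c()
  for (i in seq_len(nrow(segs))) {
    v <- segs$v[i]
    gm <- gate_dynamics(p$na$m, v)
    gh <- gate_dynamics(p$na$h, v)
    rhs <- function(t, y, parms) {
      list(c((gm$inf - y[1]) / gm$tau, (gh$inf - y[2]) / gh$tau))
    }
    times <- seq(segs$t0[i], segs$t1[i], by = 0.005)
    sol <- deSolve::ode(y, times, rhs, NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    keep <- if (i == 1) seq_len(nrow(sol)) else 2:nrow(sol)
    tt <- c(tt, sol[keep, 1]); mm <- c(mm, sol[keep, 2])
    hh <- c(hh, sol[keep, 3]); vv <- c(vv, rep(v, length(keep)))
    y <- sol[nrow(sol), 2:3]
  }
  i_oracle <- gna * mm^3 * hh * (vv - p$na$e_rev_mv) * 1e3
  tr <- run_voltage_clamp("na", data.frame(v_mv = c(-80, -120, -40),
                                           dur_ms = c(10, 30, 20)), p)
  err <- max(abs(tr$i_pa - i_oracle)) / max(abs(i_oracle))
  expect_lt(err, 0.005)
})

test_that("the implicit solve is converged and occupancies are conserved", {
  tr <- epresp_pair()$control$traces
  expect_lt(attr(tr, "resid_max"), 1e-8)
  expect_lt(attr(tr, "occ_err_max"), 1e-10)
  occ <- attr(tr, "occ")
  expect_true(all(occ >= 0))
  sums <- occ[, 1:6] + 0  # per-subtype blocks each sum to 1
  for (s in 0:2) {
    expect_equal(rowSums(occ[, s * 6 + 1:6]), rep(1, nrow(occ)),
                 tolerance = 1e-9)
  }
})

test_that("membrane current audit residual shrinks under step refinement", {
  p <- test_params()
  sg <- sphere_grid(10, p$passive)
  mech <- build_mechanisms(sg, p, active = FALSE, calcium = FALSE)
  resid_at <- function(dt) {
    cfg <- sim_config(duration = 20, dt = dt, v_init = -81, record = "sphere")
    tr <- run_sim(sg, mech, list(inj = data.frame(site = "sphere", pos = 0.5,
                                                  onset = 5, dur = 10,
                                                  amp_na = 0.02)), cfg)
    sel <- tr$time_ms > 6 & tr$time_ms < 14   # away from the discontinuities
    r <- membrane_current_audit(tr$time_ms, tr$v_sphere, mech$cm_nf,
                                mech$g_leak_us, mech$e_leak,
                                i_inj = ifelse(tr$time_ms >= 5 &
                                               tr$time_ms < 15, 0.02, 0))
    n <- length(tr$time_ms)
    max(abs(r[sel[2:(n - 1)]]))
  }
  r1 <- resid_at(0.1)
  r2 <- resid_at(0.05)
  expect_lt(r2, r1)
  # zero input, zero channels: residual is exactly zero at rest
  cfg <- sim_config(duration = 5, dt = 0.05, v_init = -81, record = "sphere")
  tr0 <- run_sim(sg, mech, list(), cfg)
  r0 <- membrane_current_audit(tr0$time_ms, tr0$v_sphere, mech$cm_nf,
                               mech$g_leak_us, mech$e_leak)
  expect_lt(max(abs(r0)), 1e-12)
})

test_that("steady-state initialization matches the definitions", {
  p <- test_params()
  ss <- steady_state(p, -80)
  gd <- gate_dynamics(p$na$m, -80)
  expect_equal(unname(ss$gates[["m"]]), gd$alpha / (gd$alpha + gd$beta),
               tolerance = 1e-12)
  for (s in c("pq", "n", "r")) {
    pi0 <- markov_stationary(p$ca$subtypes[[s]], -80)
    q <- markov_generator(p$ca$subtypes[[s]], -80)
    # stationary vector lies in the null space of the transposed generator
    expect_lt(max(abs(as.numeric(t(q) %*% pi0))), 1e-8)
    expect_equal(unname(ss$occ[, s]), unname(pi0), tolerance = 1e-12)
  }
})

test_that("halving the time step changes AP and Ca2+ current marginally", {
  a <- ap_ca_run(dt = 0.05)
  b <- ap_ca_run(dt = 0.025)
  expect_lt(abs(a$ap_peak_mv - b$ap_peak_mv), 1)
  expect_lt(abs(a$metrics$peak_pa / b$metrics$peak_pa - 1), 0.02)
})

test_that("voltage clamp decouples the clamped compartment from the cable", {
  p <- test_params()
  lev <- data.frame(v_mv = c(-80, 0, -80), dur_ms = c(5, 5, 5))
  one <- run_voltage_clamp("ca_pq", lev, p, dt = 0.01)
  # same channel clamped inside a two-compartment cable: identical current
  sg <- sphere_grid(10, p$passive)
  mech <- build_mechanisms(sg, p, active = FALSE, calcium = FALSE)
  area <- sg$comp$area_cm2
  pa <- matrix(0, 1, 3)
  pa[1, 1] <- p$ca$subtypes$pq$pbar_cm_s * area
  nstep <- as.integer(15 / 0.01)
  edges <- c(5, 10, 15)
  tgrid <- (0:nstep) * 0.01
  seg <- pmin(findInterval(tgrid, c(0, edges), left.open = TRUE,
                           rightmost.closed = TRUE), 3)
  seg[1] <- 1
  cmd <- c(-80, 0, -80)[seg]
  out <- mfaxon:::engine_run_cpp(
    parent = c(-1L, 0L), ga_us = c(0, 0.01),
    cm_nf = rep(mech$cm_nf, 2),
    g_leak_us = rep(mech$g_leak_us, 2), e_leak = mech$e_leak,
    g_na_us = c(0, 0), e_na = 50, g_k_us = c(0, 0), e_k = -85,
    gates = mech$gates,
    ca_comp = 0L, ca_pa = pa, ca_rates = mech$ca_rates,
    cao = mech$cao, cai = mech$cai, temp = mech$temp,
    inj = matrix(0, 0, 4), syn = matrix(0, 0, 6),
    dt = 0.01, nstep = nstep, v_init = -80, theta = 0.5,
    clamped = c(TRUE, FALSE), clamp_v = cmd,
    rec_idx = 0L, rec_ca_rows = 0L, settle_steps = 0L)
  i_two <- out$ica[[1]][, 4] * 1e3
  expect_identical(one$i_pa, i_two)
})
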