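test_that("gate steady states and rates behave over the physiological range", {
  p <- test_params()
  v <- seq(-120, 70, by = 1)
  for (g in list(p$na$m, p$na$h, p$k$n, p$k$hk)) {
    d <- gate_dynamics(g, v)
    expect_true(all(d$inf >= 0 & d$inf <= 1))
    expect_true(all(d$tau > 0))
    expect_true(all(d$alpha >= 0) && all(d$beta >= 0))
    # HH identity for the (inf, tau) parameterization
    expect_equal(1 / (d$alpha + d$beta), d$tau, tolerance = 1e-12)
    expect_equal(d$alpha / (d$alpha + d$beta), d$inf, tolerance = 1e-12)
  }
  h <- gate_dynamics(p$na$h, v)
  expect_true(all(diff(h$inf) < 0))     # inactivation monotone decreasing
  m <- gate_dynamics(p$na$m, v)
  expect_true(all(diff(m$inf) > 0))
})

test_that("the six-state generator is a conservative adjacent-only chain", {
  p <- test_params()
  for (s in p$ca$subtypes) {
    for (v in c(-120, -80, -40, 0, 40, 70)) {
      q <- markov_generator(s, v)
      expect_equal(unname(rowSums(q)), rep(0, 6), tolerance = 1e-13)
      off <- q; diag(off) <- 0
      expect_true(all(off >= 0))
      # only nearest-neighbour transitions
      idx <- which(off != 0, arr.ind = TRUE)
      expect_true(all(abs(idx[, 1] - idx[, 2]) == 1))
    }
  }
})

test_that("stationary occupancy concentrates in C0 at -120 mV", {
  p <- test_params()
  for (s in p$ca$subtypes) {
    pi0 <- markov_stationary(s, -120)
    expect_gt(pi0[["C0"]], 0.99)
    expect_equal(sum(pi0), 1, tolerance = 1e-12)
  }
})

test_that("stationary distribution matches long-run clamp occupancies", {
  p <- test_params()
  lev <- data.frame(v_mv = -30, dur_ms = 400)
  tr <- run_voltage_clamp("ca_pq", lev, p, dt = 0.01)
  occ <- attr(tr, "occ")
  pi0 <- markov_stationary(p$ca$subtypes$pq, -30)
  expect_equal(unname(occ[nrow(occ), 1:6]), unname(pi0), tolerance = 1e-6)
})

test_that("GHK and ohmic current conventions are respected", {
  p <- test_params()
  # inward (negative) at -80 with cao >> cai; reversal far positive
  expect_lt(ghk_flux(-80, 1e-4), 0)
  expect_lt(ghk_flux(40, 1e-4), 0)
  expect_lt(abs(ghk_flux(40, 1e-4)), abs(ghk_flux(-80, 1e-4)))
  # ohmic channel at its reversal carries no current
  expect_equal(channel_current_density(-85, 0.5, gbar_ms_cm2 = 36,
                                       e_rev = -85), 0)
  # fully closed calcium channel carries no current
  expect_equal(channel_current_density(-80, 0, perm_cm_s = 1e-5), 0)
})

test_that("chloride Nernst potential reproduces the reported anchors", {
  expect_equal(nernst_chloride(154, 154), 0)
  # doubling both concentrations leaves E unchanged
  expect_equal(nernst_chloride(12), nernst_chloride(24, 308))
  expect_lt(abs(nernst_chloride(12) - (-65)), 2)
  expect_lt(abs(nernst_chloride(7) - (-78)), 2)
  expect_lt(abs(nernst_chloride(21) - (-52)), 2)
  expect_error(nernst_chloride(-1), "domain error")
})

test_that("synaptic conductance waveform is causal and normalized", {
  t <- seq(0, 60, by = 0.01)
  g <- synaptic_conductance(t, gmax = 2, tau_rise = 2, tau_decay = 30,
                            onset = 5)
  expect_true(all(g[t < 5] == 0))
  expect_equal(max(g), 2, tolerance = 1e-6)  # sampled on a 10 us grid
  tp <- syn_time_to_peak(2, 30)
  expect_equal(t[which.max(g)] - 5, tp, tolerance = 0.02)
  expect_error(synaptic_conductance(t, 1, tau_rise = 3, tau_decay = 2),
               "configuration error")
})

test_that("calibrated Ca2+ subtype I-V relationships are bell shaped", {
  for (ch in c("ca_pq", "ca_n", "ca_r")) {
    tab <- channel_table(ch)
    iv <- iv_table(tab)
    vmin <- attr(iv, "v_at_peak_inward")
    expect_gt(vmin, -70)             # interior maximum of |I|
    expect_lt(vmin, 40)
    k <- which(tab$v_test == vmin)
    expect_true(all(diff(tab$i_peak_pa[1:k]) < 0))
    expect_true(all(diff(tab$i_peak_pa[k:nrow(tab)]) > 0))
  }
})
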