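test_that("EPreSP peaks decay monotonically and arrive progressively later", {
  r <- epresp_run()
  expect_true(all(diff(r$peaks$peak_mv) < 0))
  expect_true(all(diff(r$peaks$t_peak_ms) > 0))
  expect_true(r$fit$ok)
  expect_gt(r$fit$r2, 0.97)
  expect_lt(abs(r$soma_peak_mv - 20), 0.5)
})

test_that("zero synaptic conductance leaves the axon at rest", {
  p <- test_params()
  r0 <- simulate_epresp(p, gmax_total_ns = 0, duration = 40,
                        grid = test_grid())
  expect_lt(max(abs(r0$peaks$peak_mv)), 0.05)
})

test_that("clearly suprathreshold dendritic input is rejected", {
  p <- test_params()
  expect_error(simulate_epresp(p, gmax_total_ns = 1000, duration = 60,
                               grid = test_grid()),
               "suprathreshold")
})

test_that("AP-evoked Ca2+ current scales linearly with channel density", {
  a <- ap_ca_run()
  d2 <- ap_ca_run(ca_scale = 2)
  expect_gt(a$ap_peak_mv, 0)
  expect_lt(abs(d2$metrics$peak_pa / a$metrics$peak_pa - 2), 0.02)
  expect_lt(abs(d2$metrics$charge_fc / a$metrics$charge_fc - 2), 0.02)
  expect_lt(abs(d2$ap_peak_mv - a$ap_peak_mv), 0.1)
})

test_that("R-type current decays more slowly than P/Q during the same AP", {
  tr <- ap_ca_run()$traces
  t <- tr$time_ms
  after <- function(i) {
    pk <- which.min(i)
    sel <- pk:length(i)
    # time to fall to 10% of peak
    t[sel][which(abs(i[sel]) <= 0.1 * abs(i[pk]))[1]] - t[pk]
  }
  expect_gt(after(tr$ica_r_bouton_1), after(tr$ica_pq_bouton_1))
})

test_that("a preceding EPreSP lowers the AP peak and the Ca2+ current", {
  r <- epresp_pair()
  expect_lt(r$ap_peak_cond_mv, r$ap_peak_control_mv)
  expect_lt(r$peak_ratio_pct, 100)
  expect_lt(r$charge_ratio_pct, 100)
  # subthreshold EPreSP alone drives a small but nonzero Ca2+ current
  expect_gt(r$subthreshold_ica$peak_pa, 0)
  expect_lt(r$subthreshold_ica$peak_pa, 0.01 * r$control$metrics$peak_pa)
})

test_that("modulation ratios are invariant to Ca2+ density rescaling", {
  p <- test_params()
  r1 <- epresp_pair()
  for (s in c("pq", "n", "r")) {
    p$ca$subtypes[[s]]$pbar_cm_s <- 2 * p$ca$subtypes[[s]]$pbar_cm_s
  }
  r2 <- simulate_epresp_plus_ap(p, grid = test_grid())
  expect_lt(abs(r2$peak_ratio_pct / r1$peak_ratio_pct - 1), 0.005)
  expect_lt(abs(r2$charge_ratio_pct / r1$charge_ratio_pct - 1), 0.005)
})

test_that("null conditioning input leaves the Ca2+ current unchanged", {
  p <- test_params()
  r <- simulate_epresp_plus_ap(p, gmax_total_ns = 0, grid = test_grid())
  expect_equal(r$peak_ratio_pct, 100, tolerance = 1e-6)
  expect_equal(r$charge_ratio_pct, 100, tolerance = 1e-6)
  g0 <- simulate_gaba_epresp_plus_ap(p, g_per_source = 0, grid = test_grid())
  expect_equal(g0$peak_ratio_pct, 100, tolerance = 1e-6)
})

test_that("shunt-only GABA suppresses less than the depolarizing condition", {
  p <- test_params()
  dep <- gaba_pair()
  sh <- simulate_gaba_epresp_plus_ap(p, e_gaba = -78, grid = test_grid())
  expect_lt(sh$peak_ratio_pct, 100)
  expect_lt(dep$peak_ratio_pct, sh$peak_ratio_pct)
  # depolarizing GABA-EPreSP visible at the first bouton
  v <- dep$solo_traces$v_bouton_1
  expect_gt(max(v) - v[1], 1)
})

test_that("paired-pulse clamp shows no facilitation and full slow recovery", {
  p <- test_params()
  pp <- paired_pulse_ca_test(p, interval_ms = 50)
  expect_gt(pp$ratio, 0.95)
  expect_lt(pp$ratio, 1.05)
  expect_false(pp$overlap)
  slow <- paired_pulse_ca_test(p, interval_ms = 500)
  expect_equal(slow$ratio, 1, tolerance = 1e-3)
  fast <- paired_pulse_ca_test(p, interval_ms = 1)
  expect_true(is.finite(fast$ratio))
  expect_true(fast$overlap)
})

test_that("channel characterization flags unfittable sweeps instead of failing", {
  tab <- channel_table("na")
  expect_true(is.na(tab$tau_act_ms[tab$v_test == -70]))
  expect_false(anyNA(subset(tab, v_test >= -40 & v_test <= 40)$tau_act_ms))
})
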