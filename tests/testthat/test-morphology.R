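test_that("granule cell tree has the specified composition", {
  m <- build_granule_cell()
  k <- table(m$sections$kind)
  expect_equal(unname(k[["soma"]]), 1)
  expect_equal(unname(k[["dendrite_trunk"]]), 1)
  expect_equal(unname(k[["dendrite_primary"]]), 3)
  expect_equal(unname(k[["dendrite_secondary"]]), 9)
  expect_equal(unname(k[["axon"]]), 10)
  expect_equal(unname(k[["bouton"]]), 10)
  expect_equal(unname(k[["filopodium"]]), 40)
  expect_equal(unname(k[["collateral"]]), 3)
  expect_equal(unname(k[["collateral_bouton"]]), 3)
  # only the first axonal cylinder tapers
  ax1 <- subset(m$sections, id == "axon_1")
  expect_equal(ax1$diam_prox, 1)
  expect_equal(ax1$diam_dist, 0.4)
  tapered <- with(m$sections, sum(diam_prox != diam_dist))
  expect_equal(tapered, 1L)
})

test_that("collaterals originate 50, 100 and 200 um down the axon", {
  m <- build_granule_cell()
  # distance from the soma midpoint to each collateral origin =
  # soma half-length + arc distance along the axon
  orig <- vapply(1:3, function(i) {
    path_distance(m, "soma", list(id = paste0("collateral_", i), pos = 0))
  }, numeric(1))
  expect_equal(orig, 7.5 + c(50, 100, 200))
})

test_that("degenerate counts and invalid dimensions are handled", {
  g <- default_params()$geometry
  g$collateral$origins_um <- list()
  m <- build_granule_cell(g)
  expect_false(any(m$sections$kind == "collateral"))
  g2 <- default_params()$geometry
  g2$soma$diam <- -1
  expect_error(build_granule_cell(g2), "configuration error")
  g3 <- default_params()$geometry
  g3$collateral$origins_um <- c(50, 5000)
  expect_error(build_granule_cell(g3), "beyond the axon")
})

test_that("path distances are symmetric, zero on identity, and additive", {
  m <- build_granule_cell()
  expect_equal(path_distance(m, "soma", "soma"), 0)
  # soma center to bouton-1 midpoint: soma radius + cylinder + bouton radius
  expect_equal(path_distance(m, "soma", "bouton_1"), 7.5 + 150 + 3.5)
  pairs <- list(c("soma", "bouton_10"), c("dend_secondary_3", "bouton_2"),
                c("filo_4_2", "collateral_bouton_1"))
  for (pr in pairs) {
    expect_equal(path_distance(m, pr[1], pr[2]), path_distance(m, pr[2], pr[1]))
  }
  # inter-bouton spacing equals cylinder + bouton length
  d12 <- path_distance(m, "bouton_1", "bouton_2")
  expect_equal(d12, 150 + 7)
  expect_error(path_distance(m, "soma", "nonexistent"), "lookup error")
})

test_that("discretization produces the documented segment counts and areas", {
  cyl <- cylinder_morphology(0.4, 150)
  g <- discretize(cyl, discretization_rule(5))
  # odd-segment rule: ceiling(150/5) = 30 -> 31 segments
  expect_equal(nrow(g$comp), 31L)
  # single-compartment sphere area (cylinder with L = d)
  sg <- sphere_grid(10)
  expect_equal(nrow(sg$comp), 1L)
  expect_equal(sg$comp$area_cm2 * 1e8, pi * 10^2)
})

test_that("total membrane area is invariant under re-discretization", {
  m <- build_granule_cell()
  a1 <- sum(discretize(m, discretization_rule(10))$comp$area_cm2)
  a2 <- sum(discretize(m, discretization_rule(3))$comp$area_cm2)
  analytic <- sum(mfaxon:::section_area_um2(m$sections)) * 1e-8
  expect_lt(abs(a1 / a2 - 1), 1e-3)
  expect_lt(abs(a1 / analytic - 1), 1e-3)
})

test_that("passive cable matches the analytic steady-state solution", {
  p <- default_params()
  pv <- p$passive
  L <- 1000; d <- 0.4
  m <- cylinder_morphology(d, L, pv)
  g <- discretize(m, discretization_rule(2))
  mech <- build_mechanisms(g, p, active = FALSE, calcium = FALSE)
  mech$e_leak <- -80
  n <- nrow(g$comp)
  cfg <- sim_config(duration = 600, dt = 0.5, v_init = -80,
                    record = "cable")
  proto <- list(inj = data.frame(site = "cable", pos = 0.002, onset = 0,
                                 dur = 600, amp_na = 0.01))
  tr <- run_sim(g, mech, proto, cfg)
  v <- attr(tr, "v_final") + 80
  # lambda = sqrt(Rm * d / (4 Ri)), lengths in cm
  lam_cm <- sqrt(pv$rm_kohm_cm2 * 1e3 * (d * 1e-4) / (4 * pv$ri_ohm_cm))
  lam <- lam_cm * 1e4
  x <- g$comp$xc - g$comp$xc[1]
  pred <- cosh((L - x) / lam) / cosh(L / lam)   # sealed distal end
  expect_lt(max(abs(v / v[1] - pred)), 0.02)
  # input resistance of the sealed finite cable: R = r_i * lambda * coth(L/lambda)
  ri_per_cm <- 4 * pv$ri_ohm_cm / (pi * (d * 1e-4)^2)
  r_in <- ri_per_cm * lam_cm / tanh(L / lam) * 1e-6  # MOhm
  r_sim <- v[1] / 0.01                               # mV/nA = MOhm
  expect_lt(abs(r_sim / r_in - 1), 0.02)
})

test_that("somatic input resistance converges under grid refinement", {
  p <- default_params()
  m <- build_granule_cell(p$geometry, p$passive)
  rin <- function(max_seg) {
    g <- discretize(m, discretization_rule(max_seg))
    mech <- build_mechanisms(g, p, active = FALSE, calcium = FALSE)
    cfg <- sim_config(duration = 400, dt = 0.5, v_init = -81, record = "soma")
    tr <- run_sim(g, mech, list(inj = data.frame(site = "soma", pos = 0.5,
                                                 onset = 0, dur = 400,
                                                 amp_na = 0.005)), cfg)
    (tr$v_soma[nrow(tr)] + 81) / 0.005
  }
  expect_lt(abs(rin(10) / rin(5) - 1), 0.01)
})
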