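test_that("Hill index and rate scale match the closed forms", {
  expect_equal(hill_coefficient(50), 2.600, tolerance = 1e-4)
  expect_equal(hill_coefficient(75), 2.589, tolerance = 1e-4)
  expect_equal(hill_coefficient(25), 2.591, tolerance = 1e-3)
  expect_equal(kc_rate(0), 6.325)
  expect_equal(kc_rate(50), 6.325 * exp(2.88697 * 0.011537 * 50))
  expect_equal(kc_rate(50), 33.4, tolerance = 0.002)
  expect_equal(kc_rate(100), 176.8, tolerance = 0.001)
  # monotone increasing
  s <- seq(0, 100, by = 5)
  expect_true(all(diff(kc_rate(s)) > 0))
})

test_that("equilibrium saturation: half point, endpoints, sigmoid shape", {
  p <- rcm_params()
  expect_equal(hb_equilibrium_saturation(p$P50, p), 50, tolerance = 1e-5)
  expect_equal(hb_equilibrium_saturation(0, p), 0)
  expect_equal(hb_equilibrium_saturation(56, p), 74.9, tolerance = 0.005)
  crv <- hb_curve(p, po2 = seq(0, 120, by = 1))
  expect_true(all(diff(crv$saturation_pct) >= 0))
  # half-saturation within 0.5 mmHg of P50
  half <- stats::approx(crv$saturation_pct, crv$po2_mmHg, xout = 50)$y
  expect_lt(abs(half - p$P50), 0.5)
  # sigmoid: steeper around P50 than at the tails
  slope <- diff(crv$saturation_pct)
  expect_gt(slope[37], slope[5])
  expect_gt(slope[37], slope[110])
})

test_that("association and dissociation balance at the fixed point", {
  p <- rcm_params()
  r <- rcmo2:::hb_pct_rates(50, p$P50, p)
  expect_equal(r$jdiss_pct, r$jasso_pct)
  hs <- hb_step(50, p$P50, hb_content(p), p)
  expect_equal(hs$sat, 50, tolerance = 1e-6)
  expect_equal(hs$dq, 0, tolerance = 1e-6)
  # no bound oxygen and no driving pressure: nothing moves
  hs0 <- hb_step(0, 0, hb_content(p), p)
  expect_equal(hs0$sat, 0)
  expect_equal(hs0$dq, 0)
})

test_that("hb_step conserves dissolved + bound oxygen exactly", {
  p <- rcm_params()
  hbt <- hb_content(p)
  sat <- c(20, 50, 74.8, 95)
  po2 <- c(56, 10, 56, 30)
  q <- po2 * p$alpha
  hs <- hb_step(sat, po2, hbt, p)
  T0 <- q + 4 * 0.01 * hbt * sat
  T1 <- (q + hs$dq) + 4 * 0.01 * hbt * hs$sat
  expect_equal(T1, T0, tolerance = 1e-12)
})

test_that("saturation relaxes monotonically to equilibrium at fixed PO2", {
  p <- rcm_params()
  eq <- hb_equilibrium_saturation(56, p)
  up <- hb_relax(20, 56, p, n_ticks = 400)
  dn <- hb_relax(95, 56, p, n_ticks = 400)
  expect_true(all(diff(up) >= -1e-9))
  expect_true(all(diff(dn) <= 1e-9))
  expect_equal(tail(up, 1), eq, tolerance = 0.5)
  expect_equal(tail(dn, 1), eq, tolerance = 0.5)
})

test_that("compatibility flags change the kinetics as documented", {
  p_lit <- rcm_params(hb_literal_asso = TRUE)
  # the printed form drives association with the saturated fraction: at
  # S = 60 it is 60/40 of the unsaturated-fraction association
  r_lit <- rcmo2:::hb_pct_rates(60, 56, p_lit)
  r_def <- rcmo2:::hb_pct_rates(60, 56, rcm_params())
  expect_equal(r_lit$jasso_pct, r_def$jasso_pct * 60 / 40)
  expect_equal(r_lit$jdiss_pct, r_def$jdiss_pct)
  p_mono <- rcm_params(hb_monomer = TRUE)
  hs4 <- hb_step(70, 30, 2340, rcm_params())
  hs1 <- hb_step(70, 30, 2340, p_mono)
  # same direction, four-fold smaller oxygen displacement per % in the
  # monomer reading
  expect_equal(sign(hs1$dq), sign(hs4$dq))
  expect_lt(abs(hs1$dq), abs(hs4$dq))
})
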