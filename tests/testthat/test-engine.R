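# Engine tests share a few moderately expensive runs, built once here.
eng_sim <- run_to_steady_state(rcm_sim(ref_params, ref_grid))

test_that("an empty, unfed, non-consuming tissue stays empty", {
  p0 <- rcm_params(RBF = 0, PTC_feed = 0, LUM_feed = 0, JmaxHK_epi = 0,
                   Jmax_cap_specific = 0, Jmax_int = 0, frPR = 0)
  g <- build_tissue("1540", p0)
  sim <- rcm_sim(p0, g)
  sim$sat[] <- 0
  sim <- step_ticks(sim, 50)
  expect_equal(sim$q, numeric(length(g$type)))
  expect_equal(max(abs(sim$sat)), 0)
})

test_that("capillaries equilibrate to their feed within milliseconds", {
  sim <- rcm_sim(ref_params, ref_grid)
  sim <- step_ticks(sim, 10, sample_every = 1)
  m <- sim$monitor
  # PTC mean climbs to within a few mmHg of its feed in ~5 ms
  expect_gt(m$PTC_PO2[m$time_ms == 5], 50)
  expect_gt(mean_po2(eng_sim, "PTC"), ref_params$PTC_feed - 2)
})

test_that("compartments equilibrate in the expected order from all-zero", {
  sim <- step_ticks(rcm_sim(ref_params, ref_grid), 1200, sample_every = 1)
  m <- sim$monitor
  rise50 <- function(col) {
    y <- m[[col]]
    m$time_ms[which(y >= tail(y, 1) / 2)[1]]
  }
  t_ptc <- rise50("PTC_PO2"); t_lum <- rise50("LUM_PO2")
  t_epi <- rise50("EPI_PO2"); t_int <- rise50("INT_PO2")
  expect_lt(t_ptc, 5)
  expect_lt(t_ptc, t_lum)
  expect_lte(t_lum, t_epi)
  expect_lt(t_epi, t_int)
  # the interstitium is the last compartment to stabilize
  expect_gt(t_int, 2 * t_lum)
})

test_that("identical inputs give bit-identical trajectories", {
  s1 <- step_ticks(rcm_sim(ref_params, ref_grid), 200)
  s2 <- step_ticks(rcm_sim(ref_params, ref_grid), 200)
  expect_identical(s1$monitor, s2$monitor)
  expect_identical(s1$q, s2$q)
  expect_identical(s1$sat, s2$sat)
})

test_that("per-tick oxygen budget closes to 1e-9 relative", {
  sim <- step_ticks(rcm_sim(ref_params, ref_grid), 300)
  hbt <- sim$hbt
  for (k in 1:20) {
    T0 <- sum(sim$q) + 4 * 0.01 * hbt * sum(sim$sat)
    sim <- step_ticks(sim, 1, track_budget = TRUE)
    T1 <- sum(sim$q) + 4 * 0.01 * hbt * sum(sim$sat)
    rel <- abs((T1 - T0) - (sim$budget$conv_net_amol -
                            sim$budget$consumed_amol)) / T1
    expect_lt(rel, 1e-9)
  }
})

test_that("divergence and invalid states abort with context", {
  sim <- rcm_sim(ref_params, ref_grid, clamp = 5L, clamp_po2 = 250)
  expect_error(run_to_steady_state(sim), "divergence")
  sim2 <- rcm_sim(ref_params, ref_grid)
  sim2$q[3] <- NA_real_
  expect_error(step_ticks(sim2, 1), "patch")
})

test_that("patch clamping holds the requested PO2", {
  sim <- rcm_sim(ref_params, ref_grid, clamp = c(10L, 11L), clamp_po2 = 90)
  sim <- step_ticks(sim, 100)
  po2 <- sim$q * 1000 / (ref_params$alpha * sim$grid$volume)
  expect_equal(po2[10], 90)
  expect_equal(po2[11], 90)
})

test_that("anoxemia washes oxygen out within tens of milliseconds", {
  ps <- rcm_params("rcmstar")
  g <- build_tissue("1540", ps)
  tr <- run_transient(ps, g, rcm_protocol("anoxemia"), horizon_ms = 600)
  expect_lt(tr$t50_ms[["tissue"]], 100)
  expect_gt(tr$t50_ms[["tissue"]], 5)
  expect_lt(tr$t50_ms[["PTC"]], tr$t50_ms[["tissue"]])
})

test_that("half-time extraction interpolates and reports non-crossings", {
  t <- c(0, 10, 20, 30)
  expect_equal(rcmo2:::.crossing_time(t, c(40, 30, 15, 10), 0.5), 10 + 10 * 10 / 15)
  expect_equal(rcmo2:::.crossing_time(t, c(40, 38, 36, 35), 0.5), Inf)
  expect_true(is.na(rcmo2:::.crossing_time(t, c(0, 0, 0, 0), 0.5)))
})

test_that("swapping the hemoglobin and consumption operators is benign", {
  # near-commuting operators: the steady state moves by well under a mmHg
  # at half-millisecond ticks
  p05 <- rcm_params(tick = 0.5)
  g05 <- build_tissue("1540", p05)
  a <- run_to_steady_state(rcm_sim(p05, g05), max_ticks = 20000)
  b <- run_to_steady_state(rcm_sim(p05, g05,
         order = c("conv", "cons", "diff", "hb")), max_ticks = 20000)
  expect_lt(abs(a$sst_po2 - b$sst_po2), 0.1)
})
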