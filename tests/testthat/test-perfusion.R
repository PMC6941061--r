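test_that("flow cascade reproduces the hand-computed reference values", {
  f <- compute_flow_cascade(ref_params)
  expect_equal(f$CBF, 4.77)
  expect_equal(f$OpNe, 27000)
  expect_equal(f$SNGBF, 176.7, tolerance = 1e-3)
  expect_equal(f$SNGFR, 33.0, tolerance = 2e-3)
  expect_equal(f$SNAPR, 0.51 * f$SNGFR)
  expect_equal(f$TVF, f$SNGFR - 0.5 * f$SNAPR)
  expect_equal(f$wkGFR, f$SNGFR * 27000 * 1e-6)
  # hand arithmetic with SNGFR = 33 exactly
  expect_equal(0.51 * 33, 16.83)
  expect_equal(33 - 0.5 * 16.83, 24.585)
})

test_that("zero flow zeroes the whole cascade", {
  f <- compute_flow_cascade(ref_params, rbf = 0)
  for (k in c("CBF", "SNGBF", "SNEABF", "SNGFR", "SNAPR", "CVF", "TVF",
              "SNFLNa", "wkGFR"))
    expect_equal(f[[k]], 0)
})

test_that("cascade mass balance holds exactly", {
  for (rbf in c(0.2, 1, 5.3, 10)) {
    f <- compute_flow_cascade(ref_params, rbf = rbf)
    expect_equal(f$SNEABF + f$SNGFR, f$SNGBF)
    # both halves of reabsorbed fluid accounted once
    expect_equal(ref_params$fCapBr * f$CVF + f$TVF, f$SNEABF + f$SNGFR)
  }
})

test_that("every flow quantity is homogeneous of degree 1 in RBF", {
  f1 <- compute_flow_cascade(ref_params, rbf = 2)
  f3 <- compute_flow_cascade(ref_params, rbf = 6)
  for (k in c("CBF", "SNGBF", "SNEABF", "SNGFR", "SNAPR", "CVF", "TVF",
              "SNFLNa", "wkGFR"))
    expect_equal(f3[[k]], 3 * f1[[k]], tolerance = 1e-12)
})

test_that("per-patch sodium transport follows the section scaling", {
  f <- compute_flow_cascade(ref_params)
  tna40 <- sodium_transport_per_patch(f, ref_params, ref_grid)
  expect_equal(tna40, 1.915e5, tolerance = 0.005)
  g50 <- build_tissue("1550", ref_params)
  tna50 <- sodium_transport_per_patch(f, ref_params, g50)
  expect_equal(tna50 / tna40, 12 / 16)
  p0 <- rcm_params(frPR = 0)
  expect_equal(sodium_transport_per_patch(compute_flow_cascade(p0), p0,
                                          ref_grid), 0)
})

test_that("convective flow factors convert nL/min per patch volume", {
  ff <- flow_factors(make_flows(CVF = 24, TVF = 24.6), ref_params, ref_grid)
  expect_equal(ff$CFF, 0.40)               # residence time 2.5 ms
  expect_equal(ff$TFF, 24.6 / (4 * 0.06 * 1000))
  ff0 <- flow_factors(make_flows(CVF = 0, TVF = 0), ref_params, ref_grid)
  expect_equal(ff0$CFF, 0)
  expect_equal(ff0$TFF, 0)
  # a tick too long for the flow must error, naming the remedy
  p20 <- rcm_params(tick = 20)
  expect_error(flow_factors(make_flows(CVF = 24, TVF = 24.6), p20, ref_grid),
               "tick")
})

test_that("apparent capillary velocity matches the cross-section formula", {
  expect_equal(apparent_capillary_velocity(make_flows(CVF = 23), ref_params),
               23 * (1e6 / 6e4) / (pi * 25), tolerance = 1e-12)
  expect_equal(apparent_capillary_velocity(make_flows(CVF = 23), ref_params),
               4.88, tolerance = 0.002)
  p25 <- rcm_params(capFactor = 0.25)
  expect_equal(apparent_capillary_velocity(make_flows(CVF = 23), p25),
               1.22, tolerance = 0.002)
  expect_equal(apparent_capillary_velocity(make_flows(CVF = 0), ref_params), 0)
})
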