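test_that("unidirectional diffusion flow matches the Fick expression", {
  p <- rcm_params()
  g <- make_chain_grid(c("EPI", "EPI"), p)
  op <- diffusion_operator(g, p)
  # source at 75 amol (56 mmHg): flow (1/10) * 1.1 * 800 * 0.075 = 6.6
  q <- c(75, 0)
  q1 <- diffusion_step(q, op)
  expect_equal(q[1] - q1[1], 6.6)
  expect_equal(q1[2], 6.6)
})

test_that("equal concentrations exchange nothing; closed system conserves", {
  p <- rcm_params()
  g <- make_chain_grid(c("EPI", "EPI"), p)
  op <- diffusion_operator(g, p)
  expect_equal(diffusion_step(c(40, 40), op), c(40, 40))
  q <- c(75, 10)
  tot <- sum(q)
  for (k in 1:10000) q <- diffusion_step(q, op)
  expect_equal(sum(q), tot, tolerance = 1e-12)
  expect_equal(q[1], q[2], tolerance = 1e-9)
})

test_that("two-patch relaxation matches the analytic exponential within 1%", {
  p <- rcm_params(tick = 0.1)
  g <- make_chain_grid(c("EPI", "EPI"), p)
  op <- diffusion_operator(g, p)
  kexact <- 2 * 1.1 * 800 / (10 * 1000)   # 2 D S / (L V) per ms
  q <- c(75, 25)
  n <- 50                                  # 5 ms, about one relaxation time
  for (k in seq_len(n)) q <- diffusion_step(q, op)
  delta_num <- q[1] - q[2]
  delta_exact <- (75 - 25) * exp(-kexact * n * p$tick)
  expect_lt(abs(delta_num - delta_exact) / delta_exact, 0.01)
})

test_that("diffusion stability check errors with the admissible tick", {
  p <- rcm_params(tick = 5)
  g <- make_chain_grid(c("LUM", "EPI", "LUM"), p)  # heavy brush-border edges
  expect_error(diffusion_operator(g, p), "maximum admissible tick")
})

test_that("consumption is Michaelis-Menten gated and floors at zero", {
  p <- rcm_params()
  jmax <- c(0.2, 0.2, 0.2)
  cs0 <- consumption_step(c(0, 0, 0), jmax, p)
  expect_equal(cs0$consumed, c(0, 0, 0))
  # [O2] = Km gives half-maximal rate (Km = 1.1 uM -> q = 1.1 amol)
  csk <- consumption_step(c(1.1, 1.1, 1.1), jmax, p)
  expect_equal(csk$consumed, jmax * 0.5 * p$tick, tolerance = 1e-3)
  # demand larger than content consumes exactly the content
  p_hi <- rcm_params()
  cs <- consumption_step(c(0.01, 50, 50), c(10, 0.2, 0.2), p_hi)
  expect_true(all(cs$q >= 0))
  expect_equal(cs$q[1], 0)
  expect_equal(cs$consumed[1], 0.01)
})

test_that("transport-coupled consumption converts sodium flux to oxygen cost", {
  p <- rcm_params()
  f <- compute_flow_cascade(p)
  tna <- sodium_transport_per_patch(f, p, ref_grid)
  cr <- consumption_rates(ref_grid, p, tna)
  epi <- ref_grid$type == "EPI"
  # high-oxygen limit, back to mM-EPI/min: ~10 (vs NaK-pump capacity 396)
  jtna_mm_min <- unique(cr$tna_o2[epi]) * 6e4 / 1000
  expect_equal(jtna_mm_min, 10.0, tolerance = 0.01)
  # housekeeping terms per compartment
  expect_equal(unique(cr$hk[epi]) * 6e4 / 1000, p$JmaxHK_epi)
  expect_equal(unique(cr$hk[ref_grid$type == "INT"]) * 6e4 / 1000, p$Jmax_int)
  expect_equal(unique(cr$hk[ref_grid$type == "PTC"]) * 6e4 / 1000,
               jmax_cap_patch(p))
})

test_that("convective renewal: fixed point, filling rate, ischemia rule", {
  idx <- list(ptc = 1:2, lum = 3:4)
  q <- c(75.04, 75.04, 53.6, 53.6)
  cr <- convective_renewal(q, c(74, 74), idx, 0.4, 0.1, 75.04, 53.6, 74.8)
  expect_equal(cr$q, q)                          # feed-equilibrated state
  cr2 <- convective_renewal(c(0, 0, 0, 0), c(0, 0), idx, 0.4, 0.1,
                            75.04, 53.6, 74.8)
  expect_equal(cr2$q[1], 30.016)                 # 0.4 x 75.04 after one tick
  cr3 <- convective_renewal(q, c(74, 74), idx, 0, 0, 75.04, 53.6, 74.8)
  expect_equal(cr3$q, q)                         # zero flow changes nothing
  expect_equal(cr3$sat, c(74, 74))
  expect_error(convective_renewal(q, c(74, 74), idx, 1.4, 0.1,
                                  75.04, 53.6, 74.8), "\\[0, 1\\]")
})
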