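test_that("reference tissue 1540 meets its morphometric contract", {
  g <- ref_grid
  for (s in g$sections) {
    expect_length(s$epi, 12)
    expect_length(s$lum, 4)
  }
  m <- g$morphometry
  expect_gte(m$tubule_fraction, 0.60)
  expect_lte(m$tubule_fraction, 0.80)
  expect_gte(m$capillary_density_mm2, 250)
  expect_lte(m$capillary_density_mm2, 1110)
  expect_lte(abs(m$nc_nt_realized - 1.5), 0.1)
  expect_equal(m$tissue_area_mm2, 0.1024)
})

test_that("all six named variants satisfy every grid invariant", {
  for (code in c("1040", "1050", "1540", "1550", "2040", "2050")) {
    g <- build_tissue(code, ref_params)
    expect_s3_class(g, "rcm_tissue")
    expect_silent(validate_tissue(g))
    ne <- if (g$spec$orTub_diameter == 40) 12 else 16
    nl <- if (g$spec$orTub_diameter == 40) 4 else 9
    expect_equal(g$n_epi_per_section, ne)
    expect_equal(g$n_lum_per_section, nl)
    # adjacency rules, checked exhaustively
    for (i in which(g$type == "LUM"))
      expect_true(all(g$type[g$neighbours[[i]]] %in% c("LUM", "EPI")))
    for (i in which(g$type == "PTC"))
      expect_false(any(g$type[g$neighbours[[i]]] == "LUM"))
  }
})

test_that("tissue construction is deterministic", {
  g1 <- build_tissue("1540", ref_params)
  g2 <- build_tissue("1540", ref_params)
  expect_identical(g1$type, g2$type)
  expect_identical(g1$edges, g2$edges)
})

test_that("exchange surfaces are the documented pairwise values", {
  p <- ref_params
  expect_equal(esa_lookup("EPI", "LUM", p), 2000)
  expect_equal(esa_lookup("LUM", "EPI", p), 2000)  # symmetric
  expect_equal(esa_lookup("EPI", "EPI", p), 800)
  expect_equal(esa_lookup("PTC", "EPI", p), 157)
  expect_equal(esa_lookup("PTC", "INT", p), 39)
  expect_equal(esa_lookup("INT", "INT", p), 100)
  expect_equal(esa_lookup("PTC", "LUM", p), 100)
  expect_error(esa_lookup("XXX", "EPI", p), "unknown patch type")
})

test_that("tissue map serialization is lossless and uses the C/E/L/I codes", {
  f <- withr::local_tempfile(fileext = ".map")
  write_tissue_map(ref_grid, f)
  lines <- readLines(f)
  expect_length(lines, 32)
  expect_true(all(nchar(lines) == 32))
  expect_true(all(strsplit(paste(lines, collapse = ""), "")[[1]] %in%
                  c("C", "E", "L", "I")))
  g2 <- read_tissue_map(f, ref_params)
  expect_identical(g2$type, ref_grid$type)
  expect_equal(length(g2$sections), length(ref_grid$sections))
})

test_that("muscle variant re-types the lumen and keeps the capillary bed", {
  gm <- build_muscle_variant("1540", ref_params, qo2 = 3)
  expect_equal(sum(gm$type == "LUM"), 0)
  expect_equal(sum(gm$type == "PTC"), sum(ref_grid$type == "PTC"))
  expect_equal(sum(gm$type == "EPI"),
               sum(ref_grid$type %in% c("EPI", "LUM")))
  # uniform fibre consumption: 3 mM/min -> 0.05 amol/ms per patch
  cr <- consumption_rates(gm, ref_params, tna = 0)
  expect_equal(unique(cr$hk[gm$type == "EPI"]), 0.05)
  expect_equal(unique(cr$tna_o2), 0)
})

test_that("impossible specs fail with a morphometric message", {
  expect_error(rcm_tissue_spec("9940"), "ratio")
  expect_error(rcm_tissue_spec("1560"), "diameter")
})
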