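# Shared fixtures, built in code.

# A minimal closed micro-grid: n patches in a chain, all of one type, for
# diffusion oracles.  Mirrors the rcm_tissue contract.
make_chain_grid <- function(types, params) {
  n <- length(types)
  nb <- lapply(seq_len(n), function(i) {
    out <- integer(0)
    if (i > 1) out <- c(out, i - 1L)
    if (i < n) out <- c(out, i + 1L)
    out
  })
  g <- structure(list(
    spec = rcm_tissue_spec("1540"), nx = n, ny = 1L,
    volume = rep(1000, n), patch_length = 10, type = types,
    sections = list(), n_epi_per_section = NA_integer_,
    n_lum_per_section = NA_integer_, neighbours = nb), class = "rcm_tissue")
  g <- refresh_edges(g, params)
  g$morphometry <- tissue_morphometry(g)
  g
}

# A hand-made flow state (class rcm_flows) for factor/velocity unit tests.
make_flows <- function(CVF = 24, TVF = 24.6, RBF = 5.3) {
  structure(list(RBF = RBF, CBF = NA, OpNe = NA, SNGBF = NA, SNEABF = NA,
                 SNGFR = NA, SNAPR = NA, CVF = CVF, TVF = TVF,
                 SNFLNa = NA, wkGFR = NA), class = "rcm_flows")
}

# Cached reference tissue (built once per test run).
ref_params <- rcm_params()
ref_grid <- build_tissue("1540", ref_params)
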