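# Tissue construction: a 32 x 32 lattice of 10-um cubic patches mapping the
# four cortical histological components (PTC capillaries, EPI tubular
# epithelium, LUM tubule lumen, INT interstitium).  Tubule cross-sections
# are square blocks (4x4 for 40-um outer diameter: 12 EPI ring + 4 LUM core;
# 5x5 for 50 um: 16 EPI + 9 LUM) on a fixed lattice, separated by 1-patch
# interstitial corridors in which single capillary patches are placed.

.GRID_N <- 32L
.PATCH_L <- 10      # um, patch edge and centre-to-centre diffusion distance
.PATCH_V <- 1000    # um^3

.type_codes <- c(PTC = "C", EPI = "E", LUM = "L", INT = "I")

#' Parse a tissue specification code
#'
#' Tissue variants are named by capillary/tubule ratio x 10 concatenated
#' with the outer tubule diameter in um: the reference tissue is `"1540"`
#' (ratio 1.5, 40 um).
#'
#' @param spec a code like `"1540"`, or a list with `nc_nt_ratio` and
#'   `orTub_diameter`.
#' @param variant `"renal"` or `"muscle"`.
#' @return a list of class `rcm_tissue_spec`.
#' @export
rcm_tissue_spec <- function(spec = "1540", variant = c("renal", "muscle")) {
  variant <- match.arg(variant)
  if (is.character(spec)) {
    if (!grepl("^[0-9]{4}$", spec)) stop("tissue code must be 4 digits, e.g. '1540'")
    ratio <- as.numeric(substr(spec, 1, 2)) / 10
    diam <- as.numeric(substr(spec, 3, 4))
  } else {
    ratio <- spec$nc_nt_ratio
    diam <- spec$orTub_diameter
  }
  if (!ratio %in% c(1.0, 1.5, 2.0))
    stop("capillary/tubule ratio must be 1.0, 1.5 or 2.0, got ", ratio)
  if (!diam %in% c(40, 50))
    stop("outer tubule diameter must be 40 or 50 um, got ", diam)
  structure(list(nc_nt_ratio = ratio, orTub_diameter = diam,
                 name = sprintf("%02d%02d", as.integer(ratio * 10),
                                as.integer(diam)),
                 variant = variant),
            class = "rcm_tissue_spec")
}

# Block origin columns (1-based) for each tubule size on the 32-patch grid.
.block_starts <- function(diam) {
  if (diam == 40) c(1L, 5L, 10L, 14L, 19L, 23L, 28L)  # 7 blocks of 4
  else            c(1L, 7L, 13L, 19L, 25L)            # 5 blocks of 5
}

#' Effective exchange surface between two patch types
#'
#' Symmetric lookup of the pairwise effective exchange surface area (ESA)
#' used in the Fick diffusion flows: EPI-LUM gets the brush-border factor
#' (2000 um^2), EPI-EPI the peritubular cell surface (800), PTC-EPI the
#' (pre-adjusted) capillary-epithelium contact (157), PTC-INT 39; every
#' other pair uses the default 100 um^2.
#'
#' @param typeA,typeB patch types among `"PTC"`, `"EPI"`, `"LUM"`, `"INT"`.
#' @param params an `rcm_params` object.
#' @return surface area, um^2 (vectorized over pairs).
#' @export
esa_lookup <- function(typeA, typeB, params) {
  ok <- c("PTC", "EPI", "LUM", "INT")
  if (!all(typeA %in% ok) || !all(typeB %in% ok))
    stop("unknown patch type")
  a <- pmin(typeA, typeB); b <- pmax(typeA, typeB)  # canonical order
  key <- paste(a, b, sep = "-")
  s <- rep(params$esa_default, length(key))
  s[key == "EPI-LUM"] <- params$bbmf
  s[key == "EPI-EPI"] <- params$ppsa
  s[key == "EPI-PTC"] <- params$pcsa
  s[key == "INT-PTC"] <- params$pcsint
  s
}

.diffusivity <- function(type, params) {
  c(PTC = params$D_PTC, EPI = params$D_EPI,
    LUM = params$D_LUM, INT = params$D_INT)[type]
}

#' Build a cortical tissue grid
#'
#' Deterministic constructive layout (no randomness): square tubule blocks
#' on a fixed lattice separated by 1-patch interstitial corridors; capillary
#' patches placed singly in the corridors by a row-major scan, preferring
#' sites adjacent to epithelium and not adjacent to an already-placed
#' capillary, until the target capillary/tubule count is met; remaining
#' corridor patches are interstitium.  Grid boundaries are closed (no-flux).
#'
#' @param spec an `rcm_tissue_spec` (or a code string accepted by
#'   [rcm_tissue_spec()]).
#' @param params an `rcm_params` object (ESA entries, diffusivities).
#' @return an object of class `rcm_tissue`; see Details.
#' @details The returned list carries `type` (length-1024 character vector,
#'   row-major), `nx`, `ny`, `volume` (um^3 per patch), `sections` (per
#'   tubule: indices of its EPI ring and LUM core), `n_epi_per_section`,
#'   `n_lum_per_section`, `edges` (data.frame i, j, S, D of unique adjacent
#'   pairs) and the morphometry report.
#' @export
build_tissue <- function(spec = "1540", params = rcm_params()) {
  if (!inherits(spec, "rcm_tissue_spec")) spec <- rcm_tissue_spec(spec)
  n <- .GRID_N
  b <- if (spec$orTub_diameter == 40) 4L else 5L
  starts <- .block_starts(spec$orTub_diameter)
  type <- matrix("INT", n, n)  # [row, col]
  sections <- list()
  for (sy in starts) for (sx in starts) {
    rows <- sy:(sy + b - 1); cols <- sx:(sx + b - 1)
    blk <- matrix("EPI", b, b)
    blk[2:(b - 1), 2:(b - 1)] <- "LUM"
    type[rows, cols] <- blk
    idx <- as.vector(outer(rows, (cols - 1) * n, `+`))  # column-major index
    tt <- as.vector(blk)
    sections[[length(sections) + 1L]] <- list(
      epi = idx[tt == "EPI"], lum = idx[tt == "LUM"])
  }
  n_tub <- length(sections)
  # capillary count: round to the ratio, then nudge within +-0.1 of the
  # ratio so the areal density lands inside the morphometric 250-1110 mm^-2
  area_mm2 <- (n * .PATCH_L / 1000)^2
  nc <- round(spec$nc_nt_ratio * n_tub)
  lo <- ceiling(250 * area_mm2); hi <- floor(1110 * area_mm2)
  nc_adj <- min(max(nc, lo), hi)
  if (abs(nc_adj / n_tub - spec$nc_nt_ratio) > 0.1)
    stop("cannot satisfy capillary density 250-1110 mm^-2 while keeping ",
         "Nc/Nt within 0.1 of ", spec$nc_nt_ratio, " on a 32x32 grid")
  nc <- nc_adj
  type_v <- as.vector(type)  # column-major: index = row + (col-1)*n
  corridor <- which(type_v == "INT")
  if (length(corridor) < nc)
    stop("not enough interstitial corridor patches (", length(corridor),
         ") to place ", nc, " capillaries")
  nb <- .neighbour_list(n)
  # row-major scan order over the grid
  scan <- order((corridor - 1L) %% n, (corridor - 1L) %/% n)
  corridor <- corridor[scan]
  placed <- logical(n * n)
  n_placed <- 0L
  for (pass in 1:3) {
    for (i in corridor) {
      if (n_placed >= nc) break
      if (placed[i]) next
      nbs <- nb[[i]]
      near_epi <- any(type_v[nbs] == "EPI")
      near_ptc <- any(placed[nbs])
      ok <- switch(pass, near_epi && !near_ptc, near_epi, TRUE)
      if (ok) { placed[i] <- TRUE; n_placed <- n_placed + 1L }
    }
    if (n_placed >= nc) break
  }
  if (n_placed < nc)
    stop("could not place ", nc, " capillaries in the corridors")
  type_v[placed] <- "PTC"

  grid <- structure(list(
    spec = spec, nx = n, ny = n, volume = rep(.PATCH_V, n * n),
    patch_length = .PATCH_L, type = type_v,
    sections = sections,
    n_epi_per_section = if (b == 4) 12L else 16L,
    n_lum_per_section = if (b == 4) 4L else 9L,
    neighbours = nb), class = "rcm_tissue")
  grid$edges <- .build_edges(grid, params)
  grid$morphometry <- tissue_morphometry(grid)
  validate_tissue(grid)
  grid
}

# Von Neumann neighbour indices for an n x n grid, column-major, closed
# boundaries.
.neighbour_list <- function(n) {
  lapply(seq_len(n * n), function(i) {
    r <- (i - 1L) %% n + 1L; c <- (i - 1L) %/% n + 1L
    out <- integer(0)
    if (r > 1) out <- c(out, i - 1L)
    if (r < n) out <- c(out, i + 1L)
    if (c > 1) out <- c(out, i - n)
    if (c < n) out <- c(out, i + n)
    out
  })
}

# Unique adjacent pairs with their effective surface and mean diffusivity.
.build_edges <- function(grid, params) {
  i <- rep(seq_along(grid$neighbours), lengths(grid$neighbours))
  j <- unlist(grid$neighbours)
  keep <- i < j
  i <- i[keep]; j <- j[keep]
  ta <- grid$type[i]; tb <- grid$type[j]
  data.frame(i = i, j = j,
             S = esa_lookup(ta, tb, params),
             D = (.diffusivity(ta, params) + .diffusivity(tb, params)) / 2)
}

#' Recompute edge surfaces/diffusivities for a (possibly new) parameter set
#' @param grid an `rcm_tissue`.
#' @param params an `rcm_params`.
#' @return the grid with refreshed `edges`.
#' @export
refresh_edges <- function(grid, params) {
  grid$edges <- .build_edges(grid, params)
  grid
}

#' Morphometry report of a tissue grid
#'
#' @param grid an `rcm_tissue`.
#' @return a list: per-type patch counts, volume fractions, capillary areal
#'   density (mm^-2), tubule volume fraction, realized Nc/Nt ratio.
#' @export
tissue_morphometry <- function(grid) {
  counts <- table(factor(grid$type, levels = c("PTC", "EPI", "LUM", "INT")))
  ntot <- length(grid$type)
  area_mm2 <- (grid$nx * grid$patch_length / 1000) *
              (grid$ny * grid$patch_length / 1000)
  n_tub <- length(grid$sections)
  list(counts = c(counts),
       fractions = c(counts) / ntot,
       tubule_fraction = unname((counts["EPI"] + counts["LUM"]) / ntot),
       capillary_density_mm2 = unname(counts["PTC"] / area_mm2),
       n_tubules = n_tub,
       nc_nt_realized = unname(if (n_tub) counts["PTC"] / n_tub else NA_real_),
       tissue_area_mm2 = area_mm2)
}

#' Validate the structural invariants of a tissue grid
#'
#' Checks section composition (12 EPI + 4 LUM at 40 um, 16 + 9 at 50 um),
#' adjacency rules (LUM only next to LUM/EPI; PTC never next to LUM), the
#' tubule volume fraction (0.60-0.80 for renal variants), the capillary
#' areal density (250-1110 mm^-2), and the realized Nc/Nt ratio (+-0.1).
#'
#' @param grid an `rcm_tissue`.
#' @return the grid, invisibly; errors listing the violated constraint.
#' @export
validate_tissue <- function(grid) {
  m <- grid$morphometry
  sp <- grid$spec
  for (s in grid$sections) {
    if (length(s$epi) != grid$n_epi_per_section ||
        length(s$lum) != grid$n_lum_per_section)
      stop("tubule section with ", length(s$epi), " EPI + ", length(s$lum),
           " LUM patches; expected ", grid$n_epi_per_section, " + ",
           grid$n_lum_per_section)
  }
  lum <- which(grid$type == "LUM")
  for (i in lum) {
    tn <- grid$type[grid$neighbours[[i]]]
    if (any(!tn %in% c("LUM", "EPI")))
      stop("LUM patch ", i, " adjacent to ", paste(setdiff(tn, c("LUM", "EPI")),
           collapse = ","), "; LUM may only touch LUM or EPI")
  }
  if (sp$variant == "renal") {
    if (m$tubule_fraction < 0.60 || m$tubule_fraction > 0.80)
      stop("tubule volume fraction ", round(m$tubule_fraction, 3),
           " outside 0.60-0.80")
    if (abs(m$nc_nt_realized - sp$nc_nt_ratio) > 0.1)
      stop("realized Nc/Nt ", round(m$nc_nt_realized, 2),
           " differs from spec ", sp$nc_nt_ratio, " by more than 0.1")
  }
  if (m$capillary_density_mm2 < 250 || m$capillary_density_mm2 > 1110)
    stop("capillary density ", round(m$capillary_density_mm2),
         " mm^-2 outside 250-1110")
  invisible(grid)
}

#' Build a muscle-oriented tissue variant
#'
#' Same capillary layout as the renal counterpart, but every luminal patch
#' is re-typed epithelial (muscle fibres have no lumen), all EPI patches
#' are assigned one uniform consumption rate, and there is no tubular flow.
#'
#' @param spec tissue code or `rcm_tissue_spec`.
#' @param params an `rcm_params` object.
#' @param qo2 uniform fibre oxygen consumption, mM/min (default 3, within
#'   the sub-maximal striated-muscle range 1-5).
#' @return an `rcm_tissue` with `spec$variant == "muscle"`, carrying
#'   `muscle_qo2`.
#' @export
build_muscle_variant <- function(spec = "1540", params = rcm_params(),
                                 qo2 = 3) {
  if (!inherits(spec, "rcm_tissue_spec")) spec <- rcm_tissue_spec(spec)
  base <- build_tissue(rcm_tissue_spec(spec$name, "renal"), params)
  spec$variant <- "muscle"
  base$spec <- spec
  base$type[base$type == "LUM"] <- "EPI"
  base$sections <- list()
  base$muscle_qo2 <- qo2
  base$edges <- .build_edges(base, params)
  base$morphometry <- tissue_morphometry(base)
  validate_tissue(base)
  base
}

#' @export
print.rcm_tissue <- function(x, ...) {
  m <- x$morphometry
  cat("<rcm_tissue> spec", x$spec$name, paste0("(", x$spec$variant, ")"),
      "-", x$nx, "x", x$ny, "patches\n")
  cat("  counts:", paste(names(m$counts), m$counts, collapse = "  "), "\n")
  cat(sprintf("  tubule fraction %.3f, capillary density %.0f mm^-2, Nc/Nt %.2f\n",
              m$tubule_fraction, m$capillary_density_mm2, m$nc_nt_realized))
  invisible(x)
}

#' Write a tissue map as a 32-line text grid
#'
#' One character per patch: `C` = PTC, `E` = EPI, `L` = LUM, `I` = INT;
#' one text line per grid row.
#'
#' @param grid an `rcm_tissue`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tissue_map <- function(grid, path) {
  n <- grid$nx
  ch <- .type_codes[grid$type]
  mat <- matrix(ch, n, n)  # column-major like type
  writeLines(apply(mat, 1, paste, collapse = ""), path)
  invisible(path)
}

#' Read a tissue map written by [write_tissue_map()]
#'
#' Restores patch types and rebuilds neighbour links and edges; tubule
#' section membership is reconstructed by connected-component labelling of
#' the LUM cores with their surrounding EPI rings when the map matches a
#' block layout, otherwise left empty.
#'
#' @param path file path.
#' @param params an `rcm_params` for the edge table.
#' @param spec optional `rcm_tissue_spec` or code; when given, sections are
#'   reconstructed from the standard block lattice of that spec.
#' @return an `rcm_tissue`.
#' @export
read_tissue_map <- function(path, params = rcm_params(), spec = NULL) {
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  if (any(nchar(lines) != n))
    stop("tissue map must be a square character grid")
  rev_codes <- setNames(names(.type_codes), .type_codes)
  mat <- do.call(rbind, strsplit(lines, ""))  # [row, col]
  if (any(!mat %in% .type_codes)) stop("tissue map contains unknown characters")
  type_v <- as.vector(matrix(unname(rev_codes[mat]), n, n))
  grid <- structure(list(
    spec = if (is.null(spec)) rcm_tissue_spec("1540") else
      if (inherits(spec, "rcm_tissue_spec")) spec else rcm_tissue_spec(spec),
    nx = n, ny = n, volume = rep(.PATCH_V, n * n), patch_length = .PATCH_L,
    type = type_v, sections = list(),
    n_epi_per_section = NA_integer_, n_lum_per_section = NA_integer_,
    neighbours = .neighbour_list(n)), class = "rcm_tissue")
  ref <- try(build_tissue(grid$spec, params), silent = TRUE)
  if (!inherits(ref, "try-error") && identical(ref$type, grid$type)) {
    grid$sections <- ref$sections
    grid$n_epi_per_section <- ref$n_epi_per_section
    grid$n_lum_per_section <- ref$n_lum_per_section
  }
  grid$edges <- .build_edges(grid, params)
  grid$morphometry <- tissue_morphometry(grid)
  grid
}
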