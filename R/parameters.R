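# Unit conventions used throughout ("patch units"):
#   length um, time ms, oxygen amount amol, pressure mmHg.
#   1 amol per 1000-um^3 patch == 1 umol/L (uM); 1 nL = 1e6 um^3;
#   1 min = 6e4 ms. The two conversion constants live only here.
.NL_PER_UM3   <- 1e-6   # nL per um^3
.MS_PER_MIN   <- 6e4    # ms per min

#' Convert a volumetric flow from nL/min to um^3/ms
#'
#' The factor 1/(6e-2) of the convective flow-factor equations: 1 nL/min
#' equals 16.67 um^3/ms.
#'
#' @param nl_min flow in nL/min.
#' @return flow in um^3/ms.
#' @keywords internal
nlmin_to_um3ms <- function(nl_min) nl_min / .NL_PER_UM3 / .MS_PER_MIN

#' Convert a specific rate in mM/min to amol/ms for one patch
#'
#' 1 mM/min over a patch of volume `volume` um^3 is `volume` amol/min
#' (1 mM = 1 amol/um^3 is wrong by 1000: 1 mM = 1000 uM = 1 amol per um^3
#' -- see below).  Concretely 1 mM = 1000 uM and 1 uM = 1 amol per
#' 1000 um^3, so 1 mM/min = volume amol/min per patch = volume/6e4 amol/ms.
#'
#' @param mm_min rate in mM/min.
#' @param volume patch volume in um^3 (default 1000).
#' @return rate in amol/ms per patch.
#' @keywords internal
mmmin_to_amolms <- function(mm_min, volume = 1000) mm_min * volume / .MS_PER_MIN

# Reference (rcm0) parameter values.  Flow inputs in mL/(min.gkw) ("flow
# units", FU), pressures mmHg, lengths um, diffusivities um^2/ms
# (1e-5 cm^2/s = 1 um^2/ms), solubility uM/mmHg, consumption rates mM/min.
.preset_rcm0 <- list(
  RBF        = 5.3,      # renal blood flow, FU
  frCBF      = 0.90,     # cortical fraction of RBF
  Ntot       = 32400,    # nephrons per gkw
  frNCtx     = 27000 / 32400,  # operational fraction; OpNe = 27,000/gkw
  FF         = 0.34,     # filtration fraction
  Hta        = 0.45,     # arterial hematocrit
  frPR       = 0.51,     # fractional proximal reabsorption
  fCapBr     = 6,        # capillaries per efferent arteriole
  Nap        = 142,      # plasma Na+, mmol/L
  frTC       = 0.81,     # transcellular fraction of Na+ reabsorption
  fBIC       = 1.15,     # bicarbonate factor (pump-independent reabsorption)
  PO2ratio   = 4.5,      # Oxphos ATP/O2 stoichiometry
  NaATP      = 3,        # Na+ pumped per ATP (NaK-pump stoichiometry)
  Km         = 1.1,      # cytochrome-oxidase Km for O2, uM
  Hb4RBC     = 5.2,      # tetramer Hb in RBC, mmol/L-RBC
  P50        = 36.8,     # Hb half-saturation PO2, mmHg
  alpha      = 1.34,     # O2 solubility, uM/mmHg
  D_PTC      = 1.40,     # O2 diffusivity, um^2/ms
  D_LUM      = 2.80,
  D_EPI      = 1.10,
  D_INT      = 2.20,
  bbmf       = 2000,     # EPI-LUM exchange surface, um^2 (brush border)
  ppsa       = 800,      # EPI-EPI exchange surface, um^2
  pcsa       = 157,      # PTC-EPI exchange surface, um^2 (2x-adjusted, Rc 5)
  pcsint     = 39,       # PTC-INT exchange surface, um^2
  esa_default = 100,     # default exchange surface, um^2
  Rc         = 5.0,      # capillary radius, um
  TubLength  = 10400,    # effective tubule length, um
  JmaxHK_epi = 1.9,      # EPI housekeeping consumption, mM-EPI/min
  Jmax_cap_specific = 1.2,  # endothelial specific consumption, mM/min
  endo_thickness = 0.75, # endothelial crown thickness, um
  Jmax_int   = 0.5,      # interstitial housekeeping, mM-INT/min
  tick       = 1,        # step duration, ms
  capFactor  = 1.0,      # capillary hemodynamic factor (scales CFF only)
  PTC_feed   = 56,       # capillary feed PO2, mmHg
  LUM_feed   = 40,       # luminal feed PO2, mmHg
  Hb_active  = TRUE,
  hb_literal_asso = FALSE, # printed Eq-18 form (saturated fraction)
  hb_monomer = FALSE,      # monomer reading of Hbt (no factor 4)
  tna_follows_flow = FALSE # recompute TNa when RBF changes mid-protocol
)

# The five physiological adjustments of the fine-tuned preset (rcmstar).
.preset_rcmstar_delta <- list(
  TubLength = 12400,
  frPR      = 0.75,
  frTC      = 0.56,
  fBIC      = 1.5,
  PO2ratio  = 5.5
)

# Plausible ranges: overrides outside these are accepted with a warning.
.param_ranges <- list(
  RBF = c(0, 15), frCBF = c(0.7, 1), Ntot = c(20000, 45000),
  frNCtx = c(0.5, 1), FF = c(0.15, 0.5), Hta = c(0.3, 0.6),
  frPR = c(0, 1), fCapBr = c(2, 12), Nap = c(120, 160),
  frTC = c(0, 1), fBIC = c(1, 2), PO2ratio = c(3, 6.5), NaATP = c(2, 4),
  Km = c(0.1, 10), Hb4RBC = c(3, 7), P50 = c(25, 45), alpha = c(1, 1.7),
  D_PTC = c(0.5, 5), D_LUM = c(0.5, 5), D_EPI = c(0.5, 5), D_INT = c(0.5, 5),
  bbmf = c(100, 4000), ppsa = c(100, 2000), pcsa = c(50, 400),
  pcsint = c(10, 200), esa_default = c(50, 200),
  Rc = c(2, 10), TubLength = c(5000, 20000),
  JmaxHK_epi = c(0, 10), Jmax_cap_specific = c(0, 5),
  endo_thickness = c(0.3, 1.5), Jmax_int = c(0, 5),
  capFactor = c(0.01, 2), PTC_feed = c(0, 150), LUM_feed = c(0, 150)
)

.fraction_fields <- c("frCBF", "frNCtx", "FF", "Hta", "frPR", "frTC")
.nonneg_fields <- c("RBF", "Ntot", "fCapBr", "Nap", "fBIC", "PO2ratio",
                    "NaATP", "Km", "Hb4RBC", "P50", "alpha",
                    "D_PTC", "D_LUM", "D_EPI", "D_INT",
                    "bbmf", "ppsa", "pcsa", "pcsint", "esa_default",
                    "Rc", "TubLength", "JmaxHK_epi", "Jmax_cap_specific",
                    "endo_thickness", "Jmax_int", "capFactor",
                    "PTC_feed", "LUM_feed")
.logical_fields <- c("Hb_active", "hb_literal_asso", "hb_monomer",
                     "tna_follows_flow")

#' Build a validated parameter set
#'
#' Returns the full registry of model constants for one of the two named
#' configurations: `"rcm0"`, the reference setting with every parameter at
#' its bibliographic reference value, or `"rcmstar"`, the physiologically
#' adjusted setting that differs from the reference in exactly five values
#' (tubule length 12,400 um, fractional reabsorption 0.75, transcellular
#' fraction 0.56, bicarbonate factor 1.5, ATP/O2 5.5).
#'
#' @param preset `"rcm0"` or `"rcmstar"`.
#' @param ... named overrides of individual fields, e.g. `RBF = 0`.
#' @param overrides optional named list of overrides (merged after `...`).
#' @return an object of class `rcm_params`: a named list of constants.
#' @examples
#' p <- rcm_params("rcm0")
#' p$frPR            # 0.51
#' ps <- rcm_params("rcmstar")
#' ps$TubLength      # 12400
#' @export
rcm_params <- function(preset = c("rcm0", "rcmstar"), ..., overrides = NULL) {
  preset <- match.arg(preset)
  p <- .preset_rcm0
  if (preset == "rcmstar")
    p[names(.preset_rcmstar_delta)] <- .preset_rcmstar_delta
  ov <- c(list(...), overrides)
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("all parameter overrides must be named")
    for (k in names(ov)) {
      if (!k %in% names(p))
        stop("unknown parameter key: '", k, "'")
      v <- ov[[k]]
      if (k %in% .logical_fields) {
        if (!is.logical(v) || length(v) != 1L || is.na(v))
          stop("parameter '", k, "' must be a single logical value")
      } else {
        if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
          stop("parameter '", k, "' must be a single finite numeric value")
        rng <- .param_ranges[[k]]
        if (!is.null(rng) && (v < rng[1] || v > rng[2]))
          warning("override ", k, " = ", v, " lies outside plausible range [",
                  rng[1], ", ", rng[2], "]")
      }
      p[[k]] <- v
    }
  }
  p$preset <- preset
  class(p) <- "rcm_params"
  validate_params(p)
  p
}

#' Validate hard invariants of a parameter set
#' @param p an `rcm_params` object.
#' @return `p`, invisibly; errors on violation.
#' @keywords internal
validate_params <- function(p) {
  for (k in .fraction_fields) {
    v <- p[[k]]
    if (v < 0 || v > 1) stop("parameter '", k, "' must lie in [0, 1], got ", v)
  }
  for (k in .nonneg_fields) {
    if (p[[k]] < 0) stop("parameter '", k, "' must be >= 0, got ", p[[k]])
  }
  if (p$tick <= 0 || p$tick > 20)
    stop("tick must lie in (0, 20] ms, got ", p$tick)
  invisible(p)
}

#' @export
print.rcm_params <- function(x, ...) {
  cat("<rcm_params> preset:", x$preset, "\n")
  num <- x[!names(x) %in% c("preset", .logical_fields)]
  df <- data.frame(value = unlist(num))
  print(df)
  cat("flags:",
      paste(sprintf("%s=%s", .logical_fields,
                    unlist(x[.logical_fields])), collapse = ", "), "\n")
  invisible(x)
}

#' Hemoglobin tetramer content of one capillary patch
#'
#' Hbt = Hb4RBC * Hta * V / 1000 amol (default 2340 amol for a 1000-um^3
#' patch): tetramer hemoglobin at arterial hematocrit, homogenized over the
#' patch. With four O2 per tetramer this gives a blood O2 capacity of
#' 9360 amol/patch (~9.4 mM).
#'
#' @param params an `rcm_params` object.
#' @param volume patch volume, um^3.
#' @return tetramer amount, amol per patch.
#' @export
hb_content <- function(params, volume = 1000) {
  params$Hb4RBC * params$Hta * volume / 1000 * 1000 # mmol/L -> uM -> amol
}

#' Per-patch maximal capillary (endothelial) consumption
#'
#' The literature rate (1.2 mM/min) is specific to the endothelium; a PTC
#' patch carries only an endothelial crown of thickness h at radius Rc, so
#' the specific rate is scaled by the crown volume fraction
#' pi (Rc^2 - (Rc - h)^2) * 10 / 1000 (~0.218 at Rc 5, h 0.75).
#'
#' @param params an `rcm_params` object.
#' @return maximal PTC consumption, mM-patch/min.
#' @export
jmax_cap_patch <- function(params) {
  Rc <- params$Rc
  h <- min(params$endo_thickness, Rc)
  crown <- pi * (Rc^2 - (Rc - h)^2) * 10 / 1000
  params$Jmax_cap_specific * crown
}

#' Dissolved oxygen content of a patch at a given PO2
#'
#' content = alpha * po2 * volume / 1000 amol, with alpha in uM/mmHg; for the
#' default 1000-um^3 patch, 1 amol corresponds to 1 uM.
#'
#' @param po2 oxygen partial pressure, mmHg (scalar or vector, >= 0).
#' @param params an `rcm_params` object (uses `alpha`).
#' @param volume patch volume, um^3.
#' @return oxygen content, amol.
#' @examples
#' p <- rcm_params()
#' po2_to_content(56, p)   # 75.04 amol
#' @export
po2_to_content <- function(po2, params, volume = 1000) {
  if (any(po2 < 0)) stop("po2 must be >= 0")
  if (any(volume <= 0)) stop("volume must be > 0")
  params$alpha * po2 * volume / 1000
}

#' Inverse of [po2_to_content()]
#' @param content oxygen content, amol.
#' @param params an `rcm_params` object.
#' @param volume patch volume, um^3.
#' @return PO2, mmHg.
#' @export
content_to_po2 <- function(content, params, volume = 1000) {
  content / (params$alpha * volume / 1000)
}

#' Read a flat key-value configuration file
#'
#' A minimal TOML dialect: one `key = value` pair per line, `#` comments,
#' values numeric, `true`/`false`, or quoted strings. A `preset` key selects
#' the base configuration; every other key overrides a parameter field.
#'
#' @param path file path.
#' @return an `rcm_params` object.
#' @export
read_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regexpr("=", ln, fixed = TRUE)
    if (m < 0) stop("malformed config line (no '='): ", ln)
    k <- trimws(substr(ln, 1, m - 1))
    v <- trimws(substr(ln, m + 1, nchar(ln)))
    if (grepl('^".*"$', v) || grepl("^'.*'$", v)) {
      val <- substr(v, 2, nchar(v) - 1)
    } else if (tolower(v) %in% c("true", "false")) {
      val <- as.logical(toupper(v))
    } else {
      val <- suppressWarnings(as.numeric(v))
      if (is.na(val)) stop("non-numeric value for key '", k, "': ", v)
    }
    kv[[k]] <- val
  }
  preset <- if (!is.null(kv$preset)) kv$preset else "rcm0"
  kv$preset <- NULL
  rcm_params(preset = preset, overrides = kv)
}

#' Write a parameter set as a flat key-value file
#'
#' Inverse of [read_params()]: reloading reproduces the set field-for-field.
#'
#' @param params an `rcm_params` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  keys <- setdiff(names(params), "preset")
  fmt <- vapply(keys, function(k) {
    v <- params[[k]]
    if (is.logical(v)) sprintf("%s = %s", k, tolower(as.character(v)))
    else sprintf("%s = %s", k, format(v, digits = 17))
  }, character(1))
  writeLines(c(sprintf('preset = "%s"', params$preset), fmt), path)
  invisible(path)
}
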