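# The perfusion cascade: from whole-kidney renal blood flow down to the
# volumetric flow of one capillary (CVF) and one tubule (TVF), the sodium
# load and per-patch reabsorptive transport, and the per-tick convective
# renewal factors.

#' Compute the dependent flow cascade
#'
#' CBF = RBF frCBF; OpNe = Ntot frNCtx; SNGBF = 1e6 CBF / OpNe;
#' SNEABF = SNGBF (1 - FF (1 - Hta)); SNGFR = SNGBF - SNEABF;
#' SNAPR = frPR SNGFR; CVF = SNEABF / fCapBr + 0.5 SNAPR / fCapBr;
#' TVF = SNGFR - 0.5 SNAPR.  Reabsorbed fluid is returned to the capillaries
#' at tubule mid-length, hence the half-weighting of SNAPR on both sides.
#'
#' @param params an `rcm_params` object.
#' @param rbf optional renal blood flow override, FU (mL/min/gkw); defaults
#'   to `params$RBF`.
#' @return an object of class `rcm_flows` with fields CBF (FU), OpNe
#'   (per gkw), SNGBF, SNEABF, SNGFR, SNAPR, CVF, TVF (nL/min), SNFLNa
#'   (amol/min), and wkGFR (mL/min/gkw, back-calculated).
#' @examples
#' f <- compute_flow_cascade(rcm_params())
#' round(f$SNGFR, 1)  # 33.0 nL/min
#' @export
compute_flow_cascade <- function(params, rbf = NULL) {
  RBF <- if (is.null(rbf)) params$RBF else rbf
  if (RBF < 0) stop("RBF must be >= 0")
  CBF <- RBF * params$frCBF
  OpNe <- params$Ntot * params$frNCtx
  if (OpNe <= 0 && RBF > 0)
    stop("no operational nephrons (OpNe = 0) with non-zero RBF")
  SNGBF <- if (OpNe > 0) 1e6 * CBF / OpNe else 0
  SNEABF <- SNGBF * (1 - params$FF * (1 - params$Hta))
  SNGFR <- SNGBF - SNEABF
  SNAPR <- params$frPR * SNGFR
  CVF <- SNEABF / params$fCapBr + 0.5 * SNAPR / params$fCapBr
  TVF <- SNGFR - 0.5 * SNAPR
  SNFLNa <- 1e6 * SNGFR * params$Nap
  structure(list(RBF = RBF, CBF = CBF, OpNe = OpNe, SNGBF = SNGBF,
                 SNEABF = SNEABF, SNGFR = SNGFR, SNAPR = SNAPR,
                 CVF = CVF, TVF = TVF, SNFLNa = SNFLNa,
                 wkGFR = SNGFR * OpNe * 1e-6),
            class = "rcm_flows")
}

#' Sodium reabsorption assigned to one epithelial patch
#'
#' TNa = frPR SNFLNa (1 / nEPI) (10 / TubLength) amol/min: the whole-tubule
#' reabsorption, scaled to the 10-um slice the slab represents and shared
#' among the EPI patches of one tubule cross-section (12 at 40 um outer
#' diameter, 16 at 50 um).
#'
#' @param flow an `rcm_flows` object.
#' @param params an `rcm_params` object.
#' @param grid an `rcm_tissue`.
#' @return TNa per EPI patch, amol/min.
#' @export
sodium_transport_per_patch <- function(flow, params, grid) {
  n_epi <- grid$n_epi_per_section
  if (is.na(n_epi) || n_epi == 0) return(0)
  params$frPR * flow$SNFLNa * (1 / n_epi) * (10 / params$TubLength)
}

#' Per-tick convective renewal factors
#'
#' CFF = capFactor CVF tick / (6e-2 Vcap); TFF = TVF tick /
#' (nLUM 6e-2 Vlum), with the factor 1/(6e-2) converting nL/min to um^3/ms.
#' The capillary hemodynamic factor scales the capillary renewal only
#' (it corrects the apparent capillary velocity / residence time).
#'
#' @param flow an `rcm_flows` object.
#' @param params an `rcm_params` object.
#' @param grid an `rcm_tissue`.
#' @return list with `CFF` and `TFF` (fractions per tick, both in [0, 1]).
#' @examples
#' p <- rcm_params(); g <- build_tissue("1540", p)
#' flow_factors(compute_flow_cascade(p), p, g)
#' @export
flow_factors <- function(flow, params, grid) {
  vcap <- 1000; vlum <- 1000
  cff <- params$capFactor * nlmin_to_um3ms(flow$CVF) * params$tick / vcap
  n_lum <- grid$n_lum_per_section
  tff <- if (is.na(n_lum) || n_lum == 0 || length(grid$sections) == 0) 0
         else nlmin_to_um3ms(flow$TVF) * params$tick / (n_lum * vlum)
  if (cff < 0 || cff > 1)
    stop("capillary flow factor ", round(cff, 3),
         " outside [0, 1]; reduce the tick duration")
  if (tff < 0 || tff > 1)
    stop("tubular flow factor ", round(tff, 3),
         " outside [0, 1]; reduce the tick duration")
  list(CFF = cff, TFF = tff)
}

#' Apparent capillary blood velocity
#'
#' v = capFactor CVF / (6e-2 pi Rc^2): the per-capillary volumetric flow
#' over the capillary cross-section; um/ms, numerically equal to mm/s.
#'
#' @param flow an `rcm_flows` object.
#' @param params an `rcm_params` object.
#' @return velocity, mm/s.
#' @export
apparent_capillary_velocity <- function(flow, params) {
  if (params$Rc <= 0) stop("Rc must be > 0")
  params$capFactor * nlmin_to_um3ms(flow$CVF) / (pi * params$Rc^2)
}

#' @export
print.rcm_flows <- function(x, ...) {
  cat("<rcm_flows> RBF", x$RBF, "FU\n")
  v <- unlist(x[c("CBF", "OpNe", "SNGBF", "SNEABF", "SNGFR", "SNAPR",
                  "CVF", "TVF", "SNFLNa", "wkGFR")])
  print(data.frame(value = v))
  invisible(x)
}

#' Flow state as a one-row data frame (for CSV output)
#' @param flow an `rcm_flows` object.
#' @return a data.frame with unit-annotated column names.
#' @export
flows_as_df <- function(flow) {
  data.frame(RBF_FU = flow$RBF, CBF_FU = flow$CBF, OpNe_per_gkw = flow$OpNe,
             SNGBF_nl_min = flow$SNGBF, SNEABF_nl_min = flow$SNEABF,
             SNGFR_nl_min = flow$SNGFR, SNAPR_nl_min = flow$SNAPR,
             CVF_nl_min = flow$CVF, TVF_nl_min = flow$TVF,
             SNFLNa_amol_min = flow$SNFLNa, wkGFR_ml_min_gkw = flow$wkGFR)
}
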