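# The three per-tick oxygen field operators: convective renewal of the
# perfused patches, Fick diffusion on the lattice, and Michaelis-Menten
# consumption.  The engine (engine.R) composes them; they are also exposed
# individually for verification.

#' Build the synchronous diffusion update matrix
#'
#' For every ordered neighbour pair the unidirectional flow is
#' Jdiff(i->j) = (1/L) Dij Sij [O2]_i amol/ms, with L = 10 um, Dij the mean
#' of the two patch diffusivities and Sij the pairwise effective exchange
#' surface.  All flows are computed from start-of-tick contents, so one
#' tick is the linear map q <- P q with
#' P = I + tick (C^T - diag(rowSums(C))), C_ij = Dij Sij / (L V_i).
#'
#' @param grid an `rcm_tissue` (with `edges` built for the active params).
#' @param params an `rcm_params` object.
#' @return list with the sparse matrix `P`, the per-patch outflow fraction
#'   per tick `outflow`, and `max_tick`, the largest stable tick (ms).
#' @export
diffusion_operator <- function(grid, params) {
  e <- grid$edges
  L <- grid$patch_length
  V <- grid$volume
  cij <- e$D * e$S / (L * V[e$i])   # fraction of q_i leaving towards j, /ms
  cji <- e$D * e$S / (L * V[e$j])
  n <- length(grid$type)
  out_rate <- numeric(n)
  tab1 <- tapply(cij, e$i, sum); tab2 <- tapply(cji, e$j, sum)
  out_rate[as.integer(names(tab1))] <- out_rate[as.integer(names(tab1))] + tab1
  out_rate[as.integer(names(tab2))] <- out_rate[as.integer(names(tab2))] + tab2
  worst <- which.max(out_rate)
  max_tick <- 1 / max(out_rate)
  if (out_rate[worst] * params$tick > 1)
    stop("diffusion unstable at tick ", params$tick, " ms: patch ", worst,
         " (type ", grid$type[worst], ") would lose ",
         round(out_rate[worst] * params$tick, 2),
         " of its content per tick; maximum admissible tick is ",
         signif(max_tick, 3), " ms")
  tick <- params$tick
  ii <- c(e$i, e$j, e$j, e$i, seq_len(n))
  jj <- c(e$i, e$j, e$i, e$j, seq_len(n))
  xx <- c(-tick * cij, -tick * cji, tick * cij, tick * cji, rep(1, n))
  P <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  list(P = P, outflow = out_rate * tick, max_tick = max_tick)
}

#' One synchronous diffusion tick
#'
#' @param q oxygen contents, amol (length = patches).
#' @param op the operator from [diffusion_operator()].
#' @return updated contents.
#' @export
diffusion_step <- function(q, op) {
  as.numeric(op$P %*% q)
}

#' One convective-renewal tick
#'
#' Every capillary patch exchanges the fraction CFF of its volume against
#' feed blood, every luminal patch the fraction TFF against feed filtrate:
#' q <- q + f (q_feed - q).  Capillary hemoglobin saturation is renewed the
#' same way against the feed-equilibrium saturation.
#'
#' @param q oxygen contents, amol.
#' @param sat PTC saturation vector, percent.
#' @param idx list with `ptc` and `lum` patch indices.
#' @param cff,tff renewal fractions in [0, 1].
#' @param q_feed_ptc,q_feed_lum feed oxygen contents, amol.
#' @param s_feed feed saturation, percent.
#' @return list with updated `q` and `sat`.
#' @export
convective_renewal <- function(q, sat, idx, cff, tff,
                               q_feed_ptc, q_feed_lum, s_feed) {
  if (cff < 0 || cff > 1 || tff < 0 || tff > 1)
    stop("renewal factors must lie in [0, 1]")
  if (cff > 0) {
    q[idx$ptc] <- q[idx$ptc] + cff * (q_feed_ptc - q[idx$ptc])
    sat <- sat + cff * (s_feed - sat)
  }
  if (tff > 0 && length(idx$lum))
    q[idx$lum] <- q[idx$lum] + tff * (q_feed_lum - q[idx$lum])
  list(q = q, sat = sat)
}

#' Per-patch maximal consumption rates (amol/ms)
#'
#' PTC patches consume through their endothelial crown, INT patches at the
#' interstitial housekeeping rate, EPI patches at the epithelial
#' housekeeping rate plus the sodium-transport cost
#' JTNa = (1/NaATP) / PO2ratio * (frTC / fBIC) * TNa.  All rates are gated
#' at run time by the Michaelis-Menten factor [O2]/(Km + [O2]).
#'
#' @param grid an `rcm_tissue`.
#' @param params an `rcm_params` object.
#' @param tna sodium transport per EPI patch, amol/min.
#' @return list with `jmax` (amol/ms, housekeeping + transport, per patch)
#'   and its components `hk` and `tna_o2`.
#' @export
consumption_rates <- function(grid, params, tna) {
  n <- length(grid$type)
  hk <- numeric(n)
  epi <- grid$type == "EPI"
  if (!is.null(grid$muscle_qo2)) {
    hk[epi] <- mmmin_to_amolms(grid$muscle_qo2, grid$volume[epi])
  } else {
    hk[epi] <- mmmin_to_amolms(params$JmaxHK_epi, grid$volume[epi])
  }
  ptc <- grid$type == "PTC"
  hk[ptc] <- mmmin_to_amolms(jmax_cap_patch(params), grid$volume[ptc])
  int <- grid$type == "INT"
  hk[int] <- mmmin_to_amolms(params$Jmax_int, grid$volume[int])
  tna_o2 <- numeric(n)
  if (is.null(grid$muscle_qo2)) {
    # TNa amol-Na/min -> amol-O2/ms: ATP per Na (1/NaATP) over ATP per O2,
    # pump-driven (transcellular) fraction only, bicarbonate-coupled
    # reabsorption proceeding at no oxygen cost
    tna_o2[epi] <- (1 / params$NaATP) / params$PO2ratio *
      (params$frTC / params$fBIC) * tna / .MS_PER_MIN
  }
  list(jmax = hk + tna_o2, hk = hk, tna_o2 = tna_o2)
}

#' One consumption tick
#'
#' Demand = jmax * M * tick with M = [O2]/(Km + [O2]) ([O2] in uM); a patch
#' never over-draws: the step consumes at most the content present.
#'
#' @param q oxygen contents, amol.
#' @param jmax maximal rates, amol/ms (from [consumption_rates()]).
#' @param params an `rcm_params` object.
#' @param volume per-patch volumes, um^3.
#' @return list with updated `q` and `consumed` (amol per patch this tick).
#' @export
consumption_step <- function(q, jmax, params, volume = 1000) {
  conc <- q * 1000 / volume           # uM
  m <- conc / (params$Km + conc)
  demand <- jmax * m * params$tick
  take <- pmin(demand, q)
  list(q = q - take, consumed = take)
}
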