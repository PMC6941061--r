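# The tick engine: simulation state, the fixed-order tick, steady-state
# detection, protocols (steady / ischemia / anoxemia / custom overrides),
# and time-series monitors.

#' Create a simulation state
#'
#' Assembles everything one run needs: the flow cascade at the requested
#' renal blood flow, per-tick renewal fractions, per-patch consumption
#' rates, the diffusion operator, and the initial oxygen field (all patches
#' at zero oxygen; capillary hemoglobin initialized at the feed-equilibrium
#' saturation).
#'
#' @param params an `rcm_params` object.
#' @param grid an `rcm_tissue`; defaults to the reference "1540" tissue.
#' @param rbf renal blood flow, FU; defaults to `params$RBF`.
#' @param ptc_feed,lum_feed feed PO2, mmHg; default from `params`.
#' @param order intra-tick operator order (a permutation of
#'   `c("conv", "hb", "diff", "cons")`).
#' @param clamp optional integer vector of patch indices whose PO2 is held
#'   fixed (after each tick) at `clamp_po2`.
#' @param clamp_po2 PO2 value(s) for clamped patches, mmHg.
#' @return an object of class `rcm_sim`.
#' @export
rcm_sim <- function(params, grid = NULL, rbf = NULL,
                    ptc_feed = NULL, lum_feed = NULL,
                    order = c("conv", "hb", "diff", "cons"),
                    clamp = integer(0), clamp_po2 = numeric(0)) {
  if (is.null(grid)) grid <- build_tissue("1540", params)
  stopifnot(setequal(order, c("conv", "hb", "diff", "cons")))
  grid <- refresh_edges(grid, params)
  rbf <- if (is.null(rbf)) params$RBF else rbf
  ptc_feed <- if (is.null(ptc_feed)) params$PTC_feed else ptc_feed
  lum_feed <- if (is.null(lum_feed)) params$LUM_feed else lum_feed
  flow <- compute_flow_cascade(params, rbf)
  ff <- flow_factors(flow, params, grid)
  tna <- sodium_transport_per_patch(flow, params, grid)
  cons <- consumption_rates(grid, params, tna)
  op <- diffusion_operator(grid, params)
  idx <- list(ptc = which(grid$type == "PTC"),
              epi = which(grid$type == "EPI"),
              lum = which(grid$type == "LUM"),
              int = which(grid$type == "INT"))
  hbt <- hb_content(params)
  s_feed <- hb_equilibrium_saturation(ptc_feed, params)
  n <- length(grid$type)
  sim <- structure(list(
    params = params, grid = grid, flow = flow, ff = ff, tna = tna,
    cons = cons, op = op, idx = idx, hbt = hbt,
    rbf = rbf, ptc_feed = ptc_feed, lum_feed = lum_feed,
    q_feed_ptc = po2_to_content(ptc_feed, params),
    q_feed_lum = po2_to_content(lum_feed, params),
    s_feed = s_feed, order = order,
    clamp = clamp, clamp_po2 = clamp_po2,
    q = numeric(n),
    sat = rep(s_feed, length(which(grid$type == "PTC"))),
    time_ms = 0), class = "rcm_sim")
  if (length(clamp)) sim$q[clamp] <- po2_to_content(clamp_po2, params)
  sim
}

#' Change run inputs of an existing simulation state
#'
#' Recomputes flows and renewal fractions for new RBF and/or feeds while
#' keeping the oxygen field.  By default the per-patch sodium transport is
#' held at its pre-change value (local reabsorption persists for a while
#' after flow stops); set `tna_follows_flow = TRUE` in the parameters to
#' re-derive TNa from the new filtration rate.
#'
#' @param sim an `rcm_sim`.
#' @param rbf,ptc_feed,lum_feed new inputs (NULL keeps the current value).
#' @return the updated `rcm_sim`.
#' @export
set_inputs <- function(sim, rbf = NULL, ptc_feed = NULL, lum_feed = NULL) {
  p <- sim$params
  if (!is.null(rbf)) {
    sim$rbf <- rbf
    sim$flow <- compute_flow_cascade(p, rbf)
    sim$ff <- flow_factors(sim$flow, p, sim$grid)
    if (isTRUE(p$tna_follows_flow)) {
      sim$tna <- sodium_transport_per_patch(sim$flow, p, sim$grid)
      sim$cons <- consumption_rates(sim$grid, p, sim$tna)
    }
  }
  if (!is.null(ptc_feed)) {
    sim$ptc_feed <- ptc_feed
    sim$q_feed_ptc <- po2_to_content(ptc_feed, p)
    sim$s_feed <- hb_equilibrium_saturation(ptc_feed, p)
  }
  if (!is.null(lum_feed)) {
    sim$lum_feed <- lum_feed
    sim$q_feed_lum <- po2_to_content(lum_feed, p)
  }
  sim
}

# volume-weighted mean PO2 over a set of patches
.mean_po2 <- function(q, params, volume, which = NULL) {
  if (!is.null(which)) { q <- q[which]; volume <- volume[which] }
  if (!length(q)) return(NA_real_)
  sum(q) * 1000 / (params$alpha * sum(volume))
}

#' Advance a simulation by a number of ticks
#'
#' Applies, in the configured order (default: convection, hemoglobin,
#' diffusion, consumption), the per-tick operators, advancing the clock by
#' `tick` ms each step and sampling the monitors every `sample_every` ms.
#'
#' @param sim an `rcm_sim`.
#' @param n_ticks number of ticks to run.
#' @param sample_every monitor sampling interval, ms (default 10).
#' @param track_budget record the per-tick oxygen budget (convective in/out,
#'   consumed, hemoglobin exchange) for conservation checks.
#' @return the `rcm_sim` with an attached `monitor` data.frame (columns
#'   time_ms, tPO2, PTC_PO2, EPI_PO2, LUM_PO2, INT_PO2, Hb_sat,
#'   QO2_total_amol_ms) and, if requested, a `budget` data.frame.
#' @export
step_ticks <- function(sim, n_ticks, sample_every = 10, track_budget = FALSE) {
  p <- sim$params
  tick <- p$tick
  q <- sim$q; sat <- sim$sat
  idx <- sim$idx; op <- sim$op
  cff <- sim$ff$CFF; tff <- sim$ff$TFF
  qfp <- sim$q_feed_ptc; qfl <- sim$q_feed_lum; sfd <- sim$s_feed
  jmax <- sim$cons$jmax
  hbt <- sim$hbt
  vol <- sim$grid$volume
  clamp <- sim$clamp
  q_clamp <- if (length(clamp)) po2_to_content(sim$clamp_po2, p) else numeric(0)
  stoich <- if (isTRUE(p$hb_monomer)) 1 else 4
  sample_ticks <- max(1L, round(sample_every / tick))
  n_samp <- floor(n_ticks / sample_ticks) + 1L
  mon <- matrix(NA_real_, n_samp, 8)
  bud <- if (track_budget) matrix(NA_real_, n_ticks, 5) else NULL
  snap <- function(row, t) {
    mon[row, ] <<- c(t,
      .mean_po2(q, p, vol),
      .mean_po2(q, p, vol, idx$ptc), .mean_po2(q, p, vol, idx$epi),
      .mean_po2(q, p, vol, idx$lum), .mean_po2(q, p, vol, idx$int),
      if (length(sat)) mean(sat) else NA_real_, last_cons / tick)
  }
  last_cons <- 0
  row <- 1L
  snap(row, sim$time_ms)
  for (k in seq_len(n_ticks)) {
    conv_in_out <- 0; consumed_tot <- 0; hb_dq <- 0
    for (step in sim$order) {
      if (step == "conv") {
        if (cff > 0 || tff > 0) {
          if (track_budget)
            conv_in_out <- conv_in_out + cff * sum(qfp - q[idx$ptc]) +
              tff * sum(qfl - q[idx$lum]) +
              cff * stoich * 0.01 * hbt * sum(sfd - sat)
          cr <- convective_renewal(q, sat, idx, cff, tff, qfp, qfl, sfd)
          q <- cr$q; sat <- cr$sat
        }
      } else if (step == "hb") {
        if (isTRUE(p$Hb_active) && length(idx$ptc)) {
          po2_ptc <- q[idx$ptc] * 1000 / (p$alpha * vol[idx$ptc])
          hs <- hb_step(sat, po2_ptc, hbt, p)
          if (track_budget) hb_dq <- sum(hs$dq)
          sat <- hs$sat
          q[idx$ptc] <- q[idx$ptc] + hs$dq
        }
      } else if (step == "diff") {
        q <- as.numeric(op$P %*% q)
      } else { # cons
        cs <- consumption_step(q, jmax, p, vol)
        q <- cs$q
        consumed_tot <- sum(cs$consumed)
      }
    }
    if (length(clamp)) q[clamp] <- q_clamp
    last_cons <- consumed_tot
    sim$time_ms <- sim$time_ms + tick
    if (track_budget)
      bud[k, ] <- c(sim$time_ms, conv_in_out, consumed_tot, hb_dq, sum(q))
    if (any(is.na(q)) || any(q < 0))
      stop("invalid oxygen content (NaN or negative) at t = ", sim$time_ms,
           " ms, patch ", which(is.na(q) | q < 0)[1])
    if (k %% sample_ticks == 0L) {
      row <- row + 1L
      snap(row, sim$time_ms)
    }
  }
  sim$q <- q; sim$sat <- sat
  mon <- mon[seq_len(row), , drop = FALSE]
  colnames(mon) <- c("time_ms", "tPO2", "PTC_PO2", "EPI_PO2", "LUM_PO2",
                     "INT_PO2", "Hb_sat", "QO2_total_amol_ms")
  sim$monitor <- as.data.frame(mon)
  if (track_budget) {
    colnames(bud) <- c("time_ms", "conv_net_amol", "consumed_amol",
                       "hb_dq_amol", "total_q_amol")
    sim$budget <- as.data.frame(bud)
  }
  sim
}

#' Volume-weighted mean tissue PO2 of a simulation state
#' @param sim an `rcm_sim`.
#' @param compartment `"tissue"` (all patches) or one of `"PTC"`, `"EPI"`,
#'   `"LUM"`, `"INT"`.
#' @return mean PO2, mmHg.
#' @export
mean_po2 <- function(sim, compartment = "tissue") {
  w <- switch(compartment, tissue = NULL,
              PTC = sim$idx$ptc, EPI = sim$idx$epi,
              LUM = sim$idx$lum, INT = sim$idx$int,
              stop("unknown compartment: ", compartment))
  .mean_po2(sim$q, sim$params, sim$grid$volume, w)
}

#' Oxygen-consumption report of a simulation state
#'
#' Instantaneous Michaelis-Menten-gated consumption at the current oxygen
#' field, split by compartment, expressed per litre of compartment volume
#' and per litre of whole tissue, per minute.
#'
#' @param sim an `rcm_sim`.
#' @return a list: `per_patch_amol_ms` (vector), `epi_mm_epi_min`
#'   (epithelial consumption, mM-EPI/min; housekeeping + transport),
#'   `epi_tna_mm_epi_min` (transport share), `ctx_mm_ctx_min`
#'   (epithelial consumption per litre of tissue), and
#'   `total_mm_ctx_min` (all compartments per litre of tissue).
#' @export
consumption_report <- function(sim) {
  g <- sim$grid
  conc <- sim$q * 1000 / g$volume
  m <- conc / (sim$params$Km + conc)
  per_patch <- sim$cons$jmax * m
  epi <- g$type == "EPI"
  v_epi <- sum(g$volume[epi])
  v_all <- sum(g$volume)
  # amol/ms -> amol/min, over um^3: 1 amol/um^3 = 1 mmol/L, hence mM/min
  to_mm_min <- function(amol_ms, vol_um3) amol_ms * .MS_PER_MIN / vol_um3
  list(per_patch_amol_ms = per_patch,
       epi_mm_epi_min = to_mm_min(sum(per_patch[epi]), v_epi),
       epi_tna_mm_epi_min = to_mm_min(sum((sim$cons$tna_o2 * m)[epi]), v_epi),
       ctx_mm_ctx_min = to_mm_min(sum(per_patch[epi]), v_all),
       total_mm_ctx_min = to_mm_min(sum(per_patch), v_all))
}

#' Run a simulation to steady state
#'
#' Iterates from the current state until, over a sliding 100-ms window, the
#' per-compartment mean PO2 changes by less than `tol` mmHg (all
#' compartments), or `max_ticks` ticks have elapsed (then warns).  Aborts
#' on divergence (any PO2 above 200 mmHg).
#'
#' @param sim an `rcm_sim` (typically fresh from [rcm_sim()]).
#' @param tol convergence tolerance, mmHg per 100 ms window (default 0.01).
#' @param max_ticks iteration cap (default 10000).
#' @param sample_every monitor sampling interval, ms.
#' @param quiet suppress the non-convergence warning.
#' @return the converged `rcm_sim`; `sim$sst_po2` holds the volume-weighted
#'   mean tissue PO2 and `sim$converged` the convergence flag.
#' @export
run_to_steady_state <- function(sim, tol = 0.01, max_ticks = 10000,
                                sample_every = 10, quiet = FALSE) {
  p <- sim$params
  window_ms <- 100
  chunk <- max(1L, round(window_ms / p$tick))
  total <- 0L
  prev <- NULL
  monitors <- list()
  converged <- FALSE
  while (total < max_ticks) {
    n <- min(chunk, max_ticks - total)
    sim <- step_ticks(sim, n, sample_every = sample_every)
    monitors[[length(monitors) + 1L]] <-
      if (length(monitors)) sim$monitor[-1, , drop = FALSE] else sim$monitor
    total <- total + n
    if (max(sim$q * 1000 / (p$alpha * sim$grid$volume)) > 200)
      stop("divergence: PO2 above 200 mmHg at t = ", sim$time_ms, " ms")
    cur <- c(mean_po2(sim), mean_po2(sim, "PTC"), mean_po2(sim, "EPI"),
             mean_po2(sim, "LUM"), mean_po2(sim, "INT"))
    if (!is.null(prev) && n == chunk &&
        all(abs(cur - prev) < tol, na.rm = TRUE)) {
      converged <- TRUE
      break
    }
    prev <- cur
  }
  if (!converged && !quiet)
    warning("steady state not reached within ", max_ticks, " ticks")
  sim$monitor <- do.call(rbind, monitors)
  sim$converged <- converged
  sim$sst_po2 <- mean_po2(sim)
  sim
}

#' Define a perturbation protocol
#'
#' @param name `"steady"`, `"ischemia"` (RBF set to zero), `"anoxemia"`
#'   (both feeds set to zero), or `"custom"`.
#' @param switch_at switch time after the pre-run, ms (>= 0).
#' @param rbf,ptc_feed,lum_feed post-switch overrides for `"custom"`.
#' @return a list of class `rcm_protocol`.
#' @export
rcm_protocol <- function(name = c("steady", "ischemia", "anoxemia", "custom"),
                         switch_at = 0, rbf = NULL, ptc_feed = NULL,
                         lum_feed = NULL) {
  name <- match.arg(name)
  if (switch_at < 0) stop("switch_at must be >= 0")
  if (name == "ischemia") rbf <- 0
  if (name == "anoxemia") { ptc_feed <- 0; lum_feed <- 0 }
  structure(list(name = name, switch_at = switch_at, rbf = rbf,
                 ptc_feed = ptc_feed, lum_feed = lum_feed),
            class = "rcm_protocol")
}

# first time a sampled series falls to `frac` of its initial value, by
# linear interpolation between samples; Inf if it never does
.crossing_time <- function(time, y, frac) {
  y0 <- y[1]
  if (!is.finite(y0) || y0 <= 0) return(NA_real_)
  target <- frac * y0
  below <- which(y <= target)
  below <- below[below > 1]
  if (!length(below)) return(Inf)
  k <- below[1]
  t0 <- time[k - 1]; t1 <- time[k]
  v0 <- y[k - 1]; v1 <- y[k]
  if (v0 == v1) return(t1)
  t0 + (v0 - target) / (v0 - v1) * (t1 - t0)
}

#' Run a transient protocol from steady state
#'
#' Establishes the pre-switch steady state, applies the protocol overrides,
#' then follows the relaxation, reporting the half-time t50 (first time
#' each tracked variable falls to half its pre-switch value, linearly
#' interpolated between samples) and the time to 10%, for the mean tissue
#' PO2, the mean capillary PO2, and the hemoglobin saturation.
#'
#' @param params an `rcm_params` object.
#' @param grid an `rcm_tissue` (NULL builds the reference tissue).
#' @param protocol an `rcm_protocol`.
#' @param horizon_ms post-switch simulated horizon, ms.
#' @param sample_every monitor sampling interval, ms.
#' @param sim optional pre-run steady-state `rcm_sim` to reuse.
#' @param max_ticks_ss cap for the pre-run steady state.
#' @return an object of class `rcm_transient`: list with `t50` and `t10pct`
#'   (named vectors over tissue/PTC/Hb_sat; `Inf` means "did not reach it
#'   within the horizon"), the pre-switch values, and the sampled `monitor`.
#' @export
run_transient <- function(params, grid = NULL, protocol = rcm_protocol("ischemia"),
                          horizon_ms = 15000, sample_every = 10,
                          sim = NULL, max_ticks_ss = 10000) {
  if (is.null(sim)) {
    sim <- rcm_sim(params, grid)
    sim <- run_to_steady_state(sim, max_ticks = max_ticks_ss)
  }
  if (protocol$switch_at > 0)
    sim <- step_ticks(sim, round(protocol$switch_at / params$tick),
                      sample_every = sample_every)
  pre <- c(tissue = mean_po2(sim), PTC = mean_po2(sim, "PTC"),
           Hb_sat = if (length(sim$sat)) mean(sim$sat) else NA_real_)
  sim$time_ms <- 0
  sim <- set_inputs(sim, rbf = protocol$rbf, ptc_feed = protocol$ptc_feed,
                    lum_feed = protocol$lum_feed)
  sim <- step_ticks(sim, round(horizon_ms / params$tick),
                    sample_every = sample_every)
  m <- sim$monitor
  t50 <- c(tissue = .crossing_time(m$time_ms, m$tPO2, 0.5),
           PTC = .crossing_time(m$time_ms, m$PTC_PO2, 0.5),
           Hb_sat = .crossing_time(m$time_ms, m$Hb_sat, 0.5))
  t10 <- c(tissue = .crossing_time(m$time_ms, m$tPO2, 0.1),
           PTC = .crossing_time(m$time_ms, m$PTC_PO2, 0.1),
           Hb_sat = .crossing_time(m$time_ms, m$Hb_sat, 0.1))
  structure(list(protocol = protocol, pre = pre, t50_ms = t50,
                 t10pct_ms = t10, monitor = m, sim = sim),
            class = "rcm_transient")
}

#' @export
print.rcm_transient <- function(x, ...) {
  cat("<rcm_transient>", x$protocol$name, "\n")
  cat("  pre-switch:", paste(sprintf("%s=%.2f", names(x$pre), x$pre),
                             collapse = "  "), "\n")
  cat("  t50 (s):   ", paste(sprintf("%s=%.3g", names(x$t50_ms),
                                     x$t50_ms / 1000), collapse = "  "), "\n")
  invisible(x)
}
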