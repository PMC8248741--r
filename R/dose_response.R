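# ATP dose-response sweeps and mechanistic flux diagnostics ------------------

#' Log-spaced ATP dose grid
#'
#' @param from,to grid limits (M), within `[1e-9, 1e-1]`.
#' @param per_decade grid density (points per decade), default 25.
#' @return strictly increasing numeric vector of doses (M).
#' @export
dose_grid <- function(from = 1e-8, to = 1e-2, per_decade = 25) {
  stopifnot(from > 0, to > from)
  10^seq(log10(from), log10(to), by = 1 / per_decade)
}

variant_protocol_args <- function(variant) {
  switch(variant,
    full = list(knockout = "none", initial_markov = "naive_C1"),
    p2y2_only = list(knockout = "p2x7", initial_markov = "naive_C1"),
    p2x7_naive = list(knockout = "p2y2", initial_markov = "naive_C1"),
    p2x7_sensitized = list(knockout = "p2y2", initial_markov = "sensitized_C4"),
    stop("unknown variant: ", variant)
  )
}

#' Sweep the ATP dose axis for one model variant
#'
#' Runs one stimulation protocol per dose and summarizes each response.
#' Variants map onto knockout/initial-pool combinations: `"full"` (wild
#' type), `"p2y2_only"` (P2X7 knockout), `"p2x7_naive"` /
#' `"p2x7_sensitized"` (P2Y2 knockout started from the C1 or C4 receptor
#' pool). Equilibration is performed once and reused across doses.
#'
#' @param variant one of `"full"`, `"p2y2_only"`, `"p2x7_naive"`,
#'   `"p2x7_sensitized"`.
#' @param grid dose grid (M), strictly increasing, within `[1e-9, 1e-1]`.
#' @param p a [model_params()] object.
#' @param duration recording window per dose (s), default 120.
#' @param dt output sampling interval (s).
#' @return object of class `dose_response`: a data frame with one row per
#'   dose and columns `ATP`, `max_Ca` (raw maximum, uM), `magnitude` (max
#'   minus resting Ca, uM), `norm_magnitude` (magnitude / curve max),
#'   `auc_0_10` (trapezoidal area under J_P2X7 over 0-10 s, uM),
#'   `max_J_P2X7`, `max_J_IP3R` (uM/s), `t_half` (s, NA when the flux never
#'   halves). Attributes: `variant`, `rest` (resting state), `params`.
#' @examples
#' \donttest{
#' crv <- sweep_dose_response("p2y2_only", dose_grid(1e-7, 1e-5, 5))
#' crv$magnitude
#' }
#' @export
sweep_dose_response <- function(variant, grid = dose_grid(),
                                p = model_params(), duration = 120,
                                dt = 0.1) {
  if (any(diff(grid) <= 0)) stop("dose grid must be strictly increasing")
  if (any(grid < 1e-9 | grid > 1e-1)) stop("doses must lie in [1e-9, 1e-1] M")
  va <- variant_protocol_args(variant)
  rest <- equilibrate(p, knockout = va$knockout,
                      initial_markov = va$initial_markov)
  rows <- lapply(grid, function(a) {
    proto <- protocol(ATP = a, duration = duration, knockout = va$knockout,
                      initial_markov = va$initial_markov, dt = dt)
    sim <- tryCatch(run_protocol(proto, p, rest = rest),
                    error = function(e) stop("dose ", a, " M: ",
                                             conditionMessage(e)))
    fd <- flux_diagnostics(sim)
    data.frame(ATP = a,
               max_Ca = max(sim$state[, "Ca_i"]),
               magnitude = max(sim$state[, "Ca_i"]) - rest[["Ca_i"]],
               auc_0_10 = fd[["auc_0_10"]],
               max_J_P2X7 = fd[["max_J_P2X7"]],
               max_J_IP3R = fd[["max_J_IP3R"]],
               t_half = fd[["t_half"]])
  })
  out <- do.call(rbind, rows)
  out$norm_magnitude <- out$magnitude / max(out$magnitude)
  out <- out[, c("ATP", "max_Ca", "magnitude", "norm_magnitude",
                 "auc_0_10", "max_J_P2X7", "max_J_IP3R", "t_half")]
  structure(out, variant = variant, rest = rest, params = p,
            class = c("dose_response", "data.frame"))
}

#' Mechanistic flux diagnostics for one simulation
#'
#' Summaries of the P2X7R and IP3R calcium fluxes used to dissect the
#' non-monotonic dose response: the trapezoidal area under the P2X7R flux
#' over the first 10 s (total early Ca2+ entry), the maximal P2X7R and
#' IP3R fluxes over the full record, and the time for the P2X7R flux to
#' decay to half of its maximum (`t_half`, linearly interpolated; `NA` if
#' the flux never falls below half-max within the record).
#'
#' @param sim a `ca_sim` from [run_protocol()] covering at least 10 s.
#' @return named numeric vector: `auc_0_10` (uM), `max_J_P2X7` (uM/s),
#'   `max_J_IP3R` (uM/s), `t_half` (s).
#' @export
flux_diagnostics <- function(sim) {
  stopifnot(inherits(sim, "ca_sim"))
  post <- sim$time >= 0
  t <- sim$time[post]
  if (max(t) < 10) stop("simulation must cover at least 10 s post-onset")
  jx7 <- sim$fluxes[post, "J_P2X7"]
  jip <- sim$fluxes[post, "J_IP3R"]

  w <- t <= 10
  auc <- sum(diff(t[w]) * (jx7[w][-1] + jx7[w][-sum(w)]) / 2)

  i_max <- which.max(jx7)
  max_jx7 <- jx7[i_max]
  t_half <- NA_real_
  if (max_jx7 > 0) {
    after <- seq(i_max, length(t))
    below <- after[jx7[after] <= max_jx7 / 2]
    if (length(below)) {
      j <- below[1]
      if (j == i_max) {
        t_half <- 0
      } else {
        # linear interpolation between the bracketing samples
        t1 <- t[j - 1]; t2 <- t[j]
        y1 <- jx7[j - 1]; y2 <- jx7[j]
        t_half <- t1 + (max_jx7 / 2 - y1) * (t2 - t1) / (y2 - y1) - t[i_max]
      }
    }
  }
  c(auc_0_10 = auc, max_J_P2X7 = max_jx7, max_J_IP3R = max(jip),
    t_half = t_half)
}

#' Locate troughs and the peak of a dose-response curve
#'
#' Finds local minima (troughs) and the global maximum (peak) of the
#' normalized magnitude versus log10 dose after a 3-point moving-median
#' pre-filter (no spline smoothing, so extrema cannot be displaced by
#' fitting). Flat runs are compressed before extremum detection; extrema
#' are reported at the nearest grid dose. A terminal grid point lower than
#' its neighbor counts as a trough only when an interior local maximum
#' precedes it (the curve has turned down after a peak); a monotone curve
#' therefore yields no troughs.
#'
#' @param curve a `dose_response` from [sweep_dose_response()], or a data
#'   frame with columns `ATP` and `magnitude` (>= 5 points per decade).
#' @return list with `trough_doses` (M, possibly empty) and `peak_dose` (M).
#' @export
find_extrema <- function(curve) {
  atp <- curve$ATP
  y <- curve$magnitude
  stopifnot(length(y) >= 3, all(diff(atp) > 0))
  if (1 / mean(diff(log10(atp))) < 5)
    stop("grid must have at least 5 points per decade")
  yf <- stats::runmed(y, 3, endrule = "keep")

  # compress flat runs so plateaus register as single candidate points
  keep <- c(TRUE, diff(yf) != 0)
  idx <- which(keep)
  z <- yf[idx]
  n <- length(z)
  troughs <- integer(0)
  peaks <- integer(0)
  if (n >= 3) {
    interior <- 2:(n - 1)
    troughs <- interior[z[interior] < z[interior - 1] & z[interior] < z[interior + 1]]
    peaks <- interior[z[interior] > z[interior - 1] & z[interior] > z[interior + 1]]
  }
  # terminal trough: curve has turned down after an interior peak
  if (n >= 2 && z[n] < z[n - 1] && length(peaks) && max(peaks) < n)
    troughs <- c(troughs, n)
  list(trough_doses = atp[idx[troughs]],
       peak_dose = atp[which.max(yf)])
}

#' High-dose plateau level of a dose-response curve
#'
#' Mean response magnitude over the top `span_decades` of the dose axis,
#' used to quantify the level a submodel curve settles at near the upper
#' end of the sweep (e.g. the P2X7-only plateaus quoted relative to the
#' wild-type curve maximum).
#'
#' @param curve a `dose_response` (or data frame with `ATP`, `magnitude`).
#' @param span_decades width of the terminal dose band (log10 units).
#' @return mean magnitude (uM) over the band.
#' @export
plateau_level <- function(curve, span_decades = 0.25) {
  top <- max(curve$ATP)
  band <- curve$ATP >= top * 10^(-span_decades)
  mean(curve$magnitude[band])
}

#' Export a dose-response curve
#'
#' Wide CSV, one row per dose, one column per summary, with the variant
#' label in a `variant` column.
#'
#' @param curve a `dose_response`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
export_dose_response <- function(curve, path) {
  df <- as.data.frame(curve)
  df$variant <- attr(curve, "variant")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("<dose_response> variant = %s, %d doses in [%g, %g] M\n",
              attr(x, "variant"), nrow(x), min(x$ATP), max(x$ATP)))
  ex <- find_extrema(x)
  cat("  peak:", format(ex$peak_dose, digits = 3), "M; troughs:",
      if (length(ex$trough_doses))
        paste(format(ex$trough_doses, digits = 3), collapse = ", ")
      else "none", "\n")
  invisible(x)
}
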