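# Synthetic single-cell ensembles -------------------------------------------

#' Specify a synthetic cell population
#'
#' Encodes the heterogeneity structure used to emulate single-cell Fura2
#' recordings: cell-to-cell lognormal variation of pump/receptor densities
#' (`v_PMCA`, `v_SERCA`, `v_IP3R`, `g_X7`) and of the initial ER Ca2+ load,
#' a mixture of naive and sensitized P2X7R pools (a cell starts from C4
#' with probability `p_sensitized`, otherwise C1), additive Gaussian
#' measurement noise, and an optional per-"cell line" shift of the dose
#' axis (log10 units) emulating line-to-line dose sensitivity differences.
#'
#' @param n_cells number of cells.
#' @param cv_v_PMCA,cv_v_SERCA,cv_v_IP3R,cv_g_X7,cv_Ca_ER coefficients of
#'   variation of the lognormal multipliers (default 0.2; 0 disables).
#' @param p_sensitized probability a cell's P2X7R pool starts sensitized
#'   (C4), in `[0, 1]`.
#' @param noise_sd additive Gaussian noise SD in signal units; default 2%
#'   of the resting Ca2+ signal (`NULL` means use that default at
#'   generation time).
#' @param dose_shift log10 dose-axis shift applied to this population's
#'   nominal doses (emulates a cell line with shifted sensitivity).
#' @param seed RNG seed recorded in every output.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(n_cells = 50, cv_v_PMCA = 0.2, cv_v_SERCA = 0.2,
                            cv_v_IP3R = 0.2, cv_g_X7 = 0.2, cv_Ca_ER = 0.2,
                            p_sensitized = 0, noise_sd = NULL,
                            dose_shift = 0, seed = 1) {
  cvs <- c(cv_v_PMCA, cv_v_SERCA, cv_v_IP3R, cv_g_X7, cv_Ca_ER)
  stopifnot(n_cells >= 1, all(cvs >= 0),
            p_sensitized >= 0, p_sensitized <= 1)
  structure(list(n_cells = n_cells, cv_v_PMCA = cv_v_PMCA,
                 cv_v_SERCA = cv_v_SERCA, cv_v_IP3R = cv_v_IP3R,
                 cv_g_X7 = cv_g_X7, cv_Ca_ER = cv_Ca_ER,
                 p_sensitized = p_sensitized, noise_sd = noise_sd,
                 dose_shift = dose_shift, seed = seed),
            class = "population_spec")
}

# lognormal multiplier with unit median and given CV
rlnorm_mult <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
}

#' Generate a synthetic single-cell trace ensemble
#'
#' For each cell, draws parameter multipliers and the initial P2X7R pool
#' according to the spec, runs the stimulation protocol at every dose
#' (dose axis shifted by `spec$dose_shift`), perturbs the initial ER load,
#' and adds measurement noise. Identical parameter draws (e.g. when all
#' CVs are zero) share one ODE solution. Fully reproducible from
#' `spec$seed`; the seed and spec are attached to the result and embedded
#' by [write_traces()].
#'
#' @param spec a [population_spec()].
#' @param doses nominal dose grid (M).
#' @param p a [model_params()] object (population medians).
#' @param knockout,duration,baseline,dt protocol settings (see
#'   [protocol()]); `baseline` defaults to 10 s of pre-stimulus record for
#'   baseline estimation.
#' @return list of [ca_trace()] objects (one per cell x dose) with
#'   metadata `cell`, `dose` (nominal, M), `line_shift`, `sensitized`;
#'   attributes `spec` and `excluded` (count of solver-failed cells).
#' @export
generate_population <- function(spec, doses, p = model_params(),
                                knockout = "none", duration = 120,
                                baseline = 10, dt = 0.1) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  n <- spec$n_cells
  mult <- data.frame(
    v_PMCA = rlnorm_mult(n, spec$cv_v_PMCA),
    v_SERCA = rlnorm_mult(n, spec$cv_v_SERCA),
    v_IP3R = rlnorm_mult(n, spec$cv_v_IP3R),
    g_X7 = rlnorm_mult(n, spec$cv_g_X7),
    Ca_ER = rlnorm_mult(n, spec$cv_Ca_ER)
  )
  sensitized <- stats::runif(n) < spec$p_sensitized
  noise_sd <- spec$noise_sd   # resolved per cell below (2% of resting)

  traces <- list()
  excluded <- 0L
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    cell_p <- p
    cell_p$v_PMCA <- p$v_PMCA * mult$v_PMCA[i]
    cell_p$v_SERCA <- p$v_SERCA * mult$v_SERCA[i]
    cell_p$v_IP3R <- p$v_IP3R * mult$v_IP3R[i]
    cell_p$g_X7 <- p$g_X7 * mult$g_X7[i]
    validate_params(cell_p)
    pool <- if (sensitized[i]) "sensitized_C4" else "naive_C1"
    key_base <- paste(paste(signif(unlist(mult[i, ]), 12), collapse = "|"),
                      pool, sep = "|")
    for (a in doses) {
      a_eff <- a * 10^spec$dose_shift
      key <- paste(key_base, a_eff, sep = "|")
      if (exists(key, envir = cache, inherits = FALSE)) {
        sim <- get(key, envir = cache)
      } else {
        sim <- tryCatch({
          rest <- equilibrate(cell_p, knockout = knockout,
                              initial_markov = pool)
          rest[["Ca_ER"]] <- rest[["Ca_ER"]] * mult$Ca_ER[i]
          run_protocol(protocol(ATP = a_eff, duration = duration,
                                knockout = knockout, initial_markov = pool,
                                baseline = baseline, dt = dt),
                       cell_p, rest = rest)
        }, error = function(e) "FAILED")
        assign(key, sim, envir = cache)
      }
      if (identical(sim, "FAILED")) { excluded <- excluded + 1L; next }
      sdn <- if (is.null(noise_sd)) 0.02 * sim$diagnostics$rest[["Ca_i"]]
             else noise_sd
      sig <- sim$state[, "Ca_i"] + stats::rnorm(length(sim$time), 0, sdn)
      traces[[length(traces) + 1L]] <- ca_trace(
        sim$time, sig, onset = 0,
        meta = list(cell = sprintf("cell%03d", i), dose = a,
                    line_shift = spec$dose_shift,
                    sensitized = sensitized[i], seed = spec$seed)
      )
    }
  }
  attr(traces, "spec") <- spec
  attr(traces, "excluded") <- excluded
  traces
}

#' Magnitude distribution and modality call
#'
#' Kernel-density summary of single-cell response magnitudes at one dose
#' plus a bimodality call: Gaussian mixtures with one and two components
#' are fitted (equal-variance and free-variance families) and two modes are
#' declared when the two-component fit improves BIC by more than
#' `delta_bic` (default 10).
#'
#' @param traces ensemble from [generate_population()] (or any list of
#'   `ca_trace` with `dose` metadata).
#' @param dose dose (M) selecting the traces to analyze.
#' @param min_cells minimum number of cells for a modality call (default
#'   50; below it the call is withheld as `NA`).
#' @param delta_bic BIC margin declaring bimodality.
#' @return list with `magnitudes`, `density` (stats::density), `modality`
#'   (`"unimodal"`, `"bimodal"` or NA), `delta_bic`, `component_means`,
#'   `mixing_weights`.
#' @importFrom mclust Mclust mclustBIC
#' @export
magnitude_distribution <- function(traces, dose, min_cells = 50,
                                   delta_bic = 10) {
  sel <- Filter(function(tr) isTRUE(all.equal(tr$meta$dose, dose)), traces)
  mags <- vapply(sel, function(tr) {
    f <- extract_features(tr)
    if (isTRUE(f$responded)) f$magnitude else NA_real_
  }, numeric(1))
  mags <- mags[is.finite(mags)]
  out <- list(magnitudes = mags,
              density = if (length(mags) >= 2) stats::density(mags) else NULL,
              modality = NA_character_, delta_bic = NA_real_,
              component_means = NA_real_, mixing_weights = NA_real_)
  if (length(mags) < min_cells) return(out)
  fit1 <- Mclust(mags, G = 1, verbose = FALSE)
  fit2 <- Mclust(mags, G = 2, modelNames = c("E", "V"), verbose = FALSE)
  # mclust BIC is on the "larger is better" scale
  dbic <- max(fit2$BIC, na.rm = TRUE) - max(fit1$BIC, na.rm = TRUE)
  out$delta_bic <- dbic
  if (dbic > delta_bic) {
    out$modality <- "bimodal"
    out$component_means <- as.numeric(fit2$parameters$mean)
    out$mixing_weights <- as.numeric(fit2$parameters$pro)
  } else {
    out$modality <- "unimodal"
    out$component_means <- as.numeric(fit1$parameters$mean)
    out$mixing_weights <- 1
  }
  out
}

#' Align dose-response curves across cell lines
#'
#' Harmonizes per-line dose-response profiles: each curve's log10 dose-axis
#' shift relative to a reference curve is estimated by maximizing the
#' cross-correlation of the magnitude profiles on a common interpolated
#' log-dose grid; the shift is applied and each curve min-max rescaled to
#' `[0, 1]`. Flat (featureless) curves cannot be aligned and are refused.
#'
#' @param curves named list of data frames with columns `ATP` (M) and
#'   `magnitude`; the first is the reference.
#' @param shift_range log10 shift search window, default `c(-1.5, 1.5)`.
#' @param shift_step search resolution (log10 units), default 0.02.
#' @return list with `aligned` (list of data frames with `log10_ATP`
#'   shifted and `scaled` in `[0,1]`) and `shifts` (named numeric,
#'   reference = 0).
#' @export
align_dose_curves <- function(curves, shift_range = c(-1.5, 1.5),
                              shift_step = 0.02) {
  stopifnot(length(curves) >= 2)
  if (is.null(names(curves)))
    names(curves) <- paste0("line", seq_along(curves))
  prep <- lapply(curves, function(cv) {
    if (diff(range(cv$magnitude)) <= 0)
      stop("flat curve cannot be aligned")
    data.frame(x = log10(cv$ATP),
               y = (cv$magnitude - min(cv$magnitude)) /
                 diff(range(cv$magnitude)))
  })
  ref <- prep[[1]]
  shifts <- stats::setNames(numeric(length(curves)), names(curves))
  cand <- seq(shift_range[1], shift_range[2], by = shift_step)
  for (k in seq_along(prep)[-1]) {
    cur <- prep[[k]]
    score <- vapply(cand, function(s) {
      xs <- cur$x - s
      lo <- max(min(ref$x), min(xs)); hi <- min(max(ref$x), max(xs))
      if (hi - lo < 1) return(-Inf)  # require >= 1 decade of overlap
      gx <- seq(lo, hi, length.out = 100)
      a <- stats::approx(ref$x, ref$y, gx)$y
      b <- stats::approx(xs, cur$y, gx)$y
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(-Inf)
      stats::cor(a, b)
    }, numeric(1))
    shifts[k] <- cand[which.max(score)]
  }
  aligned <- Map(function(pr, s) {
    data.frame(log10_ATP = pr$x - s, scaled = pr$y)
  }, prep, shifts)
  list(aligned = aligned, shifts = shifts)
}
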