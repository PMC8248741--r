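# Single-cell Ca2+ trace featurization --------------------------------------

#' Construct a calcium trace
#'
#' Container for one single-cell Ca2+ recording (simulated or synthetic)
#' in arbitrary signal units (e.g. Fura2 ratio or uM).
#'
#' @param time uniform time grid (s).
#' @param signal signal values, same length as `time`.
#' @param onset stimulus onset time (s), within the record.
#' @param meta optional named list (cell id, dose, line label, ...).
#' @return object of class `ca_trace`.
#' @export
ca_trace <- function(time, signal, onset = 0, meta = list()) {
  stopifnot(length(time) == length(signal), length(time) >= 2)
  dt <- diff(time)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
    stop("trace must be uniformly sampled")
  if (onset < time[1] || onset > time[length(time)])
    stop("onset must lie within the record")
  structure(list(time = time, signal = signal, onset = onset, meta = meta),
            class = "ca_trace")
}

#' Extract a calcium trace from a simulation
#'
#' @param sim a `ca_sim` from [run_protocol()].
#' @param meta optional metadata list.
#' @return a [ca_trace()] of the cytosolic Ca2+ signal with onset at 0.
#' @export
as_ca_trace <- function(sim, meta = list()) {
  stopifnot(inherits(sim, "ca_sim"))
  meta <- utils::modifyList(list(ATP = sim$protocol$ATP,
                                 knockout = sim$protocol$knockout), meta)
  ca_trace(sim$time, sim$state[, "Ca_i"], onset = 0, meta = meta)
}

# local maxima with topographic prominence; returns indices and prominences
find_peaks <- function(y) {
  n <- length(y)
  if (n < 3) return(data.frame(index = integer(0), prominence = numeric(0)))
  idx <- which(diff(sign(diff(y))) < 0) + 1L
  # a plateau maximum registers at its first sample
  prom <- vapply(idx, function(i) {
    # walk left/right to the first strictly higher point, tracking minima
    left_min <- y[i]
    jl <- i - 1L
    while (jl >= 1L && y[jl] <= y[i]) {
      left_min <- min(left_min, y[jl]); jl <- jl - 1L
    }
    if (jl < 1L) left_min <- min(y[1:i])
    right_min <- y[i]
    jr <- i + 1L
    while (jr <= n && y[jr] <= y[i]) {
      right_min <- min(right_min, y[jr]); jr <- jr + 1L
    }
    if (jr > n) right_min <- min(y[i:n])
    y[i] - max(left_min, right_min)
  }, numeric(1))
  data.frame(index = idx, prominence = prom)
}

#' Featurize a calcium trace
#'
#' Quantifies the standard single-cell response parameters: baseline
#' (pre-onset mean, or the first sample when no pre-onset data exist),
#' response magnitude (post-onset maximum minus baseline), activation time
#' (onset to the first crossing of baseline + 10% of magnitude), peak count
#' and oscillation measures. Peaks are local maxima of a lightly smoothed
#' trace (3-sample moving average) with topographic prominence of at least
#' `prominence_frac` of the magnitude; the response is called oscillatory
#' when at least `min_secondary_peaks` peaks follow the primary one, with
#' period the median inter-peak interval of the post-primary peaks and
#' oscillation magnitude the mean prominence of the secondary peaks.
#'
#' @param trace a [ca_trace()].
#' @param prominence_frac peak prominence threshold as a fraction of the
#'   response magnitude (default 0.025). Damped Ca2+ oscillation trains
#'   halve in amplitude roughly every cycle, so late peaks of a genuine
#'   train carry prominences of a few percent of the primary transient; at
#'   the same time the threshold must sit far above measurement noise
#'   (2.5% of a typical response is >20 noise SD for Fura2-grade noise
#'   after smoothing). All thresholds here are operational choices and are
#'   exposed as arguments.
#' @param activation_frac activation threshold, fraction of magnitude.
#' @param min_secondary_peaks secondary peaks needed for the oscillatory
#'   call (default 2).
#' @param noise_floor absolute magnitude below which the cell is called
#'   non-responding (default 5 standard deviations of the pre-onset signal
#'   -- above the expected maximum of ~1000 baseline noise samples -- or 0
#'   when no pre-onset samples exist).
#' @param smooth_k moving-average window (samples).
#' @return one-row data frame: `responded`, `baseline`, `magnitude`,
#'   `activation_time` (s), `oscillatory`, `n_secondary_peaks`,
#'   `period` (s, NA unless >= 2 secondary peaks), `osc_magnitude`, `auc`
#'   (signal-seconds above baseline). Non-responding traces yield
#'   `responded = FALSE` and NA features.
#' @examples
#' t <- seq(-10, 110, 0.1)
#' y <- ifelse(t < 0, 1, 1 + 0.5 * exp(-t / 30) * sin(2 * pi * t / 15))
#' extract_features(ca_trace(t, y, onset = 0))
#' @export
extract_features <- function(trace, prominence_frac = 0.025,
                             activation_frac = 0.10,
                             min_secondary_peaks = 2,
                             noise_floor = NULL, smooth_k = 3) {
  stopifnot(inherits(trace, "ca_trace"))
  t <- trace$time; y <- trace$signal
  pre <- t < trace$onset
  post <- t >= trace$onset
  if (sum(post) * stats::median(diff(t)) < 30)
    stop("need at least 30 s of post-onset signal")
  baseline <- if (any(pre)) mean(y[pre]) else y[post][1]
  if (is.null(noise_floor))
    noise_floor <- if (sum(pre) >= 3) 5 * stats::sd(y[pre]) else 0

  tp <- t[post]; yp <- y[post]
  magnitude <- max(yp) - baseline
  na_row <- data.frame(responded = FALSE, baseline = baseline,
                       magnitude = NA_real_, activation_time = NA_real_,
                       oscillatory = NA, n_secondary_peaks = NA_integer_,
                       period = NA_real_, osc_magnitude = NA_real_,
                       auc = NA_real_)
  if (magnitude <= noise_floor || magnitude <= 0) return(na_row)

  thresh <- baseline + activation_frac * magnitude
  cross <- which(yp >= thresh)[1]
  activation_time <- tp[cross] - trace$onset

  ys <- if (smooth_k > 1) as.numeric(stats::filter(yp, rep(1 / smooth_k, smooth_k),
                                                   sides = 2)) else yp
  ys[is.na(ys)] <- yp[is.na(ys)]
  pk <- find_peaks(ys)
  pk <- pk[pk$prominence >= prominence_frac * magnitude &
             ys[pk$index] >= thresh, , drop = FALSE]

  n_sec <- 0L; period <- NA_real_; osc_mag <- NA_real_
  if (nrow(pk) >= 1) {
    primary <- pk$index[which.max(ys[pk$index])]
    sec <- pk[pk$index > primary, , drop = FALSE]
    n_sec <- nrow(sec)
    if (n_sec >= 2) {
      period <- stats::median(diff(tp[c(primary, sec$index)]))
      osc_mag <- mean(sec$prominence)
    } else if (n_sec == 1) {
      osc_mag <- sec$prominence
    }
  }
  oscillatory <- n_sec >= min_secondary_peaks
  dt <- stats::median(diff(tp))
  data.frame(responded = TRUE, baseline = baseline, magnitude = magnitude,
             activation_time = activation_time, oscillatory = oscillatory,
             n_secondary_peaks = n_sec, period = period,
             osc_magnitude = osc_mag,
             auc = sum(pmax(yp - baseline, 0)) * dt)
}

#' Summarize features across a population
#'
#' Per-dose means with standard errors and the oscillatory fraction,
#' optionally normalizing each summary to its own maximum across doses
#' (peak dose-response normalization).
#'
#' @param features data frame of per-cell features (rows from
#'   [extract_features()]) with a `dose` column.
#' @param normalize normalize per-dose means to their curve maximum.
#' @return data frame, one row per dose: `dose`, `n`, `n_responding`,
#'   `mean_magnitude`, `sem_magnitude`, `mean_activation_time`,
#'   `sem_activation_time`, `oscillatory_fraction`.
#' @export
population_summary <- function(features, normalize = FALSE) {
  stopifnot("dose" %in% names(features))
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  out <- do.call(rbind, lapply(split(features, features$dose), function(g) {
    r <- g[g$responded %in% TRUE, , drop = FALSE]
    data.frame(dose = g$dose[1], n = nrow(g), n_responding = nrow(r),
               mean_magnitude = mean(r$magnitude),
               sem_magnitude = sem(r$magnitude),
               mean_activation_time = mean(r$activation_time),
               sem_activation_time = sem(r$activation_time),
               oscillatory_fraction = mean(r$oscillatory))
  }))
  out <- out[order(out$dose), ]
  rownames(out) <- NULL
  if (normalize) {
    for (cn in c("mean_magnitude", "mean_activation_time"))
      out[[cn]] <- out[[cn]] / max(out[[cn]], na.rm = TRUE)
  }
  out
}

#' Read / write trace ensembles
#'
#' Long CSV (`cell`, `time`, `value`) with a JSON sidecar carrying per-cell
#' metadata (onset, dose, line, seed).
#'
#' @param traces list of [ca_trace()] objects.
#' @param path CSV output path.
#' @return `write_traces()` returns `path` invisibly; `read_traces()`
#'   returns a list of `ca_trace`.
#' @export
write_traces <- function(traces, path) {
  ids <- vapply(seq_along(traces), function(i) {
    id <- traces[[i]]$meta$cell
    if (is.null(id)) paste0("cell", i) else as.character(id)
  }, character(1))
  long <- do.call(rbind, Map(function(tr, id) {
    data.frame(cell = id, time = tr$time, value = tr$signal)
  }, traces, ids))
  utils::write.csv(long, path, row.names = FALSE)
  meta <- Map(function(tr, id) c(list(cell = id, onset = tr$onset), tr$meta),
              traces, ids)
  names(meta) <- ids
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  long <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = FALSE)
  lapply(split(long, long$cell), function(g) {
    m <- meta[[as.character(g$cell[1])]]
    onset <- if (!is.null(m$onset)) m$onset else 0
    m$onset <- NULL
    ca_trace(g$time, g$value, onset = onset, meta = m)
  })
}
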