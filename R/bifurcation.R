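# Slow-fast analysis: oscillatory region in the (IP3, Ca_ER) plane ----------

# [IP3] and [Ca2+]_ER vary slowly relative to Ca_i and h, so the P2Y2-only
# submodel (J_P2X7 = 0) is analyzed as a 2-D fast subsystem in (Ca_i, h)
# with the slow variables frozen as parameters. Oscillations arise where
# the fast equilibrium is unstable with a complex eigenvalue pair (between
# the two Hopf bifurcations bounding the region).

fast_rhs <- function(Ca, h, IP3, Ca_ER, p) {
  g <- gating_functions(IP3, max(Ca, 0), p)
  Jip3r <- p$v_IP3R * (g$m_inf * g$n_inf * h)^3 * (Ca_ER - Ca)
  dCa <- p$f_c * (p$J_INleak + Jip3r + p$v_ERleak * (Ca_ER - Ca) -
                    pump_flux(max(Ca, 0), p$v_PMCA, p$k_PMCA) -
                    pump_flux(max(Ca, 0), p$v_SERCA, p$k_SERCA))
  dh <- p$a2 * (g$Q2_gate - (g$Q2_gate + max(Ca, 0)) * h)
  c(dCa, dh)
}

fast_jacobian <- function(Ca, h, IP3, Ca_ER, p, eps = 1e-7) {
  # central finite differences, scaled steps
  dCa <- max(abs(Ca), 1e-3) * eps
  dh <- max(abs(h), 1e-3) * eps
  fC <- (fast_rhs(Ca + dCa, h, IP3, Ca_ER, p) -
           fast_rhs(Ca - dCa, h, IP3, Ca_ER, p)) / (2 * dCa)
  fH <- (fast_rhs(Ca, h + dh, IP3, Ca_ER, p) -
           fast_rhs(Ca, h - dh, IP3, Ca_ER, p)) / (2 * dh)
  matrix(c(fC, fH), 2, 2)
}

#' Fast-subsystem equilibrium and its stability
#'
#' Solves the two-variable fast subsystem (cytosolic Ca2+ and the IP3R
#' inactivation gate h, with `J_P2X7 = 0`) for its fixed point at frozen
#' `[IP3]` and `[Ca2+]_ER`, and classifies it by the eigenvalues of the
#' 2x2 Jacobian. At equilibrium h = h_inf(Ca), so the fixed point reduces
#' to a 1-D root problem in Ca, located by sign-change scanning (optionally
#' seeded from a neighboring solution during continuation) and refined with
#' [stats::uniroot()].
#'
#' @param IP3,Ca_ER frozen slow variables (uM), non-negative.
#' @param p a [model_params()] object.
#' @param Ca_seed optional warm start (uM) from a neighboring grid point.
#' @return list with `IP3`, `Ca_ER`, `Ca_i`, `h`, `eigenvalues` (complex
#'   length-2), `oscillatory` (TRUE iff max Re > 0 with Im != 0), `ok`
#'   (FALSE when no root was found).
#' @export
fast_equilibrium <- function(IP3, Ca_ER, p = model_params(), Ca_seed = NULL) {
  stopifnot(IP3 >= 0, Ca_ER >= 0)
  f1 <- function(Ca) {
    h <- gating_functions(IP3, Ca, p)$h_inf
    fast_rhs(Ca, h, IP3, Ca_ER, p)[1]
  }
  root <- NULL
  lo <- 1e-5; hi <- max(10, Ca_ER)
  if (!is.null(Ca_seed) && is.finite(Ca_seed) && Ca_seed > 0) {
    # bracket around the warm start first
    for (w in c(1.2, 2, 5)) {
      a <- Ca_seed / w; b <- Ca_seed * w
      if (f1(a) * f1(b) < 0) {
        root <- stats::uniroot(f1, c(a, b), tol = 1e-12)$root
        break
      }
    }
  }
  if (is.null(root)) {
    grid <- 10^seq(log10(lo), log10(hi), length.out = 200)
    fv <- vapply(grid, f1, numeric(1))
    sc <- which(fv[-1] * fv[-length(fv)] < 0)
    if (length(sc)) {
      k <- sc[1]
      root <- stats::uniroot(f1, grid[c(k, k + 1)], tol = 1e-12)$root
    }
  }
  if (is.null(root))
    return(list(IP3 = IP3, Ca_ER = Ca_ER, Ca_i = NA_real_, h = NA_real_,
                eigenvalues = c(NA_complex_, NA_complex_),
                oscillatory = NA, ok = FALSE))
  h <- gating_functions(IP3, root, p)$h_inf
  ev <- eigen(fast_jacobian(root, h, IP3, Ca_ER, p), only.values = TRUE)$values
  ev <- as.complex(ev)
  osc <- max(Re(ev)) > 0 && any(Im(ev) != 0)
  list(IP3 = IP3, Ca_ER = Ca_ER, Ca_i = root, h = h,
       eigenvalues = ev, oscillatory = osc, ok = TRUE)
}

#' Map the oscillatory region of the slow-variable plane
#'
#' Classifies a dense grid over `[IP3] x [Ca2+]_ER` by fast-subsystem
#' stability, sweeping Ca_ER at fixed IP3 with warm-started continuation,
#' and extracts the Hopf boundary as the zero contour of the eigenvalue
#' real part (restricted to complex pairs, so saddle-node crossings are not
#' mistaken for Hopf points).
#'
#' @param IP3_range,Ca_ER_range numeric length-2 windows (uM). Defaults
#'   cover IP3 up to the saturating steady state `alpha_ATP/delta` and
#'   Ca_ER from 10% of rest to the resting value.
#' @param resolution grid points per axis (>= 50 for publication-quality
#'   boundaries; smaller grids are accepted for quick looks).
#' @param p a [model_params()] object.
#' @return object of class `osc_region`: list with `IP3`, `Ca_ER` (axis
#'   grids), `re` and `im` (matrices of the leading eigenvalue pair, IP3 in
#'   rows), `mask` (logical oscillatory matrix), `boundary` (list of
#'   data frames with the Hopf polylines), `params`.
#' @export
map_oscillatory_region <- function(IP3_range = NULL, Ca_ER_range = NULL,
                                   resolution = 60, p = model_params()) {
  if (is.null(IP3_range)) IP3_range <- c(0, p$alpha_ATP / p$delta)
  if (is.null(Ca_ER_range)) {
    rest_er <- equilibrate(p)[["Ca_ER"]]
    Ca_ER_range <- c(0.1 * rest_er, rest_er)
  }
  stopifnot(all(IP3_range >= 0), all(Ca_ER_range >= 0), resolution >= 10)
  ip3 <- seq(IP3_range[1], IP3_range[2], length.out = resolution)
  cer <- seq(Ca_ER_range[1], Ca_ER_range[2], length.out = resolution)
  re <- im <- matrix(NA_real_, resolution, resolution)
  for (i in seq_along(ip3)) {
    seed <- NULL
    for (j in seq_along(cer)) {
      eq <- fast_equilibrium(ip3[i], cer[j], p, Ca_seed = seed)
      if (eq$ok) {
        seed <- eq$Ca_i
        k <- which.max(Re(eq$eigenvalues))
        re[i, j] <- Re(eq$eigenvalues[k])
        im[i, j] <- abs(Im(eq$eigenvalues[k]))
      } else {
        seed <- NULL
      }
    }
  }
  mask <- !is.na(re) & re > 0 & im > 0
  # Hopf boundary: Re = 0 contour where the pair is complex
  cl <- grDevices::contourLines(x = ip3, y = cer, z = re, levels = 0)
  boundary <- lapply(cl, function(seg) {
    df <- data.frame(IP3 = seg$x, Ca_ER = seg$y)
    # frequency along the boundary via bilinear interpolation of Im
    df$im <- bilinear_at(ip3, cer, im, df$IP3, df$Ca_ER)
    df[!is.na(df$im) & df$im > 0, , drop = FALSE]
  })
  boundary <- boundary[vapply(boundary, nrow, integer(1)) > 0]
  structure(list(IP3 = ip3, Ca_ER = cer, re = re, im = im, mask = mask,
                 boundary = boundary, params = p),
            class = "osc_region")
}

# bilinear interpolation of matrix z (x in rows, y in cols) at points (xi, yi);
# NA outside the grid
bilinear_at <- function(x, y, z, xi, yi) {
  out <- rep(NA_real_, length(xi))
  inside <- xi >= x[1] & xi <= x[length(x)] & yi >= y[1] & yi <= y[length(y)]
  for (k in which(inside)) {
    i <- findInterval(xi[k], x, rightmost.closed = TRUE)
    j <- findInterval(yi[k], y, rightmost.closed = TRUE)
    i <- min(max(i, 1), length(x) - 1)
    j <- min(max(j, 1), length(y) - 1)
    tx <- (xi[k] - x[i]) / (x[i + 1] - x[i])
    ty <- (yi[k] - y[j]) / (y[j + 1] - y[j])
    v <- z[i, j] * (1 - tx) * (1 - ty) + z[i + 1, j] * tx * (1 - ty) +
      z[i, j + 1] * (1 - tx) * ty + z[i + 1, j + 1] * tx * ty
    out[k] <- v
  }
  out
}

#' @export
print.osc_region <- function(x, ...) {
  cat(sprintf("<osc_region> %d x %d grid, IP3 in [%g, %g] uM, Ca_ER in [%g, %g] uM\n",
              length(x$IP3), length(x$Ca_ER), min(x$IP3), max(x$IP3),
              min(x$Ca_ER), max(x$Ca_ER)))
  cat(sprintf("  oscillatory fraction: %.1f%%; %d Hopf boundary segment(s)\n",
              100 * mean(x$mask, na.rm = TRUE), length(x$boundary)))
  invisible(x)
}

#' Classify a trajectory against the oscillatory region
#'
#' Projects the slow variables `([IP3](t), [Ca2+]_ER(t))` of a simulated
#' response onto the mapped region and measures the time spent inside.
#' Labels follow the three response scenarios: `"outside"` (never enters),
#' `"transits"` (inside for less than `dwell_threshold`), `"dwells"`
#' (inside at least `dwell_threshold`).
#'
#' @param sim a `ca_sim`, normally from a P2X7-knockout protocol (the
#'   region is computed for the P2Y2-only fast subsystem).
#' @param region an `osc_region` from [map_oscillatory_region()].
#' @param dwell_threshold dwell/transit cut (s), default 10 (about one
#'   oscillation period).
#' @return list with `label`, `dwell_time` (s), `inside` (logical per
#'   sample).
#' @export
classify_trajectory <- function(sim, region, dwell_threshold = 10) {
  stopifnot(inherits(sim, "ca_sim"), inherits(region, "osc_region"))
  post <- sim$time >= 0
  ip3 <- sim$state[post, "IP3"]
  cer <- sim$state[post, "Ca_ER"]
  if (max(ip3) < min(region$IP3) || min(ip3) > max(region$IP3) ||
      max(cer) < min(region$Ca_ER) || min(cer) > max(region$Ca_ER))
    stop("trajectory does not overlap the mapped region window")
  re_i <- bilinear_at(region$IP3, region$Ca_ER, region$re, ip3, cer)
  im_i <- bilinear_at(region$IP3, region$Ca_ER, region$im, ip3, cer)
  inside <- !is.na(re_i) & re_i > 0 & !is.na(im_i) & im_i > 0
  dt <- stats::median(diff(sim$time[post]))
  dwell <- sum(inside) * dt
  label <- if (dwell == 0) "outside"
    else if (dwell < dwell_threshold) "transits" else "dwells"
  list(label = label, dwell_time = dwell, inside = inside)
}

#' Export an oscillatory-region map
#'
#' Grid CSV (`IP3`, `Ca_ER`, `re_lambda`, `im_lambda`, `oscillatory`) plus
#' a boundary polyline CSV at `<path>_boundary.csv`.
#'
#' @param region an `osc_region`.
#' @param path CSV output path for the grid.
#' @return `path`, invisibly.
#' @export
export_region <- function(region, path) {
  grid <- expand.grid(IP3 = region$IP3, Ca_ER = region$Ca_ER)
  grid$re_lambda <- as.vector(region$re)
  grid$im_lambda <- as.vector(region$im)
  grid$oscillatory <- as.vector(region$mask)
  utils::write.csv(grid, path, row.names = FALSE)
  if (length(region$boundary)) {
    b <- do.call(rbind, Map(function(seg, k) cbind(segment = k, seg),
                            region$boundary, seq_along(region$boundary)))
    utils::write.csv(b, sub("\\.csv$", "_boundary.csv", path),
                     row.names = FALSE)
  }
  invisible(path)
}
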