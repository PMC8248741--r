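# shared fixtures and memoized heavy computations

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, fn) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE))
    assign(name, fn(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

default_params <- function() memo("params", model_params)

rest_state <- function(knockout = "none", pool = "naive_C1") {
  memo(paste("rest", knockout, pool),
       function() equilibrate(default_params(), knockout = knockout,
                              initial_markov = pool))
}

# damped sinusoid with known period: baseline + A exp(-t/tau) sin(2 pi t / T)
damped_sine_trace <- function(T = 15, A = 0.5, tau = 40, baseline = 1,
                              duration = 120, dt = 0.1, pre = 10,
                              noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(-pre, duration, by = dt)
  y <- baseline + ifelse(t < 0, 0, A * exp(-t / tau) * sin(2 * pi * t / T))
  if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
  ca_trace(t, y, onset = 0)
}

# minimal ca_sim with prescribed P2X7/IP3R flux time-courses (for the
# flux-diagnostics unit oracles)
synthetic_sim <- function(time, j_p2x7, j_ip3r = 0 * time) {
  state <- matrix(0, length(time), 16,
                  dimnames = list(NULL, c("Ca_i", "Ca_ER", "IP3", "h",
                                          "C1", "C2", "Q1", "Q2", "C3", "C4",
                                          "Q3", "Q4", "D1", "D2", "D3", "D4")))
  fluxes <- matrix(0, length(time), 6,
                   dimnames = list(NULL, c("J_INleak", "J_P2X7", "J_PMCA",
                                           "J_IP3R", "J_ERleak", "J_SERCA")))
  fluxes[, "J_P2X7"] <- j_p2x7
  fluxes[, "J_IP3R"] <- j_ip3r
  structure(list(time = time, state = state, fluxes = fluxes,
                 protocol = protocol(ATP = 1e-5),
                 diagnostics = list(rest = state[1, ], markov_drift = 0)),
            class = "ca_sim")
}

# eigen-decomposition matrix exponential (independent propagation oracle)
expm_eigen <- function(G, t) {
  e <- eigen(G)
  Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
}

# Verify by time-domain simulation that a nudge across a boundary point
# switches damped <-> sustained oscillation. The nudge is 5% of the value
# but at least one grid cell (the interpolated boundary is only accurate to
# the cell size); the axis is chosen from the eigenvalue map so the inside
# point is decisively unstable (Re > re_min) -- near-marginal points need
# limit-cycle growth times far beyond any feasible integration horizon.
# Returns TRUE/FALSE for a verifiable point, NA when no usable axis exists.
hopf_switch <- function(ip3, cer, p, region, frac = 0.05, thr = 0.02,
                        re_min = 0.015) {
  d_i <- max(frac * ip3, mean(diff(region$IP3)))
  d_c <- max(frac * cer, mean(diff(region$Ca_ER)))
  cand <- list(c(ip3, cer - d_c, ip3, cer + d_c),
               c(max(ip3 - d_i, 0), cer, ip3 + d_i, cer))
  for (cc in cand) {
    re1 <- bilinear_re(region, cc[1], cc[2])
    re2 <- bilinear_re(region, cc[3], cc[4])
    if (any(is.na(c(re1, re2)))) next
    if (re1 > re_min && re2 < 0) {
      inn <- cc[1:2]; out <- cc[3:4]
    } else if (re2 > re_min && re1 < 0) {
      inn <- cc[3:4]; out <- cc[1:2]
    } else next
    return(fast_amplitude(inn[1], inn[2], p, t_end = 1500) > thr &&
             fast_amplitude(out[1], out[2], p, t_end = 1500) < thr)
  }
  NA
}

bilinear_re <- function(region, ip3, cer)
  P2CaSim:::bilinear_at(region$IP3, region$Ca_ER, region$re, ip3, cer)

# long-run fast-subsystem integration; returns late-window oscillation
# amplitude (sustained limit cycle iff positive)
fast_amplitude <- function(IP3, Ca_ER, p, t_end = 600, Ca0 = 0.1) {
  rhs <- function(t, y, parms)
    list(P2CaSim:::fast_rhs(y[1], y[2], IP3, Ca_ER, p))
  h0 <- gating_functions(IP3, Ca0, p)$h_inf
  out <- deSolve::ode(c(Ca0, h0), seq(0, t_end, 0.25), rhs, NULL,
                      method = "lsoda", rtol = 1e-9, atol = 1e-11)
  late <- out[out[, 1] >= t_end / 2, 2]
  diff(range(late))
}
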