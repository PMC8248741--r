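test_that("default parameters reproduce the published table and invariants", {
  p <- default_params()
  expect_equal(p$f_c, 0.01)
  expect_equal(p$d2, 1.049)
  expect_equal(p$k7, 316)
  expect_equal(p$H2_Q2, 0.8)
  expect_true(p$f_c < p$f_ER && p$f_ER < 1)
  expect_true(p$H2_C2 < p$H2_Q1 && p$H2_Q1 < p$H2_Q2)
  expect_error(model_params(bogus = 1), "unknown parameter")
  expect_error(model_params(f_c = 0.05), "f_c < f_ER")
  expect_error(model_params(H2_Q2 = 0.001), "H2_C2 < H2_Q1 < H2_Q2")
})

test_that("parameter config files round-trip", {
  p <- model_params(v_IP3R = 12.5)
  for (ext in c("yaml", "json")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_params(p, f)
    q <- read_params(f)
    expect_equal(unclass(q), unclass(p))
  }
  shipped <- system.file("extdata", "default_params.yaml", package = "P2CaSim")
  expect_equal(unclass(read_params(shipped)), unclass(model_params()))
})

test_that("gating functions match their closed forms", {
  p <- default_params()
  expect_equal(gating_functions(p$d1, 0.1, p)$m_inf, 0.5)
  expect_equal(gating_functions(0.2, p$d5, p)$n_inf, 0.5)
  # IP3 = 0: Q2_gate = d2 d1 / d3; half-inactivation and tau at Ca = Q2_gate
  g0 <- gating_functions(0, 0, p)
  q2 <- 1.049 * 0.13 / 0.9434
  expect_equal(g0$Q2_gate, q2, tolerance = 1e-12)
  gq <- gating_functions(0, q2, p)
  expect_equal(gq$h_inf, 0.5, tolerance = 1e-12)
  expect_equal(gq$tau_h, 1 / (0.2 * 2 * q2), tolerance = 1e-12)
  expect_equal(gq$tau_h, 17.2947, tolerance = 1e-4)
  expect_error(gating_functions(-1, 0.1, p), "non-negative")
  expect_error(gating_functions(0.1, -1, p), "non-negative")
})

test_that("pump and leak fluxes follow their Hill/linear forms", {
  expect_equal(pump_flux(0, 30, 0.45), 0)
  expect_equal(pump_flux(0.45, 30, 0.45), 15)
  expect_equal(pump_flux(0.105, 22.5, 0.105), 11.25)
  ca <- seq(0, 5, 0.01)
  expect_true(all(diff(pump_flux(ca, 30, 0.45)) > 0))
  p <- default_params()
  s <- model_state(Ca_i = 0.1, Ca_ER = 100)
  expect_equal(er_leak_flux(s, p), 0.03 * 99.9)
  s_eq <- model_state(Ca_i = 5, Ca_ER = 5)
  expect_equal(er_leak_flux(s_eq, p), 0)
  # antisymmetry
  s_rev <- model_state(Ca_i = 100, Ca_ER = 0.1)
  expect_equal(er_leak_flux(s_rev, p), -er_leak_flux(s, p))
})

test_that("IP3R flux vanishes without gradient or gate and is biphasic in Ca", {
  p <- default_params()
  expect_equal(ip3r_flux(model_state(Ca_i = 2, Ca_ER = 2, IP3 = 1, h = 0.5), p), 0)
  expect_equal(ip3r_flux(model_state(Ca_i = 0.1, Ca_ER = 50, IP3 = 1, h = 0), p), 0)
  # steady-state open probability vs Ca_i has exactly one interior maximum
  for (ip3 in c(0.3, 0.5, 1)) {
    ca <- seq(1e-3, 2, length.out = 2000)
    po <- vapply(ca, function(x) {
      g <- gating_functions(ip3, x, p)
      (g$m_inf * g$n_inf * g$h_inf)^3
    }, numeric(1))
    n_max <- sum(diff(sign(diff(po))) == -2)
    expect_identical(n_max, 1L)
    i_max <- which.max(po)
    expect_true(i_max > 1 && i_max < length(po))
  }
})

test_that("P2X7 generator conserves probability and is ATP-linear in binding", {
  p <- default_params()
  for (a in c(0, 1e-6, 1e-3, 1e-2)) {
    G <- p2x7_transition_matrix(a, p)
    expect_lt(max(abs(colSums(G))), 1e-12)
  }
  expect_error(p2x7_transition_matrix(-1e-3, p), "non-negative")
  # binding entries scale linearly with ATP
  G1 <- p2x7_transition_matrix(1e-3, p)
  G2 <- p2x7_transition_matrix(2e-3, p)
  expect_equal(G2["C2", "C1"], 2 * G1["C2", "C1"])
  expect_equal(G2["C4", "C3"], 2 * G1["C4", "C3"])
  # state-dependent desensitization and recovery wiring
  expect_equal(G1["D2", "C2"], p$H2_C2)
  expect_equal(G1["D3", "Q1"], p$H2_Q1)
  expect_equal(G1["D4", "Q2"], p$H2_Q2)
  expect_equal(G1["C1", "D1"], p$H1)
})

test_that("at zero ATP the naive unbound pool is invariant", {
  p <- default_params()
  G <- p2x7_transition_matrix(0, p)
  x0 <- c(1, rep(0, 11))
  # no outflow from C1 and matrix-exponential propagation stays put
  expect_equal(as.numeric(G %*% x0), rep(0, 12))
  x_t <- expm_eigen(G, 2000) %*% x0
  expect_equal(as.numeric(x_t), x0, tolerance = 1e-9)
})

test_that("generator ODE propagation agrees with the matrix exponential", {
  p <- default_params()
  G <- p2x7_transition_matrix(1e-3, p)
  x0 <- c(1, rep(0, 11))
  oracle <- as.numeric(expm_eigen(G, 1) %*% x0)
  rhs <- function(t, y, parms) list(as.numeric(G %*% y))
  out <- deSolve::ode(x0, c(0, 1), rhs, NULL, method = "lsoda",
                      rtol = 1e-12, atol = 1e-14)
  expect_equal(as.numeric(out[2, -1]), oracle, tolerance = 1e-8)
})

test_that("P2X7 current/flux conversion matches unit arithmetic", {
  p <- default_params()
  s_open <- model_state(Ca_i = 0.1, Ca_ER = 50,
                        markov = c(0, 0, 0.5, 0.5, rep(0, 8)))
  fx <- p2x7_flux(s_open, p)
  expect_equal(fx$I, 2.5e-8 * 1 * (-0.06))
  # J = -f_Ca I / (z F V), M -> uM
  expect_equal(fx$J, 0.046 * 1.5e-9 / (2 * 96485 * 6.5e-12) * 1e6,
               tolerance = 1e-12)
  expect_equal(fx$J, 55.0106, tolerance = 1e-4)
  # closed pool: zero; linear in total open fraction
  s_closed <- model_state(Ca_i = 0.1, Ca_ER = 50, markov = "naive_C1")
  expect_equal(p2x7_flux(s_closed, p)$J, 0)
  s_half <- model_state(Ca_i = 0.1, Ca_ER = 50,
                        markov = c(0.5, 0, 0.25, 0.25, rep(0, 8)))
  expect_equal(p2x7_flux(s_half, p)$J, fx$J / 2)
})

test_that("full right-hand side obeys IP3 closed forms and conservation", {
  p <- default_params()
  s0 <- model_state(Ca_i = 0.1, Ca_ER = 50, IP3 = 0, h = 0.8)
  expect_equal(full_rhs(s0, 0, p)[["IP3"]], 0)
  s1 <- model_state(Ca_i = 0.1, Ca_ER = 50, IP3 = 2, h = 0.8)
  expect_equal(full_rhs(s1, 0, p)[["IP3"]], -p$delta * 2)
  # at ATP = k_ATP the IP3 steady state is alpha/(2 delta) = 1.5 uM
  s_ss <- model_state(Ca_i = 0.1, Ca_ER = 50, IP3 = 1.5, h = 0.8)
  expect_equal(full_rhs(s_ss, 1e-6, p)[["IP3"]], 0, tolerance = 1e-15)
  # Markov derivatives sum to zero at an arbitrary mixed state
  mk <- rep(1 / 12, 12)
  s_mix <- model_state(Ca_i = 0.2, Ca_ER = 30, IP3 = 0.5, h = 0.6, markov = mk)
  d <- full_rhs(s_mix, 1e-4, p)
  expect_lt(abs(sum(d[5:16])), 1e-12)
  expect_error(full_rhs(s_mix, 1e-4, p, knockout = "p2x4"))
  # knockouts zero exactly the targeted flux contribution
  d_p2y2 <- full_rhs(s_mix, 1e-4, p, knockout = "p2y2")
  expect_equal(d_p2y2[["Ca_ER"]],
               p$f_ER * p$gamma * (pump_flux(0.2, p$v_SERCA, p$k_SERCA) -
                                     er_leak_flux(s_mix, p)))
})

test_that("state validation enforces physical ranges", {
  expect_error(model_state(Ca_i = -1, Ca_ER = 50), "non-negative")
  expect_error(model_state(Ca_i = 0.1, Ca_ER = 50, h = 1.2), "h must")
  expect_error(model_state(Ca_i = 0.1, Ca_ER = 50, markov = rep(0.1, 12)),
               "sum to 1")
  expect_error(model_state(Ca_i = 0.1, Ca_ER = 50, markov = "primed"),
               "unknown markov")
})
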