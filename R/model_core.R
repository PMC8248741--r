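# Model state layout -------------------------------------------------------

# 16 dynamical quantities: cytosolic and ER free Ca2+ (uM), IP3 (uM), the
# Li-Rinzel slow inactivation gate h, and the 12 P2X7R Markov state
# fractions. Markov rows: naive C1 C2 Q1 Q2, sensitized C3 C4 Q3 Q4,
# desensitized D1 D2 D3 D4 (Ci/Di closed, Qi open).
STATE_NAMES <- c("Ca_i", "Ca_ER", "IP3", "h",
                 "C1", "C2", "Q1", "Q2",
                 "C3", "C4", "Q3", "Q4",
                 "D1", "D2", "D3", "D4")
MARKOV_NAMES <- STATE_NAMES[5:16]
Q_NAMES <- c("Q1", "Q2", "Q3", "Q4")

#' Construct a model state vector
#'
#' @param Ca_i,Ca_ER,IP3 concentrations (uM), non-negative.
#' @param h IP3R inactivation gate in `[0, 1]`.
#' @param markov length-12 vector of P2X7R state fractions (named or in the
#'   order C1, C2, Q1, Q2, C3, C4, Q3, Q4, D1, D2, D3, D4), or one of the
#'   shorthand strings `"naive_C1"` / `"sensitized_C4"` placing all mass in
#'   the corresponding closed state.
#' @return named numeric vector of length 16 (class `ca_state`).
#' @examples
#' s <- model_state(Ca_i = 0.05, Ca_ER = 60, IP3 = 0, h = 0.8)
#' sum(s[5:16]) # Markov fractions sum to 1
#' @export
model_state <- function(Ca_i, Ca_ER, IP3 = 0, h = 0.8, markov = "naive_C1") {
  if (is.character(markov)) {
    mk <- stats::setNames(numeric(12), MARKOV_NAMES)
    mk[switch(markov,
      naive_C1 = "C1",
      sensitized_C4 = "C4",
      stop("unknown markov shorthand: ", markov))] <- 1
  } else {
    stopifnot(length(markov) == 12)
    mk <- as.numeric(markov)
    names(mk) <- MARKOV_NAMES
  }
  s <- c(Ca_i = Ca_i, Ca_ER = Ca_ER, IP3 = IP3, h = h, mk)
  validate_state(s)
  s
}

#' Validate a model state
#'
#' Concentrations must be non-negative, `h` in `[0,1]`, Markov fractions in
#' `[0,1]` and summing to 1 within `tol`.
#' @param s state vector as returned by [model_state()].
#' @param tol tolerance on the Markov probability sum (default 1e-9).
#' @return `s` invisibly; errors on violation.
#' @export
validate_state <- function(s, tol = 1e-9) {
  stopifnot(is.numeric(s), length(s) == 16)
  if (is.null(names(s))) names(s) <- STATE_NAMES
  if (any(s[c("Ca_i", "Ca_ER", "IP3")] < 0))
    stop("concentrations must be non-negative")
  if (s["h"] < 0 || s["h"] > 1) stop("h must lie in [0, 1]")
  mk <- s[MARKOV_NAMES]
  if (any(mk < -tol) || any(mk > 1 + tol))
    stop("Markov fractions must lie in [0, 1]")
  if (abs(sum(mk) - 1) > tol)
    stop("Markov fractions must sum to 1 (got ", format(sum(mk)), ")")
  invisible(s)
}

# Gating & fluxes -----------------------------------------------------------

#' Li-Rinzel IP3R gating functions
#'
#' Instantaneous activation gates and the slow-inactivation equilibrium of
#' the Li-Rinzel IP3 receptor model. Activation by IP3 (`m_inf`) and by
#' cytosolic Ca2+ (`n_inf`) are Michaelian; inactivation by Ca2+ relaxes to
#' `h_inf` with time constant `tau_h`, where the effective Ca2+ affinity of
#' the inactivation site `Q2_gate = d2 (IP3 + d1)/(IP3 + d3)` itself depends
#' on IP3. (`Q2_gate` is a gating auxiliary, unrelated to the Markov state Q2.)
#'
#' @param IP3,Ca_i concentrations (uM), non-negative.
#' @param p a [model_params()] object.
#' @return list with `m_inf`, `n_inf`, `h_inf` (dimensionless in `[0,1]`),
#'   `tau_h` (s), `Q2_gate` (uM).
#' @examples
#' g <- gating_functions(IP3 = 0.13, Ca_i = 0.08234, model_params())
#' g$m_inf # 0.5 at IP3 = d1
#' @export
gating_functions <- function(IP3, Ca_i, p = model_params()) {
  if (any(IP3 < 0) || any(Ca_i < 0))
    stop("IP3 and Ca_i must be non-negative")
  Q2_gate <- p$d2 * (IP3 + p$d1) / (IP3 + p$d3)
  list(
    m_inf = IP3 / (IP3 + p$d1),
    n_inf = Ca_i / (Ca_i + p$d5),
    h_inf = Q2_gate / (Q2_gate + Ca_i),
    tau_h = 1 / (p$a2 * (Q2_gate + Ca_i)),
    Q2_gate = Q2_gate
  )
}

#' IP3R calcium release flux
#'
#' `J_IP3R = v_IP3R m_inf^3 n_inf^3 h^3 (Ca_ER - Ca_i)`. The cubic gate
#' product is the channel open probability; the Ca2+ dependence through
#' `n_inf` (activation) and `h` (inactivation) makes the steady-state open
#' probability biphasic in cytosolic Ca2+ (calcium-induced calcium release).
#'
#' @param state a [model_state()] vector.
#' @param p a [model_params()] object.
#' @return flux in uM/s (positive = ER to cytosol).
#' @export
ip3r_flux <- function(state, p = model_params()) {
  g <- gating_functions(state[["IP3"]], state[["Ca_i"]], p)
  p$v_IP3R * (g$m_inf * g$n_inf * state[["h"]])^3 *
    (state[["Ca_ER"]] - state[["Ca_i"]])
}

#' Hill-type Ca2+ pump flux (PMCA / SERCA)
#'
#' @param Ca_i cytosolic Ca2+ (uM), non-negative.
#' @param v maximal pump rate (uM/s).
#' @param k half-activating Ca2+ (uM).
#' @return `v Ca_i^2 / (Ca_i^2 + k^2)` in uM/s.
#' @export
pump_flux <- function(Ca_i, v, k) {
  if (any(Ca_i < 0)) stop("Ca_i must be non-negative")
  v * Ca_i^2 / (Ca_i^2 + k^2)
}

#' Passive ER leak flux
#'
#' @inheritParams ip3r_flux
#' @return `v_ERleak (Ca_ER - Ca_i)` in uM/s.
#' @export
er_leak_flux <- function(state, p = model_params()) {
  p$v_ERleak * (state[["Ca_ER"]] - state[["Ca_i"]])
}

# P2X7R Markov model --------------------------------------------------------

#' P2X7R Markov generator matrix
#'
#' Builds the 12x12 generator G of the P2X7 receptor gating scheme, so that
#' the state-fraction vector x (order C1, C2, Q1, Q2, C3, C4, Q3, Q4,
#' D1..D4) evolves as dx/dt = G x. Columns sum to zero (probability
#' conservation).
#'
#' Topology: each receptor carries three ATP binding sites, two occupied
#' for opening; along each row, forward transitions bind ATP
#' (rate proportional to `[ATP]`) and backward transitions unbind. The
#' naive row binds at k2, k4, k6 and the sensitized row at k7; unbinding
#' uses k1, k3, k5 in both. Sensitization accelerates with ATP occupancy:
#' slow from partially bound states (L1, C2 to C4 and Q1 to Q3) and fast
#' from the fully bound open state (L3, Q2 to Q4); all sensitized states
#' recover to their naive counterparts at L2. Desensitization
#' leaves the naive row with ATP-occupancy-dependent rates
#' (`H2_C2 < H2_Q1 < H2_Q2`); the desensitized row recovers at H1 and, by
#' default, retains the binding/unbinding ladder (rates of the sensitized
#' row; disable with `desensitized_ladder = FALSE`). With
#' `use_multiplicity = TRUE`, binding/unbinding carry statistical factors
#' (3,2,1)/(1,2,3) along each row.
#'
#' @param ATP applied ATP concentration in molar (M), non-negative.
#' @param p a [model_params()] object.
#' @return 12x12 generator matrix with dimnames.
#' @examples
#' G <- p2x7_transition_matrix(1e-3, model_params())
#' max(abs(colSums(G))) # 0: conservation
#' @export
p2x7_transition_matrix <- function(ATP, p = model_params()) {
  if (ATP < 0) stop("ATP must be non-negative")
  G <- matrix(0, 12, 12, dimnames = list(MARKOV_NAMES, MARKOV_NAMES))
  add <- function(from, to, rate) {
    # rate(from -> to): inflow at [to, from], outflow on diagonal
    G[to, from] <<- G[to, from] + rate
    G[from, from] <<- G[from, from] - rate
  }
  bm <- if (isTRUE(p$use_multiplicity)) c(3, 2, 1) else c(1, 1, 1)
  um <- if (isTRUE(p$use_multiplicity)) c(1, 2, 3) else c(1, 1, 1)

  ladder <- function(states, kb, ku) {
    # states: closed0, closed1, open2, open3; kb: binding rates per step
    add(states[1], states[2], bm[1] * kb[1] * ATP)
    add(states[2], states[3], bm[2] * kb[2] * ATP)
    add(states[3], states[4], bm[3] * kb[3] * ATP)
    add(states[2], states[1], um[1] * ku[1])
    add(states[3], states[2], um[2] * ku[2])
    add(states[4], states[3], um[3] * ku[3])
  }
  ku <- c(p$k1, p$k3, p$k5)
  ladder(c("C1", "C2", "Q1", "Q2"), c(p$k2, p$k4, p$k6), ku)       # naive
  ladder(c("C3", "C4", "Q3", "Q4"), c(p$k7, p$k7, p$k7), ku)       # sensitized
  if (isTRUE(p$desensitized_ladder))
    ladder(c("D1", "D2", "D3", "D4"), c(p$k7, p$k7, p$k7), ku)     # desensitized

  # naive -> sensitized: like desensitization, sensitization accelerates
  # with ATP occupancy -- slow from partially bound states (L1), fast from
  # the fully bound open state (L3)
  add("C2", "C4", p$L1); add("Q1", "Q3", p$L1)
  add("Q2", "Q4", p$L3)
  # sensitized -> naive recovery (slow, L2)
  add("C3", "C1", p$L2); add("C4", "C2", p$L2)
  add("Q3", "Q1", p$L2); add("Q4", "Q2", p$L2)
  # desensitization from naive row, rate grows with ATP occupancy
  add("C2", "D2", p$H2_C2); add("Q1", "D3", p$H2_Q1); add("Q2", "D4", p$H2_Q2)
  # slow recovery from the desensitized row to the naive counterpart
  add("D1", "C1", p$H1); add("D2", "C2", p$H1)
  add("D3", "Q1", p$H1); add("D4", "Q2", p$H1)
  G
}

#' P2X7R current and calcium flux
#'
#' All four open states share conductance `g_X7`; the whole-cell current is
#' `I = g_X7 (Q1+Q2+Q3+Q4) (V_mem - E)` and the cytosolic Ca2+ flux is the
#' calcium-carried fraction of that current converted to concentration
#' units, `J = -f_Ca I / (z F V_osteo)` (reported in uM/s). With the
#' resting potential below the reversal potential the current is inward and
#' `J >= 0`.
#'
#' @inheritParams ip3r_flux
#' @return list with `I` (amperes) and `J` (uM/s).
#' @export
p2x7_flux <- function(state, p = model_params()) {
  sumQ <- sum(state[Q_NAMES])
  I <- p$g_X7 * sumQ * (p$V_mem - p$E)
  list(I = I, J = x7_flux_coefficient(p) * sumQ)
}

#' All six calcium fluxes at a state
#'
#' @inheritParams ip3r_flux
#' @param ATP applied ATP (M); only used for consistency of the returned
#'   record (fluxes themselves do not depend on ATP at fixed state).
#' @return named numeric vector: `J_INleak`, `J_P2X7`, `J_PMCA`, `J_IP3R`,
#'   `J_ERleak`, `J_SERCA` (uM/s).
#' @export
flux_vector <- function(state, p = model_params(), ATP = 0) {
  c(J_INleak = p$J_INleak,
    J_P2X7 = p2x7_flux(state, p)$J,
    J_PMCA = pump_flux(state[["Ca_i"]], p$v_PMCA, p$k_PMCA),
    J_IP3R = ip3r_flux(state, p),
    J_ERleak = er_leak_flux(state, p),
    J_SERCA = pump_flux(state[["Ca_i"]], p$v_SERCA, p$k_SERCA))
}

# Right-hand side -----------------------------------------------------------

#' Full model right-hand side
#'
#' Time derivative of the 16-component state at fixed `[ATP]`:
#' \deqn{dCa_i/dt = f_c (J_{INleak} + J_{P2X7} - J_{PMCA} + J_{IP3R} + J_{ERleak} - J_{SERCA})}
#' \deqn{dCa_{ER}/dt = f_{ER} \gamma (J_{SERCA} - J_{IP3R} - J_{ERleak})}
#' \deqn{dIP3/dt = \alpha_{ATP} [ATP]/([ATP] + k_{ATP}) - \delta IP3}
#' plus the Li-Rinzel `h` relaxation and the Markov generator acting on the
#' 12 receptor fractions. Knockout variants zero the corresponding flux
#' (not the upstream signaling): `"p2y2"` zeroes `J_IP3R`, `"p2x7"` zeroes
#' `J_P2X7`.
#'
#' @param state a [model_state()] vector.
#' @param ATP applied ATP (M).
#' @param p a [model_params()] object.
#' @param knockout one of `"none"`, `"p2y2"`, `"p2x7"`.
#' @param G optional precomputed generator from
#'   [p2x7_transition_matrix()] (recomputed if `NULL`).
#' @return named numeric vector of 16 time derivatives.
#' @export
full_rhs <- function(state, ATP, p = model_params(),
                     knockout = c("none", "p2y2", "p2x7"), G = NULL) {
  knockout <- match.arg(knockout)
  if (ATP < 0) stop("ATP must be non-negative")
  if (is.null(G)) G <- p2x7_transition_matrix(ATP, p)
  Ca <- state[["Ca_i"]]; CaER <- state[["Ca_ER"]]
  IP3 <- state[["IP3"]]; h <- state[["h"]]
  mk <- state[MARKOV_NAMES]

  g <- gating_functions(IP3, Ca, p)
  J_ip3r <- if (knockout == "p2y2") 0 else
    p$v_IP3R * (g$m_inf * g$n_inf * h)^3 * (CaER - Ca)
  J_x7 <- if (knockout == "p2x7") 0 else
    x7_flux_coefficient(p) * sum(mk[Q_NAMES])
  J_er <- p$v_ERleak * (CaER - Ca)
  J_serca <- pump_flux(Ca, p$v_SERCA, p$k_SERCA)
  J_pmca <- pump_flux(Ca, p$v_PMCA, p$k_PMCA)

  # k_ATP is tabulated in uM; ATP is handled in M package-wide
  k_ATP_M <- p$k_ATP * 1e-6
  dIP3 <- p$alpha_ATP * ATP / (ATP + k_ATP_M) - p$delta * IP3

  d <- c(
    p$f_c * (p$J_INleak + J_x7 - J_pmca + J_ip3r + J_er - J_serca),
    p$f_ER * p$gamma * (J_serca - J_ip3r - J_er),
    dIP3,
    (g$h_inf - h) / g$tau_h,
    as.numeric(G %*% mk)
  )
  names(d) <- STATE_NAMES
  d
}
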