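test_that("closed IP3R gives a stable fast equilibrium for any ER load", {
  p <- default_params()
  for (cer in c(10, 30, 60)) {
    eq <- fast_equilibrium(0, cer, p)
    expect_true(eq$ok)
    expect_false(eq$oscillatory)
    expect_lt(max(Re(eq$eigenvalues)), 0)
    # fixed-point residual
    expect_lt(max(abs(P2CaSim:::fast_rhs(eq$Ca_i, eq$h, 0, cer, p))), 1e-9)
  }
})

test_that("a nonempty oscillatory region exists, bounded by Hopf curves", {
  p <- default_params()
  reg <- memo("region40", function() map_oscillatory_region(resolution = 40,
                                                            p = p))
  expect_gt(sum(reg$mask, na.rm = TRUE), 0)
  expect_gt(length(reg$boundary), 0)
  # boundary points carry nonzero imaginary parts (Hopf, not saddle-node)
  for (b in reg$boundary) expect_true(all(b$im > 0))
  # boundary oscillation periods 2 pi / Im within a loosely physiological
  # band (one to a few tens of seconds)
  periods <- 2 * pi / unlist(lapply(reg$boundary, `[[`, "im"))
  expect_true(all(periods > 0.5 & periods < 120))
})

test_that("no CICR means no oscillatory region", {
  p <- model_params(v_IP3R = 0)
  reg <- map_oscillatory_region(IP3_range = c(0, 3), Ca_ER_range = c(10, 60),
                                resolution = 12, p = p)
  expect_equal(sum(reg$mask, na.rm = TRUE), 0L)
})

test_that("linear classification agrees with long-run fast-subsystem simulation", {
  p <- default_params()
  reg <- memo("region40", function() map_oscillatory_region(resolution = 40,
                                                            p = p))
  set.seed(42)
  idx <- which(!is.na(reg$re))
  # sample points well inside / outside (|Re| away from 0 so transients
  # settle within the integration horizon)
  strong <- idx[abs(reg$re[idx]) > 0.01]
  pick <- c(sample(strong[reg$mask[strong]], 4),
            sample(strong[!reg$mask[strong]], 4))
  for (k in pick) {
    i <- (k - 1) %% length(reg$IP3) + 1
    j <- (k - 1) %/% length(reg$IP3) + 1
    amp <- fast_amplitude(reg$IP3[i], reg$Ca_ER[j], p)
    if (reg$mask[i, j]) expect_gt(amp, 0.02) else expect_lt(amp, 0.02)
  }
})

test_that("crossing the Hopf boundary switches damped and sustained dynamics", {
  p <- default_params()
  reg <- memo("region40", function() map_oscillatory_region(resolution = 40,
                                                            p = p))
  b <- reg$boundary[[1]]
  pts <- b[round(seq(2, nrow(b) - 1, length.out = 8)), ]
  # one side sustains a limit cycle, the other damps out
  checks <- vapply(seq_len(nrow(pts)), function(r)
    hopf_switch(pts$IP3[r], pts$Ca_ER[r], p, reg), logical(1))
  expect_gte(sum(!is.na(checks)), 3)
  expect_true(all(checks[!is.na(checks)]))
})

test_that("Hopf bifurcations are supercritical (amplitude grows from zero)", {
  p <- default_params()
  reg <- memo("region40", function() map_oscillatory_region(resolution = 40,
                                                            p = p))
  b <- reg$boundary[[1]]
  pt <- b[round(nrow(b) / 2), ]
  # find which side is oscillatory, then scan amplitude vs distance
  s <- if (fast_amplitude(pt$IP3, pt$Ca_ER * 0.97, p, t_end = 1500) > 0.02)
    -1 else 1
  dist <- c(0.005, 0.02, 0.06)
  amps <- vapply(dist, function(d)
    fast_amplitude(pt$IP3, pt$Ca_ER * (1 + s * d), p, t_end = 1500),
    numeric(1))
  # amplitude grows continuously from zero across the boundary
  expect_true(all(diff(amps) > 0))
  expect_lt(amps[1], 0.75 * amps[3])
})

test_that("region mask is stable under grid refinement up to one coarse cell", {
  p <- default_params()
  win_ip3 <- c(0.2, 1.2); win_cer <- c(8, 30)
  coarse <- map_oscillatory_region(win_ip3, win_cer, resolution = 15, p = p)
  fine <- map_oscillatory_region(win_ip3, win_cer, resolution = 29, p = p)
  # compare coarse nodes against the co-located fine nodes (every 2nd)
  sub <- fine$mask[seq(1, 29, 2), seq(1, 29, 2)]
  expect_gt(sum(coarse$mask), 0)
  disagree <- which(sub != coarse$mask, arr.ind = TRUE)
  # classifications agree on the vast majority of co-located nodes
  expect_lt(nrow(disagree) / length(sub), 0.1)
  # any disagreement must touch the boundary: a neighboring coarse cell has
  # the opposite classification
  for (r in seq_len(nrow(disagree))) {
    i <- disagree[r, 1]; j <- disagree[r, 2]
    ni <- max(1, i - 1):min(15, i + 1)
    nj <- max(1, j - 1):min(15, j + 1)
    expect_true(any(coarse$mask[ni, nj] != coarse$mask[i, j]))
  }
})

test_that("trajectory classification requires window overlap", {
  p <- default_params()
  reg <- map_oscillatory_region(IP3_range = c(2.5, 3), Ca_ER_range = c(55, 60),
                                resolution = 10, p = p)
  sim <- run_protocol(protocol(ATP = 1e-7, duration = 40, knockout = "p2x7"),
                      p, rest = rest_state(knockout = "p2x7"))
  expect_error(classify_trajectory(sim, reg), "overlap")
})
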