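test_that("degenerate spec reproduces the deterministic model exactly", {
  p <- default_params()
  spec <- population_spec(n_cells = 3, cv_v_PMCA = 0, cv_v_SERCA = 0,
                          cv_v_IP3R = 0, cv_g_X7 = 0, cv_Ca_ER = 0,
                          p_sensitized = 0, noise_sd = 0, seed = 1)
  ens <- generate_population(spec, doses = 1e-5, p, duration = 40)
  expect_length(ens, 3)
  ref <- run_protocol(protocol(ATP = 1e-5, duration = 40, baseline = 10),
                      p, rest = rest_state())
  for (tr in ens) expect_equal(tr$signal, unname(ref$state[, "Ca_i"]))
  expect_identical(attr(ens, "excluded"), 0L)
})

test_that("ensembles are reproducible from the seed", {
  spec <- population_spec(n_cells = 4, p_sensitized = 0.5, seed = 11)
  e1 <- generate_population(spec, doses = 1e-3, duration = 30,
                            knockout = "p2y2")
  e2 <- generate_population(spec, doses = 1e-3, duration = 30,
                            knockout = "p2y2")
  for (i in seq_along(e1)) expect_identical(e1[[i]]$signal, e2[[i]]$signal)
  spec2 <- population_spec(n_cells = 4, p_sensitized = 0.5, seed = 12)
  e3 <- generate_population(spec2, doses = 1e-3, duration = 30,
                            knockout = "p2y2")
  expect_false(identical(e1[[1]]$signal, e3[[1]]$signal))
})

test_that("heterogeneity produces spread that shrinks with n", {
  p <- default_params()
  spec <- population_spec(n_cells = 60, cv_g_X7 = 0.3, cv_v_PMCA = 0.3,
                          cv_v_SERCA = 0, cv_v_IP3R = 0, cv_Ca_ER = 0,
                          noise_sd = 0, seed = 3)
  ens <- generate_population(spec, doses = 1e-2, p, knockout = "p2y2",
                             duration = 40)
  mags <- vapply(ens, function(tr) {
    f <- extract_features(tr)
    f$magnitude
  }, numeric(1))
  expect_true(stats::sd(mags) > 0)
  sem_full <- stats::sd(mags) / sqrt(length(mags))
  sem_sub <- stats::sd(mags[1:15]) / sqrt(15)
  # SEM ~ 1/sqrt(n): quartering n roughly doubles the SEM
  expect_gt(sem_sub / sem_full, 1.2)
  expect_lt(sem_sub / sem_full, 3.5)
})

test_that("naive/sensitized mixtures yield bimodal magnitudes at high dose", {
  p <- default_params()
  spec <- population_spec(n_cells = 80, cv_v_PMCA = 0, cv_v_SERCA = 0,
                          cv_v_IP3R = 0, cv_g_X7 = 0, cv_Ca_ER = 0,
                          p_sensitized = 0.5, seed = 5)
  ens <- generate_population(spec, doses = 1e-2, p, knockout = "p2y2",
                             duration = 120)
  md <- magnitude_distribution(ens, dose = 1e-2)
  expect_identical(md$modality, "bimodal")
  # component means sit near the two deterministic submodel magnitudes
  det_naive <- max(run_protocol(protocol(ATP = 1e-2, knockout = "p2y2"), p,
                                rest = rest_state(knockout = "p2y2"))$state[, "Ca_i"]) -
    rest_state(knockout = "p2y2")[["Ca_i"]]
  rs <- rest_state(knockout = "p2y2", pool = "sensitized_C4")
  det_sens <- max(run_protocol(protocol(ATP = 1e-2, knockout = "p2y2",
                                        initial_markov = "sensitized_C4"), p,
                               rest = rs)$state[, "Ca_i"]) - rs[["Ca_i"]]
  cm <- sort(md$component_means)
  expect_equal(cm[1], det_naive, tolerance = 0.05)
  expect_equal(cm[2], det_sens, tolerance = 0.05)
})

test_that("single-pool populations are unimodal", {
  p <- default_params()
  spec <- population_spec(n_cells = 60, cv_v_PMCA = 0, cv_v_SERCA = 0,
                          cv_v_IP3R = 0, cv_g_X7 = 0, cv_Ca_ER = 0,
                          p_sensitized = 0, seed = 9)
  ens <- generate_population(spec, doses = 1e-2, p, knockout = "p2y2",
                             duration = 60)
  md <- magnitude_distribution(ens, dose = 1e-2)
  expect_identical(md$modality, "unimodal")
  # too few cells: call withheld
  md2 <- magnitude_distribution(ens[1:10], dose = 1e-2)
  expect_true(is.na(md2$modality))
})

test_that("dose-axis alignment recovers a known synthetic shift", {
  atp <- 10^seq(-8, -2, by = 0.05)
  shape <- function(l) 1 / (1 + exp(-(l + 5) * 2)) - 0.3 * exp(-((l + 3) / 0.4)^2)
  ref <- data.frame(ATP = atp, magnitude = shape(log10(atp)))
  shifted <- data.frame(ATP = atp, magnitude = shape(log10(atp) - 0.5))
  out <- align_dose_curves(list(ref = ref, moved = shifted))
  expect_equal(unname(out$shifts["moved"]), 0.5, tolerance = 0.05)
  expect_equal(unname(out$shifts["ref"]), 0)
  # self-alignment gives zero shift
  out2 <- align_dose_curves(list(a = ref, b = ref))
  expect_equal(unname(out2$shifts["b"]), 0, tolerance = 1e-9)
  # rescaled curves span [0, 1]
  for (al in out$aligned) {
    expect_equal(min(al$scaled), 0)
    expect_equal(max(al$scaled), 1)
  }
  flat <- data.frame(ATP = atp, magnitude = rep(1, length(atp)))
  expect_error(align_dose_curves(list(ref, flat)), "flat")
})
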