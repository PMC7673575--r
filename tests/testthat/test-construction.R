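test_that("matching index reorders co-location responses per pattern", {
  lay <- cmp_layout()
  f_ic <- c(I = 4, II = 1, III = 1, IV = 1)
  f_bc <- stats::setNames(c(4, 1, 1, 1),
                          as.character(lay$default_angle))  # peak at 45
  r <- matching_index(f_ic, f_bc, lay)
  expect_equal(unname(r["0"]), 1)
  # one-step cyclic shift: Pearson of (4,1,1,1) against its shift = -1/3
  expect_equal(unname(r["90"]), -1 / 3, tolerance = 1e-12)
  expect_equal(unname(r["-90"]), -1 / 3, tolerance = 1e-12)
  # zero variance in a 4-vector flags the pattern undefined
  r0 <- matching_index(c(I = 1, II = 1, III = 1, IV = 1), f_bc, lay)
  expect_true(all(is.na(r0)))
})

test_that("matching patterns are related by consistent reordering of targets", {
  lay <- cmp_layout()
  set.seed(8)
  f_ic <- stats::setNames(rexp(4, 1 / 5), c("I", "II", "III", "IV"))
  angles <- as.character(c(45, 135, 225, 315))
  f_bc <- stats::setNames(rexp(4, 1 / 5), angles)
  r <- matching_index(f_ic, f_bc, lay)
  # substituting f_bc(a) -> f_bc(a - 90) shifts every pattern by +90 deg
  f_bc_rot <- stats::setNames(
    f_bc[as.character(rotate_angle(as.numeric(angles), 90))], angles)
  r_rot <- matching_index(f_ic, f_bc_rot, lay)
  expect_equal(unname(r_rot["-90"]), unname(r["0"]), tolerance = 1e-12)
  expect_equal(unname(r_rot["0"]), unname(r["90"]), tolerance = 1e-12)
})

test_that("targeting ensembles put the maximal matching index on the 0-deg pattern", {
  ses <- simulate_session(session_spec(counts = c(targeting = 24),
                                       n_trials = 128, seed = 19))
  pop <- matching_population(ses, 1:24)
  expect_equal(unname(which.max(pop$median)), 2L)  # the "0" pattern
  expect_gt(pop$median["0"], 0.8)
  expect_lt(pop$p["0"], 1e-4)
  expect_lt(pop$median["-90"], 0.25)
  expect_lt(pop$median["90"], 0.25)
})

test_that("orientation-tuning similarity is positive for convergent ensembles only", {
  ses <- simulate_session(session_spec(counts = c(convergent = 20),
                                       n_trials = 128, seed = 23))
  tc <- tuning_similarity_timecourse(ses, 1:20, step = 20)
  expect_gt(nrow(tc$epochs), 0)
  # the significant epoch overlaps the early background window where the
  # orientation gain is shared across co-locations
  expect_true(any(tc$epochs$start < 500 & tc$epochs$end > 200))
  # an untuned ensemble shows no systematic positive-similarity epoch
  ses0 <- simulate_session(session_spec(counts = c(untuned = 16),
                                        n_trials = 128, seed = 24))
  tc0 <- tuning_similarity_timecourse(ses0, 1:16, step = 20)
  expect_lte(sum(tc0$sig), 0.05 * length(tc0$sig))
})

test_that("tuning similarity is symmetric in the best/second-best roles", {
  ses <- small_session()
  cv <- ses$truth$neuron_id[ses$truth$archetype == "convergent"][1]
  ts <- tuning_similarity(ses, cv)
  expect_equal(ts$r, stats::cor(ts$cell_means[ts$second, ],
                                ts$cell_means[ts$best, ]))
})

test_that("population target SDFs separate transference from targeting", {
  # transferring-dominant ensemble: rotated-background target response
  # exceeds the 0-deg response in the mid background epoch
  ses_tf <- simulate_session(session_spec(counts = c(transferring = 12),
                                          n_trials = 128, seed = 29))
  pop_tf <- suppressWarnings(
    target_population_sdf(ses_tf, 1:12, step = 10))
  expect_gt(nrow(pop_tf$epochs_rot_gt_0), 0)
  expect_true(any(pop_tf$epochs_rot_gt_0$start < 800 &
                    pop_tf$epochs_rot_gt_0$end > 300))
  # targeting-only ensemble: the two groups are indistinguishable
  ses_tg <- simulate_session(session_spec(counts = c(targeting = 12),
                                          n_trials = 128, seed = 30))
  pop_tg <- suppressWarnings(
    target_population_sdf(ses_tg, 1:12, step = 10))
  frac_diff <- mean(pop_tg$sig_rot_gt_0, na.rm = TRUE)
  expect_lt(frac_diff, 0.1)
  # untuned ensemble: no epochs beyond the step-wise false-positive rate
  ses_un <- simulate_session(session_spec(counts = c(untuned = 10),
                                          n_trials = 128, seed = 32))
  pop_un <- suppressWarnings(
    target_population_sdf(ses_un, 1:10, step = 10))
  expect_lt(mean(pop_un$sig_deg0, na.rm = TRUE), 0.12)
})

test_that("partial correlations match the residual-regression oracle", {
  set.seed(40)
  d <- rnorm(50); x <- 0.6 * d + rnorm(50, sd = 0.5); y <- rnorm(50)
  oracle <- stats::cor(stats::resid(stats::lm(d ~ y)),
                       stats::resid(stats::lm(x ~ y)))
  expect_equal(partial_cor(d, x, y), oracle, tolerance = 1e-10)
  # D identical to X with independent Y: choice term 1, other term ~ 0
  expect_equal(partial_cor(d, d, y), 1, tolerance = 1e-10)
  # independent variables carry no partial association
  z <- rnorm(50)
  expect_lt(abs(partial_cor(d, y, z)), 0.35)
  # invariance to adding a constant to all rates in a bin
  expect_equal(partial_cor(d + 7, x + 7, y + 7), partial_cor(d, x, y),
               tolerance = 1e-10)
})

test_that("error-trial activity follows choice when kappa = 1 and the instruction when kappa = 0", {
  run <- function(kappa, seed) {
    ses <- simulate_session(session_spec(counts = c(targeting = 15),
                                         n_trials = 128, error_rate = 0.2,
                                         choice_weight = kappa, seed = seed))
    error_population(ses, 1:15)
  }
  ep1 <- run(1, 51)
  expect_gt(ep1$median_choice, ep1$median_correct)
  expect_lt(ep1$p, 0.05)
  ep0 <- run(0, 52)
  expect_gt(ep0$median_correct, ep0$median_choice)
  # a neuron with too few error trials is excluded with a reason
  ses0 <- simulate_session(session_spec(counts = c(targeting = 1),
                                        n_trials = 40, error_rate = 0,
                                        seed = 53))
  res <- error_partial_correlation(ses0, 1)
  expect_false(res$included)
  expect_match(res$reason, "error trials")
})
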