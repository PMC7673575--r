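test_that("rate profiles follow the archetype rules", {
  lay <- cmp_layout()
  tr_base <- list(item = "I-A", colocation = "I", orientation_deg = 0,
                  target_deg = 45, choice_deg = 45)
  un <- neuron_spec(1, "untuned", baseline_rate = 4)
  p <- rate_profile(un, tr_base, lay)
  expect_equal(unique(p$rates), 4)

  # transferring: fires for (I-A, 90) -> target 315, silent for (II-A, 0)
  # even though the target is 315 in both
  tf <- neuron_spec(2, "transferring", preferred_target = 315)
  on <- rate_profile(tf, list(item = "I-A", colocation = "I",
                              orientation_deg = 90, target_deg = 315,
                              choice_deg = 315), lay)
  off <- rate_profile(tf, list(item = "II-A", colocation = "II",
                               orientation_deg = 0, target_deg = 315,
                               choice_deg = 315), lay)
  expect_gt(profile_rate(on, 1500), profile_rate(off, 1500))
  expect_equal(unique(off$rates), tf$baseline_rate)

  # targeting: gain for every (c, theta) whose target is preferred
  tg <- neuron_spec(3, "targeting", preferred_target = 315)
  for (cl in c("I", "II", "III", "IV")) for (th in c(-90, 0, 90)) {
    tgt <- target_location(cl, th, lay)
    pr <- rate_profile(tg, list(item = paste0(cl, "-A"), colocation = cl,
                                orientation_deg = th, target_deg = tgt,
                                choice_deg = tgt), lay)
    if (tgt == 315L) expect_gt(profile_rate(pr, 1750), tg$baseline_rate)
    else expect_equal(profile_rate(pr, 1750), tg$baseline_rate)
  }

  # item_unitized at unitization 1: identical drive for both pair items
  iu <- neuron_spec(4, "item_unitized", preferred_colocation = "I",
                    unitization = 1)
  pa <- rate_profile(iu, tr_base, lay)
  pb <- rate_profile(iu, modifyList(tr_base, list(item = "I-B")), lay)
  expect_equal(pa$rates, pb$rates)
  # at unitization 0 the set-B item gets no gain anywhere
  iu0 <- neuron_spec(5, "item_unitized", preferred_colocation = "I",
                     unitization = 0)
  pb0 <- rate_profile(iu0, modifyList(tr_base, list(item = "I-B")), lay)
  expect_equal(unique(pb0$rates), iu0$baseline_rate)

  expect_error(neuron_spec(6, "untuned", baseline_rate = 0.5), ">= 1 Hz")
  expect_error(neuron_spec(7, "item_unitized",
                           windows = list(item = c(100, 2500))),
               "within \\[0, 2000\\]")
})

test_that("thinning sampler matches Poisson expectations and a Bernoulli oracle", {
  set.seed(101)
  # constant 10 Hz over 1 s: mean count 10 across repetitions
  counts <- replicate(1000, length(generate_spikes(flat_profile(10))))
  expect_lt(abs(mean(counts) - 10), 3 * sqrt(10 / 1000))
  # variance/mean close to 1 (Poisson)
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.15)
  expect_identical(generate_spikes(flat_profile(0)), numeric(0))
  expect_error(generate_spikes(structure(list(breaks = c(0, 1), rates = -1),
                                         class = "cmp_rate_profile")),
               "non-negative")

  # piecewise rate vs an independent 1-ms Bernoulli approximation oracle
  prof <- structure(list(breaks = c(0, 200, 600, 1000),
                         rates = c(5, 25, 10)), class = "cmp_rate_profile")
  set.seed(202)
  reps <- 400
  thin_counts <- matrix(0, reps, 3)
  for (i in seq_len(reps)) {
    s <- generate_spikes(prof)
    thin_counts[i, ] <- c(sum(s < 200), sum(s >= 200 & s < 600),
                          sum(s >= 600))
  }
  oracle_counts <- matrix(0, reps, 3)
  grid_rate <- rep(c(5, 25, 10), c(200, 400, 400)) / 1000  # per 1-ms bin
  for (i in seq_len(reps)) {
    hit <- runif(1000) < grid_rate
    oracle_counts[i, ] <- c(sum(hit[1:200]), sum(hit[201:600]),
                            sum(hit[601:1000]))
  }
  for (j in 1:3) {
    se <- sqrt(var(thin_counts[, j]) / reps + var(oracle_counts[, j]) / reps)
    expect_lt(abs(mean(thin_counts[, j]) - mean(oracle_counts[, j])), 4 * se)
  }
})

test_that("simulated sessions satisfy the task invariants", {
  ses <- small_session()
  tr <- ses$trials
  # geometry invariant on every generated trial
  expect_equal(tr$target_deg,
               target_location(tr$colocation, tr$orientation_deg,
                               ses$layout))
  expect_equal(tr$correct, tr$choice_deg == tr$target_deg)
  # error_rate = 0 means all trials correct
  ses0 <- simulate_session(session_spec(counts = c(untuned = 1),
                                        n_trials = 40, error_rate = 0,
                                        seed = 3))
  expect_true(all(ses0$trials$correct))
  # overall fraction correct tracks 1 - error_rate (binomial check)
  big <- build_trials(make_schedule(1000, seed = 4), error_rate = 0.2,
                      seed = 5)
  expect_lt(abs(mean(big$correct) - 0.8), 3 * sqrt(0.2 * 0.8 / 1000))
  expect_error(session_spec(counts = c(untuned = 0)), "at least one neuron")
  expect_error(session_spec(error_rate = 1), "error_rate")
})

test_that("same seed reproduces a session and substreams isolate neurons", {
  sp <- session_spec(counts = c(untuned = 2, item_unitized = 2),
                     n_trials = 30, seed = 9)
  s1 <- simulate_session(sp)
  s2 <- simulate_session(sp)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$trials, s2$trials)
  # adding neurons of a later archetype leaves earlier spike trains intact
  sp_more <- session_spec(counts = c(untuned = 2, item_unitized = 2,
                                     targeting = 2),
                          n_trials = 30, seed = 9)
  s3 <- simulate_session(sp_more)
  expect_identical(s1$spikes, s3$spikes[s3$spikes$neuron_id %in% 1:4, ])
})

test_that("spike counts in disjoint windows behave as independent Poisson", {
  ses <- small_session()
  b <- binned_rates(ses, "item_on",
                    windows = cbind(c(-500, 0, 500), c(0, 500, 1000)))
  # untuned neurons: variance/mean of counts ~ 1 in each window
  cnts <- b$rates[1:4, , ] * 0.5
  for (w in 1:3) {
    fano <- apply(cnts[, , w], 1, function(x) var(x) / mean(x))
    expect_true(all(abs(fano - 1) < 0.35))
  }
})
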