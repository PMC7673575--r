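test_that("one-way item ANOVA matches the linear-model oracle", {
  set.seed(11)
  tr <- make_trials(64, seed = 2)
  y <- matrix(rnorm(64 * 3, mean = 5), 64, 3)
  mine <- anova1_F(y, tr$item)
  for (j in 1:3) {
    fit <- stats::anova(stats::lm(y[, j] ~ factor(tr$item)))
    expect_equal(mine$F[j], fit$`F value`[1], tolerance = 1e-10)
    expect_equal(mine$p[j], fit$`Pr(>F)`[1], tolerance = 1e-10)
  }
  # zero-variance responses are reported as not selective, not as F = Inf
  z <- matrix(3, 64, 1)
  res <- anova1_item(z, tr$item)
  expect_false(res$selective)
  # an item with < 2 trials is a labeled error
  tr2 <- tr[!(tr$item == "I-A" & duplicated(tr$item)), ]
  expect_error(anova1_F(matrix(rnorm(nrow(tr2))), tr2$item),
               "fewer than 2 trials.*I-A")
})

test_that("nested three-way F equals a model-comparison lm oracle", {
  set.seed(21)
  tr <- make_trials(90, seed = 6)
  tru <- tr[tr$orientation_deg %in% c(-90, 0, 90), ]
  y <- rnorm(nrow(tru), mean = 4) +
    2 * (tru$target_deg == 45)   # a target effect to make Fs non-trivial
  des <- nested_design(tru)
  mine <- nested_F(des, matrix(y))
  # oracle: explicit model-comparison F via lm fits on the same coding
  sum_code <- function(f) {
    f <- factor(f)
    stats::model.matrix(~f, contrasts.arg = list(f = "contr.sum"))[, -1,
                                                                   drop = FALSE]
  }
  xc <- sum_code(tru$colocation); xb <- sum_code(tru$orientation_deg)
  xt <- sum_code(tru$target_deg)
  sgn <- ifelse(endsWith(tru$item, "-A"), 1, -1)
  xi <- sapply(sort(unique(tru$colocation)),
               function(cl) ifelse(tru$colocation == cl, sgn, 0))
  full <- stats::lm(y ~ xc + xb + xt + xi)
  oracle <- sapply(list(colocation = quote(y ~ xb + xt + xi),
                        background = quote(y ~ xc + xt + xi),
                        target = quote(y ~ xc + xb + xi),
                        item = quote(y ~ xc + xb + xt)),
                   function(fml) {
                     red <- stats::lm(eval(fml))
                     a <- stats::anova(red, full)
                     c(a$F[2], a$`Pr(>F)`[2])
                   })
  expect_equal(unname(mine$F[, 1]), unname(oracle[1, ]), tolerance = 1e-10)
  expect_equal(unname(mine$p[, 1]), unname(oracle[2, ]), tolerance = 1e-10)
})

test_that("balanced designs collapse SS types and reduce to the crossed ANOVA", {
  # 2 repetitions of all 24 (item, orientation) configurations: balanced
  tr <- build_trials(make_schedule(48, orientations = c(-90, 0, 90),
                                   seed = 8))
  set.seed(31)
  y <- rnorm(48, mean = 5, sd = 1)
  des <- nested_design(tr)
  mine <- nested_F(des, matrix(y))
  # sequential (Type-I) ANOVA agrees when the design is balanced
  sgn <- ifelse(endsWith(tr$item, "-A"), 1, -1)
  xi <- sapply(sort(unique(tr$colocation)),
               function(cl) ifelse(tr$colocation == cl, sgn, 0))
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  # each factor entered last in a sequential fit reproduces the
  # model-comparison F (the Latin-rectangle constraint linking target to
  # (co-location, orientation) keeps the three spaces jointly
  # non-orthogonal, so only the last-entered term is comparable)
  C <- factor(tr$colocation); B <- factor(tr$orientation_deg)
  Tg <- factor(tr$target_deg)
  last_F <- c(
    colocation = stats::anova(stats::lm(y ~ B + Tg + xi + C))$`F value`[4],
    background = stats::anova(stats::lm(y ~ C + Tg + xi + B))$`F value`[4],
    target = stats::anova(stats::lm(y ~ C + B + xi + Tg))$`F value`[4],
    item = stats::anova(stats::lm(y ~ C + B + Tg + xi))$`F value`[4])
  expect_equal(unname(mine$F[, 1]), unname(last_F), tolerance = 1e-10)
  # dropping the nested item term gives the crossed three-way ANOVA;
  # orthogonality of item-within-co-location to the rest means the other
  # factors' sums of squares are unchanged (only the residual df moves)
  des3 <- nested_design(tr, include_item = FALSE)
  mine3 <- nested_F(des3, matrix(y))
  last3 <- c(
    colocation = stats::anova(stats::lm(y ~ B + Tg + C))$`F value`[3],
    background = stats::anova(stats::lm(y ~ C + Tg + B))$`F value`[3],
    target = stats::anova(stats::lm(y ~ C + B + Tg))$`F value`[3])
  expect_equal(unname(mine3$F[, 1]), unname(last3), tolerance = 1e-10)
})

test_that("designs with missing orientations are rejected with the factor named", {
  tr <- make_trials(60, orientations = c(0, 45), seed = 3)
  expect_error(nested_design(tr[tr$orientation_deg == 0, ]),
               "background")
})

test_that("screens recover synthetic archetypes and stay quiet on untuned cells", {
  ses <- small_session()
  scr <- screen_neurons(ses)
  m <- merge(scr, ses$truth[, c("neuron_id", "archetype")], by = "neuron_id")
  # strong unitized item neurons (gain 2 x baseline, 16 trials/item) flagged
  expect_true(all(m$item_icue[m$archetype == "item_unitized"]))
  # targeting neurons carry the target flag
  expect_true(all(m$target[m$archetype == "targeting"]))
  # convergent neurons show both co-location and background effects (at
  # this tiny n at least half; class-level sensitivity at scale is
  # checked by the acceptance suite)
  expect_gte(mean(m$convergent[m$archetype == "convergent"]), 0.5)
  # background neurons: background flag without co-location flag
  expect_true(all(m$background[m$archetype == "background"]))
  expect_false(any(m$colocation[m$archetype == "background"]))
})

test_that("a higher-gain unitized neuron is flagged with 16 trials per item", {
  ses <- simulate_session(session_spec(
    counts = c(item_unitized = 3), n_trials = 128, gain = 15, seed = 77))
  scr <- screen_neurons(ses)
  expect_true(all(scr$item_icue))
})

test_that("instantaneous F time courses behave at the null and order the phases", {
  ses <- small_session()
  truth <- ses$truth
  # flat zero-spike neuron: no significant steps anywhere
  flat <- manual_session(rep(list(numeric(0)), 128), ses$trials)
  flat$spikes <- data.frame(neuron_id = 1L, trial_id = 1L, t_ms = -400)
  inst0 <- instantaneous_F(flat, 1, step = 50)
  expect_false(any(inst0$sig, na.rm = TRUE))
  # untuned neurons: fraction of significant steps near the uncorrected alpha
  unt <- truth$neuron_id[truth$archetype == "untuned"]
  frac <- vapply(unt, function(nr) {
    inst <- instantaneous_F(ses, nr, step = 25)
    mean(inst$sig, na.rm = TRUE)
  }, 1)
  expect_lt(mean(frac), 0.05)
  # multiphase ensemble: the averaged F time courses order the operations
  # -- the joint co-location/background (convergence) epoch precedes the
  # target-dominated epoch
  mses <- simulate_session(session_spec(counts = c(multiphase = 8),
                                        n_trials = 128, seed = 63))
  fsum <- 0
  for (nr in 1:8)
    fsum <- fsum + instantaneous_F(mses, nr, step = 10,
                                   t_range = c(1000, 2000))$F
  fbar <- fsum / 8
  starts <- seq(1000, 1900, by = 10)
  t_bg <- starts[which.max(fbar["background", ])]
  t_tg <- starts[which.max(fbar["target", ])]
  expect_lt(t_bg, t_tg)
  # at the background peak the co-location signal is simultaneously
  # elevated (convergence), and the background effect has decayed by the
  # time the target effect peaks
  expect_gt(fbar["colocation", which.max(fbar["background", ])], 2)
  expect_lt(fbar["background", which.max(fbar["target", ])],
            max(fbar["background", ]) / 2)
})
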