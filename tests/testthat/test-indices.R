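items8 <- function() names(cmp_layout()$item_to_colocation)

test_that("co-location index reproduces the Fisher-Z arithmetic exactly", {
  lay <- cmp_layout()
  # set-A means equal to set-B means in every window -> rbar = 1
  m <- matrix(rep(c(9, 2, 4, 1), 2), nrow = 2, ncol = 8, byrow = TRUE)
  m <- rbind(m, m)[1:2, ]
  colnames(m) <- items8()
  res <- colocation_index(m, c(TRUE, TRUE), lay)
  expect_equal(res$rbar, 1)
  # two significant windows with r = 0 and r = 0.8 -> rbar = 0.5 exactly
  a <- c(1, 2, 3, 4)
  ac <- (a - mean(a)) / sqrt(sum((a - mean(a))^2))
  e <- c(1, -1, -1, 1) / 2
  b <- 0.8 * ac + 0.6 * e
  r0a <- c(1, 2, 1, 2); r0b <- c(1, 1, 2, 2)
  m2 <- rbind(c(r0a, r0b), c(a, b))
  colnames(m2) <- items8()
  res2 <- colocation_index(m2, c(TRUE, TRUE), lay)
  expect_equal(unname(res2$r), c(0, 0.8), tolerance = 1e-12)
  expect_equal(res2$rbar, 0.5, tolerance = 1e-12)
  # single significant window: rbar equals that window's r (Z round trip)
  res1 <- colocation_index(m2, c(FALSE, TRUE), lay)
  expect_equal(res1$rbar, 0.8, tolerance = 1e-12)
  # no significant window: index undefined
  expect_true(is.na(colocation_index(m2, c(FALSE, FALSE), lay)$rbar))
  # zero variance in a 4-vector: window skipped with a warning
  m3 <- rbind(c(rep(1, 4), a), m2[2, ])
  colnames(m3) <- items8()
  expect_warning(res3 <- colocation_index(m3, c(TRUE, TRUE), lay),
                 "zero variance")
  expect_equal(res3$rbar, 0.8, tolerance = 1e-12)
})

test_that("co-location index is invariant to exchanging the set roles", {
  lay <- cmp_layout()
  set.seed(5)
  m <- matrix(rexp(16, 1 / 5), 2, 8)
  colnames(m) <- items8()
  swapped <- m[, c(5:8, 1:4)]
  colnames(swapped) <- items8()
  expect_equal(colocation_index(m, c(TRUE, TRUE), lay)$rbar,
               colocation_index(swapped, c(TRUE, TRUE), lay)$rbar)
})

test_that("index permutation test has power on unitized neurons and a null on shuffled labels", {
  ses <- small_session()
  iu <- ses$truth$neuron_id[ses$truth$archetype == "item_unitized"]
  res <- lapply(iu, function(nr) colocation_analysis(ses, nr, n_perm = 500,
                                                     seed = nr))
  rbars <- vapply(res, `[[`, 1, "rbar")
  ps <- vapply(res, `[[`, 1, "p")
  # recovered index close to the design value 1 at unitization 1
  expect_true(all(rbars > 0.9))
  expect_true(all(ps <= 0.01))
  # permuted-label copy of a significant neuron: p typically > 0.05
  iw <- item_window_means(ses, iu[1])
  scr <- anova1_F(iw$rates, iw$items)
  sig <- !is.na(scr$p) & scr$p < 0.01 / 8
  set.seed(99)
  ps_null <- replicate(20, {
    shuffled <- sample(iw$items)
    colocation_index_permutation(iw$rates, shuffled, sig,
                                 n_perm = 200, seed = sample.int(1e6, 1))$p
  })
  expect_gt(mean(ps_null > 0.05), 0.75)
  expect_error(colocation_index_permutation(iw$rates, iw$items, sig,
                                            n_perm = 50), "at least 100")
})

test_that("mean recovered index increases with the unitization parameter", {
  rbar_at <- function(u, seed) {
    ses <- simulate_session(session_spec(
      counts = c(item_unitized = 8), n_trials = 128, unitization = u,
      seed = seed))
    mean(vapply(1:8, function(nr)
      colocation_analysis(ses, nr, n_perm = 0)$rbar, 1), na.rm = TRUE)
  }
  r <- vapply(c(0, 0.5, 1), rbar_at, 1, seed = 17)
  expect_lt(r[1], r[2])
  expect_lt(r[2], r[3])
  expect_lt(abs(r[3] - 1), 0.1)
})

test_that("empirical AUC equals the pairwise-comparison oracle", {
  expect_equal(roc_auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(roc_auc(4:6, 1:3), 1)
  expect_equal(roc_auc(1:3, 4:6), 0)
  set.seed(12)
  for (i in 1:10) {
    x <- round(rexp(7, 1 / 4), 1)
    y <- round(rexp(9, 1 / 4), 1)
    oracle <- mean(outer(x, y, function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(roc_auc(x, y), oracle, tolerance = 1e-12)
  }
  expect_error(roc_auc(numeric(0), 1:3), "non-empty")
})

test_that("re-determination permutation null is biased above 0.5 (enumeration oracle)", {
  x1 <- c(5.1, 4.2, 6.3, 5.5)
  x2 <- c(4.9, 5.0, 4.1, 5.2)
  pool <- c(x1, x2)
  splits <- utils::combn(8, 4)
  oracle_null <- apply(splits, 2, function(idx) {
    g1 <- pool[idx]; g2 <- pool[-idx]
    if (mean(g2) > mean(g1)) { tmp <- g1; g1 <- g2; g2 <- tmp }
    roc_auc(g1, g2)
  })
  expect_gt(median(oracle_null), 0.5)
  res <- auc_permutation(x1, x2, n_perm = 4000, seed = 2)
  expect_gt(res$null_median, 0.5)
  expect_equal(res$null_median, median(oracle_null), tolerance = 0.05)
  expect_error(auc_permutation(x1, x2, n_perm = 10), "at least 100")
})

test_that("ROC analysis mirrors the unitized discrimination pattern", {
  ses <- small_session()
  iu <- ses$truth$neuron_id[ses$truth$archetype == "item_unitized"]
  res <- lapply(iu, function(nr) roc_analysis(ses, nr, n_perm = 400,
                                              seed = nr))
  # best co-location vs others: discriminable (mirrors AUC = 0.84 case)
  p_coloc <- vapply(res, function(r) r$colocation_discrimination$p, 1)
  expect_true(all(p_coloc < 0.05))
  # optimal vs its pair at unitization 1: not discriminable
  p_item <- vapply(res, function(r) r$item_discrimination$p, 1)
  expect_true(all(p_item > 0.05))
  # the pair item really is the other item of the optimal's co-location
  expect_equal(item_colocation(res[[1]]$optimal_item),
               item_colocation(res[[1]]$pair_item))
})
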