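# correct trials with the three analysis orientations (-90, 0, 90)
analysis_trials <- function(session) {
  tr <- session$trials
  tr[tr$correct & tr$orientation_deg %in% c(-90, 0, 90), , drop = FALSE]
}

# contiguous TRUE runs of `mask` as (start, end) intervals over `starts`
sig_epochs <- function(starts, mask, width = 0) {
  mask[is.na(mask)] <- FALSE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep)) return(data.frame(start = numeric(0), end = numeric(0)))
  data.frame(start = starts[begins[keep]], end = starts[ends[keep]] + width)
}

#' Similarity of orientation tuning across co-locations (one neuron)
#'
#' Mean rates per (co-location, orientation) cell in the 60-1000 ms
#' background window determine the best and second-best co-location; the
#' similarity is the Pearson correlation (3 pairs, df = 1) between the two
#' co-locations' responses to the -90, 0 and 90 deg backgrounds.  A
#' positive value means the neuron keeps the same orientation tuning
#' whichever co-location signal it holds -- the "convergent" signature.
#'
#' @param session a `cmp_session`.
#' @param neuron neuron id.
#' @return list with `r`, `best`, `second`, and the 4 x 3 cell-mean matrix.
#' @export
tuning_similarity <- function(session, neuron) {
  tru <- analysis_trials(session)
  rates <- mean_rate(session, "bg_on", trials = tru$trial_id,
                     neurons = neuron)
  cell <- tapply(rates,
                 list(factor(tru$colocation, names(session$layout$default_angle)),
                      factor(tru$orientation_deg, c(-90, 0, 90))),
                 mean)
  if (anyNA(cell))
    stop("missing (co-location, orientation) cell(s): ",
         paste(which(is.na(cell)), collapse = ", "))
  ord <- order(rowMeans(cell), decreasing = TRUE)
  best <- rownames(cell)[ord[1]]; second <- rownames(cell)[ord[2]]
  list(r = stats::cor(cell[best, ], cell[second, ]),
       best = best, second = second, cell_means = cell)
}

#' Population time course of orientation-tuning similarity
#'
#' For each co-location-selective neuron, the tuning-similarity
#' correlation is recomputed in 100-ms windows sliding in `step`-ms
#' increments after background onset (best/second-best co-locations fixed
#' from the whole-window means); the population mean, SEM and a per-step
#' two-tailed Wilcoxon signed-rank test (p < 0.01) are reported, with
#' significant epochs as contiguous intervals.
#'
#' @param session a `cmp_session`.
#' @param neurons neuron ids (typically the co-location-selective set).
#' @param width,step sliding-window parameters, ms.
#' @param t_range range after background onset covered by window starts.
#' @param alpha per-step level.
#' @return list with `starts`, `r` (neuron x step), `mean`, `sem`, `p`,
#'   `sig`, and `epochs`.
#' @export
tuning_similarity_timecourse <- function(session, neurons, width = 100,
                                         step = 10, t_range = c(0, 1000),
                                         alpha = 0.01) {
  tru <- analysis_trials(session)
  rmat <- NULL
  for (nr in neurons) {
    ts <- tuning_similarity(session, nr)
    sl <- sliding_rates(session, nr, "bg_on", width = width, step = step,
                        t_range = t_range, trials = tru$trial_id)
    idx <- match(sl$trial_id, tru$trial_id)
    r_t <- vapply(seq_along(sl$starts), function(j) {
      cm <- tapply(sl$rates[, j],
                   list(factor(tru$colocation[idx],
                               names(session$layout$default_angle)),
                        factor(tru$orientation_deg[idx], c(-90, 0, 90))),
                   mean)
      suppressWarnings(stats::cor(cm[ts$best, ], cm[ts$second, ]))
    }, 1)
    rmat <- rbind(rmat, r_t)
  }
  rownames(rmat) <- neurons
  mu <- colMeans(rmat, na.rm = TRUE)
  sem <- apply(rmat, 2, function(x) stats::sd(x, na.rm = TRUE) /
                 sqrt(sum(is.finite(x))))
  p <- apply(rmat, 2, function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 3 || all(x == 0)) return(NA_real_)
    stats::wilcox.test(x, exact = FALSE)$p.value
  })
  sig <- !is.na(p) & p < alpha & mu > 0
  list(starts = sl$starts, r = rmat, mean = mu, sem = sem, p = p,
       sig = sig, epochs = sig_epochs(sl$starts, sig, width))
}

#' Matching index between co-location and target-location responses
#'
#' Correlates a neuron's item-cue-period responses to the 4 co-locations
#' with its background-cue-period responses to the 4 target locations,
#' under each of the 3 potential matching patterns: the co-locations are
#' re-sorted to the screen positions they would occupy if the background
#' were at -90, 0 or +90 deg (4 pairs, df = 2).  A high 0-deg-pattern
#' index means the retrieved location is represented at its
#' default-orientation screen position.
#'
#' @param f_ic named numeric vector: mean item-cue-period rate per
#'   co-location (`"I".."IV"`).
#' @param f_bc named numeric vector: mean background-cue-period rate per
#'   target angle (names `"45"`, `"135"`, `"225"`, `"315"` for the
#'   canonical layout).
#' @param layout a [cmp_layout()].
#' @param patterns hypothesized background orientations.
#' @return named numeric vector of Pearson r per pattern; a pattern with
#'   zero variance in either 4-vector is `NA` (flagged undefined).
#' @export
matching_index <- function(f_ic, f_bc, layout = cmp_layout(),
                           patterns = c(-90, 0, 90)) {
  colocs <- names(layout$default_angle)
  stopifnot(all(colocs %in% names(f_ic)))
  out <- vapply(patterns, function(th) {
    ang <- as.character(target_location(colocs, th, layout))
    if (!all(ang %in% names(f_bc))) return(NA_real_)
    a <- as.numeric(f_ic[colocs]); b <- as.numeric(f_bc[ang])
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, 1)
  stats::setNames(out, as.character(patterns))
}

#' Matching-index analysis for one neuron
#'
#' Computes the per-co-location item-period means (60-1000 ms from
#' item-cue onset) and per-target background-period means (60-1000 ms from
#' background onset) over the correct -90/0/90 deg trials, then the three
#' pattern correlations.
#'
#' @inheritParams tuning_similarity
#' @return list with `f_ic`, `f_bc` and the [matching_index()] vector `r`.
#' @export
matching_analysis <- function(session, neuron) {
  tru <- analysis_trials(session)
  ic <- mean_rate(session, "item_on", trials = tru$trial_id,
                  neurons = neuron)
  bc <- mean_rate(session, "bg_on", trials = tru$trial_id, neurons = neuron)
  f_ic <- tapply(ic, factor(tru$colocation,
                            names(session$layout$default_angle)), mean)
  f_bc <- tapply(bc, factor(tru$target_deg,
                            sort(unique(tru$target_deg))), mean)
  list(f_ic = f_ic, f_bc = f_bc,
       r = matching_index(f_ic, f_bc, session$layout))
}

#' Population matching-index summary
#'
#' @param session a `cmp_session`.
#' @param neurons neurons entering the analysis (those with
#'   item-selectivity during the item-cue period and target-selectivity
#'   during the background-cue period).
#' @return list with the neuron x pattern matrix `r`, per-pattern
#'   `median` and quartiles, and per-pattern two-tailed signed-rank `p`.
#' @export
matching_population <- function(session, neurons) {
  r <- t(vapply(neurons, function(nr) matching_analysis(session, nr)$r,
                numeric(3)))
  rownames(r) <- neurons
  med <- apply(r, 2, stats::median, na.rm = TRUE)
  q1 <- apply(r, 2, stats::quantile, 0.25, na.rm = TRUE, names = FALSE)
  q3 <- apply(r, 2, stats::quantile, 0.75, na.rm = TRUE, names = FALSE)
  p <- apply(r, 2, function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 3) return(NA_real_)
    stats::wilcox.test(x, exact = FALSE)$p.value
  })
  list(r = r, median = med, q1 = q1, q3 = q3, p = p)
}

#' Target-selective population SDFs by background orientation
#'
#' For each target-selective neuron, per-target SDFs (sigma = 20 ms)
#' aligned to background onset are computed separately for trials with the
#' 0 deg background and with the rotated (-90 or +90 deg) backgrounds,
#' normalized to the amplitude of the neuron's mean response to its best
#' target location (its 60-1000 ms background-period mean), and the best
#' target's curve has the mean across the other targets subtracted.
#' Population means, SEMs, per-step two-tailed t-tests of each group
#' against zero and of the rotated group against the 0 deg group
#' (p < 0.05) are returned.
#'
#' @param session a `cmp_session`.
#' @param neurons target-selective neuron ids.
#' @param t_range SDF range relative to background onset, ms.
#' @param step SDF grid step, ms.
#' @param sigma kernel sigma, ms.
#' @param alpha per-step level.
#' @return list with `time`, per-group population `mean`/`sem`, per-group
#'   vs-zero significance masks, the rotated-vs-0 mask `sig_rot_gt_0`,
#'   and epoch tables.
#' @export
target_population_sdf <- function(session, neurons, t_range = c(-200, 1000),
                                  step = 5, sigma = 20, alpha = 0.05) {
  tru <- analysis_trials(session)
  groups <- list(deg0 = tru$orientation_deg == 0,
                 rot = tru$orientation_deg %in% c(-90, 90))
  grid_n <- length(seq(t_range[1], t_range[2], by = step))
  curves <- list(deg0 = NULL, rot = NULL)
  for (nr in neurons) {
    rates <- mean_rate(session, "bg_on", trials = tru$trial_id, neurons = nr)
    per_target <- tapply(rates, tru$target_deg, mean)
    best <- names(which.max(per_target))
    norm <- per_target[[best]]
    if (!is.finite(norm) || norm <= 0) {
      warning("neuron ", nr, " excluded: non-positive best-target response")
      next
    }
    for (g in names(groups)) {
      gtr <- tru[groups[[g]], , drop = FALSE]
      tgts <- as.character(sort(unique(gtr$target_deg)))
      if (!best %in% as.character(gtr$target_deg)) {
        warning("neuron ", nr, " has no ", g, " trials for its best target")
        next
      }
      sdfs <- lapply(tgts, function(tg) {
        ids <- gtr$trial_id[as.character(gtr$target_deg) == tg]
        mean_sdf(session, nr, ids, sigma, t_range, step, "bg_on")$rate_hz
      })
      names(sdfs) <- tgts
      others <- setdiff(tgts, best)
      cv <- (sdfs[[best]] -
               Reduce(`+`, sdfs[others]) / length(others)) / norm
      curves[[g]] <- rbind(curves[[g]], cv)
    }
  }
  time <- seq(t_range[1], t_range[2], by = step)
  summarize <- function(m) {
    if (is.null(m)) return(NULL)
    list(mean = colMeans(m),
         sem = apply(m, 2, stats::sd) / sqrt(nrow(m)),
         p = apply(m, 2, function(x) {
           if (stats::sd(x) == 0) return(NA_real_)
           stats::t.test(x)$p.value
         }))
  }
  s0 <- summarize(curves$deg0); sr <- summarize(curves$rot)
  sig0 <- !is.na(s0$p) & s0$p < alpha & s0$mean > 0
  sigr <- !is.na(sr$p) & sr$p < alpha & sr$mean > 0
  # rotated > 0 deg comparison (unpaired across the two curve sets)
  p_diff <- vapply(seq_along(time), function(j) {
    x <- curves$rot[, j]; y <- curves$deg0[, j]
    if (stats::sd(c(x, y)) == 0) return(NA_real_)
    stats::t.test(x, y)$p.value
  }, 1)
  sig_rot <- !is.na(p_diff) &
    p_diff < alpha & colMeans(curves$rot) > colMeans(curves$deg0)
  list(time = time, curves = curves,
       deg0 = s0, rot = sr,
       sig_deg0 = sig0, sig_rot_vs_zero = sigr, sig_rot_gt_0 = sig_rot,
       epochs_deg0 = sig_epochs(time, sig0),
       epochs_rot = sig_epochs(time, sigr),
       epochs_rot_gt_0 = sig_epochs(time, sig_rot))
}

#' First-order partial correlation
#'
#' `pcor(d, x | y)`: correlation between `d` and `x` with the linear
#' effect of `y` removed from both, via the standard first-order formula.
#'
#' @param d,x,y numeric vectors of equal length.
#' @return partial correlation coefficient.
#' @export
partial_cor <- function(d, x, y) {
  rdx <- stats::cor(d, x); rdy <- stats::cor(d, y); rxy <- stats::cor(x, y)
  (rdx - rdy * rxy) / sqrt((1 - rdy^2) * (1 - rxy^2))
}

#' Error-trial partial-correlation analysis for one neuron
#'
#' Builds, for each 300-ms background-period bin, three arrays over the
#' neuron's error trials: D, the error-trial firing rates; X, the mean
#' correct-trial rate for the position the animal (wrongly) chose; and Y,
#' the mean correct-trial rate for the position it missed (the correct
#' answer).  In every qualifying bin -- the nested-ANOVA target effect on
#' correct trials significant at the Bonferroni per-bin threshold and the
#' across-trial mean rate above 1 Hz -- the partial correlations
#' `pcor(D, X | Y)` (choice) and `pcor(D, Y | X)` (correct position) are
#' computed, Fisher-Z averaged across qualifying bins, and
#' back-transformed.
#'
#' @param session a `cmp_session`.
#' @param neuron neuron id.
#' @param alpha family-wise level of the per-bin target-effect test.
#' @param min_errors minimum number of error trials for inclusion.
#' @param min_rate per-bin mean-rate floor, Hz.
#' @return list with `included` (FALSE with a `reason` when the neuron
#'   does not qualify), `choice_r`, `correct_r`, `n_error`, `bins_used`,
#'   and the per-bin partial correlations.
#' @export
error_partial_correlation <- function(session, neuron, alpha = 0.01,
                                      min_errors = 10, min_rate = 1) {
  tr <- session$trials
  err <- tr[!tr$correct & !is.na(tr$choice_deg), , drop = FALSE]
  if (nrow(err) < min_errors)
    return(list(included = FALSE,
                reason = sprintf("only %d error trials", nrow(err))))
  corr <- tr[tr$correct, , drop = FALSE]
  win <- analysis_windows()
  b_corr <- binned_rates(session, "bg_on", win, trials = corr$trial_id,
                         neurons = neuron)
  y_corr <- b_corr$rates[1, , , drop = TRUE]       # trials x bins
  tgt <- corr$target_deg[match(b_corr$trial_id, corr$trial_id)]
  # correct-trial rate template per target position (all orientations;
  # up to 8 on-screen positions)
  tmpl <- rowsum(y_corr, tgt) / as.vector(table(tgt))
  rownames(tmpl) <- sort(unique(tgt))
  # qualifying bins: target effect on correct -90/0/90 trials + rate floor
  tru <- analysis_trials(session)
  b_n <- binned_rates(session, "bg_on", win, trials = tru$trial_id,
                      neurons = neuron)
  des <- nested_design(tru[match(b_n$trial_id, tru$trial_id), , drop = FALSE])
  pt <- nested_F(des, b_n$rates[1, , , drop = TRUE])$p["target", ]
  qual <- !is.na(pt) & pt < alpha / nrow(win) & colMeans(y_corr) > min_rate
  if (!any(qual))
    return(list(included = FALSE, reason = "no qualifying time bin"))
  b_err <- binned_rates(session, "bg_on", win, trials = err$trial_id,
                        neurons = neuron)
  d_mat <- b_err$rates[1, , , drop = TRUE]
  err <- err[match(b_err$trial_id, err$trial_id), , drop = FALSE]
  # drop error trials whose chosen or correct position has no template
  ok <- as.character(err$choice_deg) %in% rownames(tmpl) &
    as.character(err$target_deg) %in% rownames(tmpl)
  err <- err[ok, , drop = FALSE]; d_mat <- d_mat[ok, , drop = FALSE]
  if (nrow(err) < min_errors)
    return(list(included = FALSE,
                reason = "too few error trials with usable templates"))
  r_choice <- r_correct <- rep(NA_real_, nrow(win))
  for (b in which(qual)) {
    d <- d_mat[, b]
    x <- tmpl[as.character(err$choice_deg), b]
    y <- tmpl[as.character(err$target_deg), b]
    if (stats::sd(d) == 0 || stats::sd(x) == 0 || stats::sd(y) == 0) next
    r_choice[b] <- partial_cor(d, x, y)
    r_correct[b] <- partial_cor(d, y, x)
  }
  list(included = TRUE,
       choice_r = fisher_mean_r(r_choice[qual]),
       correct_r = fisher_mean_r(r_correct[qual]),
       n_error = nrow(err), bins_used = which(qual),
       per_bin_choice = r_choice, per_bin_correct = r_correct)
}

#' Population error analysis
#'
#' Runs [error_partial_correlation()] over the target-selective neurons
#' and compares the population's choice-related and correct-position-
#' related partial correlations with a two-tailed Wilcoxon signed-rank
#' test.
#'
#' @param session a `cmp_session`.
#' @param neurons target-selective neuron ids.
#' @param ... forwarded to [error_partial_correlation()].
#' @return list with the per-neuron data.frame `per_neuron`, the
#'   signed-rank `p`, and medians of the two statistics.
#' @export
error_population <- function(session, neurons, ...) {
  rows <- lapply(neurons, function(nr) {
    res <- error_partial_correlation(session, nr, ...)
    if (!isTRUE(res$included)) return(NULL)
    data.frame(neuron_id = nr, choice_r = res$choice_r,
               correct_r = res$correct_r, n_error = res$n_error)
  })
  per <- do.call(rbind, rows)
  if (is.null(per) || nrow(per) < 3)
    return(list(per_neuron = per, p = NA_real_))
  keep <- is.finite(per$choice_r) & is.finite(per$correct_r)
  p <- stats::wilcox.test(per$choice_r[keep], per$correct_r[keep],
                          paired = TRUE, exact = FALSE)$p.value
  list(per_neuron = per, p = p,
       median_choice = stats::median(per$choice_r, na.rm = TRUE),
       median_correct = stats::median(per$correct_r, na.rm = TRUE))
}
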