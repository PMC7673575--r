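#' Per-item mean firing rates per analysis window
#'
#' @param session a `cmp_session`.
#' @param neuron neuron id.
#' @param align alignment event for the windows.
#' @param windows window matrix (default the 8 standard windows).
#' @param trials trial ids to use (default: correct trials).
#' @return list with `means` (windows x 8 items matrix, columns named by
#'   item), `rates` (trials x windows), and `items` (per-trial labels).
#' @export
item_window_means <- function(session, neuron, align = "item_on",
                              windows = analysis_windows(), trials = NULL) {
  tr <- session$trials
  if (is.null(trials)) trials <- tr$trial_id[tr$correct]
  b <- binned_rates(session, align, windows, trials = trials,
                    neurons = neuron)
  y <- b$rates[1, , , drop = TRUE]          # trials x windows
  if (is.null(dim(y))) y <- matrix(y, ncol = nrow(windows))
  items <- tr$item[match(b$trial_id, tr$trial_id)]
  m <- rowsum(y, items) / as.vector(table(items)[sort(unique(items))])
  list(means = t(m), rates = y, items = items)
}

# row-wise Pearson correlation between two matrices of 4 columns
row_cor <- function(a, b) {
  ac <- a - rowMeans(a); bc <- b - rowMeans(b)
  num <- rowSums(ac * bc)
  den <- sqrt(rowSums(ac^2) * rowSums(bc^2))
  num / den
}

# Fisher-Z average of correlations, back-transformed to r
fisher_mean_r <- function(r) {
  r <- r[!is.na(r)]
  if (!length(r)) return(NA_real_)
  tanh(mean(atanh(pmin(pmax(r, -1), 1))))
}

# column indices of set-A / set-B items ordered by co-location
coloc_item_order <- function(item_names, layout) {
  cl <- item_colocation(item_names, layout)
  st <- item_set(item_names)
  ord_cl <- names(layout$default_angle)
  list(a = vapply(ord_cl, function(c0) which(cl == c0 & st == "A"), 1L),
       b = vapply(ord_cl, function(c0) which(cl == c0 & st == "B"), 1L))
}

#' Co-location index
#'
#' Per significant analysis window, the Pearson correlation (4 pairs,
#' df = 2) between the neuron's mean responses to the set-A items and to
#' the set-B items, both ordered by co-location; the per-window r values
#' are Fisher-Z transformed, averaged across the significant windows, and
#' back-transformed into the index r-bar.  A high index means the neuron
#' responds equivalently to the two distinct items sharing a co-location,
#' i.e. it signals the retrieved location rather than item identity.
#'
#' @param means windows x 8 matrix of per-item mean rates, columns named
#'   by item label.
#' @param sig_windows logical mask of windows with a significant item
#'   effect (the 300-ms screen windows at the Bonferroni-consistent
#'   per-window threshold).
#' @param layout a [cmp_layout()].
#' @return list with per-window `r` (NA outside the mask), the index
#'   `rbar` (NA when no window is significant), and `n_windows_used`.
#'   Windows with zero variance in either 4-vector are skipped with a
#'   warning.
#' @export
colocation_index <- function(means, sig_windows, layout = cmp_layout()) {
  means <- as.matrix(means)
  if (length(sig_windows) != nrow(means))
    stop("`sig_windows` must have one entry per window")
  ord <- coloc_item_order(colnames(means), layout)
  r_all <- row_cor(means[, ord$a, drop = FALSE], means[, ord$b, drop = FALSE])
  r <- ifelse(sig_windows, r_all, NA_real_)
  use <- which(sig_windows)
  bad <- use[!is.finite(r_all[use])]
  if (length(bad))
    warning("skipping window(s) with zero variance: ",
            paste(bad, collapse = ", "))
  keep <- use[is.finite(r_all[use])]
  rbar <- if (length(keep)) fisher_mean_r(r_all[keep]) else NA_real_
  list(r = r, rbar = rbar, n_windows_used = length(keep))
}

#' Permutation test for the co-location index
#'
#' The null is built by shuffling the item labels across trials (trial
#' counts per item preserved), recomputing the per-item means and r-bar
#' with the same significant-window mask each time; this breaks every
#' item-response association, so a unitized neuron's observed index is
#' extreme at the resolution of the permutation count.  Two-tailed p with
#' the add-one correction, so p is never exactly zero.
#'
#' @param rates trials x windows matrix of single-trial firing rates.
#' @param items item label per trial.
#' @inheritParams colocation_index
#' @param n_perm number of permutations (>= 100; the recorded analyses
#'   used 10,000).
#' @param seed RNG seed.
#' @return list with observed `rbar`, `p` (two-tailed), `n_perm`.
#' @export
colocation_index_permutation <- function(rates, items, sig_windows,
                                         layout = cmp_layout(),
                                         n_perm = 10000, seed = 1L) {
  if (n_perm < 100) stop("`n_perm` must be at least 100")
  rates <- as.matrix(rates)
  items <- as.character(items)
  cnt <- as.vector(table(items))
  item_levels <- sort(unique(items))
  obs_means <- t(rowsum(rates, items) / cnt)
  colnames(obs_means) <- item_levels
  obs <- suppressWarnings(colocation_index(obs_means, sig_windows, layout))
  if (!is.finite(obs$rbar))
    stop("co-location index undefined (no usable significant window)")
  y <- rates[, sig_windows, drop = FALSE]
  ord <- coloc_item_order(item_levels, layout)
  null <- withr_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      m <- t(rowsum(y, sample(items)) / cnt)
      r <- row_cor(m[, ord$a, drop = FALSE], m[, ord$b, drop = FALSE])
      fisher_mean_r(r[is.finite(r)])
    }, 1)
  })
  null <- null[is.finite(null)]
  p <- (1 + sum(abs(null) >= abs(obs$rbar))) / (1 + length(null))
  list(rbar = obs$rbar, p = p, n_perm = n_perm, null = null)
}

#' Full co-location-index analysis for one neuron
#'
#' Runs the per-window item screen (one-way ANOVA over the 8 items at the
#' Bonferroni-consistent per-window threshold), computes the index over
#' the significant windows, and attaches the permutation p value.
#'
#' @param session a `cmp_session`.
#' @param neuron neuron id.
#' @param align epoch (`"item_on"` for the item-cue period, `"bg_on"` for
#'   the background-cue period).
#' @param alpha family-wise level of the screen.
#' @param per_window_alpha per-window threshold; defaults to
#'   `alpha / n_windows` (0.00125), the Bonferroni-consistent value.
#' @param n_perm,seed forwarded to [colocation_index_permutation()]
#'   (`n_perm = 0` skips the permutation test).
#' @return list with `rbar`, per-window `r`, `sig_windows`, and `p`
#'   (NA when `n_perm = 0` or the index is undefined).
#' @export
colocation_analysis <- function(session, neuron, align = "item_on",
                                alpha = 0.01, per_window_alpha = NULL,
                                n_perm = 1000, seed = 1L) {
  iw <- item_window_means(session, neuron, align)
  scr <- anova1_F(iw$rates, iw$items)
  if (is.null(per_window_alpha))
    per_window_alpha <- alpha / length(scr$p)
  sig <- !is.na(scr$p) & scr$p < per_window_alpha
  res <- suppressWarnings(colocation_index(iw$means, sig, session$layout))
  p <- NA_real_
  if (n_perm > 0 && is.finite(res$rbar))
    p <- colocation_index_permutation(iw$rates, iw$items, sig,
                                      session$layout,
                                      n_perm = n_perm, seed = seed)$p
  list(rbar = res$rbar, r = res$r, sig_windows = sig, p = p,
       per_window_alpha = per_window_alpha)
}

#' Area under the empirical ROC curve
#'
#' Discriminability of two sets of single-trial firing rates: the
#' probability that a random group-1 trial exceeds a random group-2 trial,
#' ties counted one half (the normalized Mann-Whitney U statistic,
#' equivalent to sweeping a rate criterion and integrating the cumulative
#' trial proportions).
#'
#' @param x1,x2 firing rates (typically 60-1000 ms means) for the two
#'   trial groups; both non-empty.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  if (n1 == 0L || n2 == 0L) stop("both trial groups must be non-empty")
  r <- rank(c(x1, x2))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Permutation test of an AUC with re-determination of the optimal group
#'
#' Trials of the two groups are pooled and re-partitioned `n_perm` times;
#' at each shuffle the partition with the higher mean rate is relabeled
#' "optimal" before the AUC is computed, exactly mirroring how the optimal
#' item is determined from the data.  Because of this re-determination the
#' null median exceeds 0.5 for finite trial counts.  One-tailed p:
#' fraction of null AUCs at or above the observed one (add-one corrected).
#'
#' @param x_opt rates for the optimal group (higher observed mean).
#' @param x_other rates for the comparison group.
#' @param n_perm number of shuffles (>= 100; 10,000 in the recorded
#'   analyses).
#' @param seed RNG seed.
#' @param comparison label recorded in the result (e.g.
#'   `"optimal_vs_pair"` or `"best_colocation_vs_others"`).
#' @return list with `auc`, `null_median`, `p`, `n_perm`, `comparison`.
#' @export
auc_permutation <- function(x_opt, x_other, n_perm = 10000, seed = 1L,
                            comparison = "optimal_vs_pair") {
  if (n_perm < 100) stop("`n_perm` must be at least 100")
  obs <- roc_auc(x_opt, x_other)
  pool <- c(x_opt, x_other)
  n1 <- length(x_opt); n <- length(pool)
  null <- withr_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, n1)
      g1 <- pool[idx]; g2 <- pool[-idx]
      if (mean(g2) > mean(g1)) { tmp <- g1; g1 <- g2; g2 <- tmp }
      roc_auc(g1, g2)
    }, 1)
  })
  list(auc = obs, null_median = stats::median(null),
       p = (1 + sum(null >= obs)) / (1 + n_perm),
       n_perm = n_perm, comparison = comparison)
}

#' ROC discrimination analyses for one neuron
#'
#' Determines the optimal item (largest 60-1000 ms mean over correct
#' trials) and its paired co-location item, then evaluates (i) optimal vs
#' pair discriminability and (ii) best co-location vs other co-locations,
#' each with the re-determination permutation null.
#'
#' @param session a `cmp_session`.
#' @param neuron neuron id.
#' @param align epoch alignment.
#' @param n_perm,seed forwarded to [auc_permutation()].
#' @return list with `optimal_item`, `pair_item`, and the two
#'   [auc_permutation()] results `item_discrimination` and
#'   `colocation_discrimination`.
#' @export
roc_analysis <- function(session, neuron, align = "item_on",
                         n_perm = 1000, seed = 1L) {
  tr <- session$trials
  corr <- tr[tr$correct, , drop = FALSE]
  rates <- mean_rate(session, align, trials = corr$trial_id,
                     neurons = neuron)
  items <- corr$item
  per_item <- tapply(rates, items, mean)
  optimal <- names(which.max(per_item))
  cl <- item_colocation(optimal, session$layout)
  pair <- setdiff(names(session$layout$item_to_colocation)[
    session$layout$item_to_colocation == cl], optimal)
  best_cl <- items %in% c(optimal, pair)
  item_disc <- auc_permutation(rates[items == optimal],
                               rates[items == pair],
                               n_perm, seed, "optimal_vs_pair")
  coloc_disc <- auc_permutation(rates[best_cl], rates[!best_cl],
                                n_perm, seed + 1L,
                                "best_colocation_vs_others")
  list(optimal_item = optimal, pair_item = pair,
       item_discrimination = item_disc,
       colocation_discrimination = coloc_disc)
}

#' Co-location index from a per-item response table on disk
#'
#' Computes the index from a CSV of per-item responses -- the format of a
#' published per-neuron source-data table: a column `item` with the 8 item
#' labels and one numeric column per analysis window (a single response
#' column gives the single-window index, which equals that window's r).
#' All rows are treated as significant windows unless a mask is given.
#'
#' @param path CSV file.
#' @param sig_windows optional logical mask over the response columns.
#' @param layout a [cmp_layout()].
#' @return as [colocation_index()].
#' @export
colocation_index_from_table <- function(path, sig_windows = NULL,
                                        layout = cmp_layout()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"item" %in% names(df))
    stop("table must contain an `item` column")
  m <- t(as.matrix(df[, setdiff(names(df), "item"), drop = FALSE]))
  colnames(m) <- df$item
  if (is.null(sig_windows)) sig_windows <- rep(TRUE, nrow(m))
  colocation_index(m, sig_windows, layout)
}
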