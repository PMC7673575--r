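#' @title Nested three-way ANOVA design for the background-cue period
#'
#' @description Builds the fixed-effects design used to screen neurons
#' after background onset: main effects of co-location (3 df), background
#' orientation (2 df, orientations -90/0/90 only) and target location
#' (3 df), with the 8 item cues nested under their co-locations (4 df,
#' a set-A-vs-set-B contrast within each co-location).  All factors use
#' sum-to-zero coding, and per-factor F statistics come from model
#' comparison against the full model's residual (a Type-III-like
#' treatment, appropriate because pseudorandom schedules are only
#' approximately balanced).
#'
#' Because the target is determined by the (co-location, orientation)
#' combination, the design is a Latin-rectangle-constrained one; the
#' function verifies estimability (full column rank) and names the
#' offending factor when levels are missing.
#'
#' @param trials trials table restricted to the trials entering the ANOVA
#'   (correct trials with -90, 0, 90 deg backgrounds).
#' @param include_item drop the nested item term to obtain the plain
#'   crossed three-way main-effects ANOVA.
#' @return object of class `cmp_nested_design`: list of QR factor bases
#'   (`q_full`, `q_drop` per factor), per-factor df, residual df, and
#'   `rank_ok` diagnostics.
#' @export
nested_design <- function(trials, include_item = TRUE) {
  n <- nrow(trials)
  need <- list(colocation = c("I", "II", "III", "IV"),
               background = c(-90, 0, 90))
  if (length(unique(trials$colocation)) < 4L)
    stop("rank-deficient design: factor `colocation` has missing levels")
  if (!setequal(unique(trials$orientation_deg), c(-90, 0, 90)))
    stop("rank-deficient design: factor `background` requires orientations -90, 0, 90")
  if (length(unique(trials$target_deg)) < 4L)
    stop("rank-deficient design: factor `target` has missing levels")
  sum_code <- function(f) {
    f <- factor(f)
    stats::model.matrix(~f, contrasts.arg = list(f = "contr.sum"))[, -1,
                                                                   drop = FALSE]
  }
  xc <- sum_code(trials$colocation)
  xb <- sum_code(trials$orientation_deg)
  xt <- sum_code(trials$target_deg)
  # item within co-location: +1 for the set-A item, -1 for the set-B item
  set_sign <- ifelse(item_set(as.character(trials$item)) == "A", 1, -1)
  xi <- sapply(sort(unique(as.character(trials$colocation))), function(cl) {
    ifelse(as.character(trials$colocation) == cl, set_sign, 0)
  })
  blocks <- list(colocation = xc, background = xb, target = xt, item = xi)
  if (!include_item) blocks$item <- NULL
  x_full <- cbind(`(Intercept)` = 1, do.call(cbind, blocks))
  qr_full <- qr(x_full)
  rank_ok <- qr_full$rank == ncol(x_full)
  if (!rank_ok)
    stop("rank-deficient design: the Latin-rectangle constraint leaves ",
         ncol(x_full) - qr_full$rank, " non-estimable column(s)")
  q_of <- function(x) qr.Q(qr(x))[, seq_len(qr(x)$rank), drop = FALSE]
  q_full <- qr.Q(qr_full)[, seq_len(qr_full$rank), drop = FALSE]
  q_drop <- lapply(names(blocks), function(f) {
    x_r <- cbind(1, do.call(cbind, blocks[setdiff(names(blocks), f)]))
    q_of(x_r)
  })
  names(q_drop) <- names(blocks)
  structure(list(q_full = q_full, q_drop = q_drop,
                 df = vapply(blocks, ncol, 1L),
                 df_res = n - qr_full$rank, n = n, rank_ok = rank_ok),
            class = "cmp_nested_design")
}

# residual sum of squares of each column of Y against basis Q
rss_against <- function(y, q) {
  y <- as.matrix(y)
  colSums(y^2) - colSums(crossprod(q, y)^2)
}

#' Per-factor F statistics under a nested design
#'
#' @param design a [nested_design()].
#' @param y numeric matrix (trials x responses); each column is tested.
#' @return list of matrices `F` and `p` (factor x response).  Responses
#'   with zero residual variation give `NA` (reported as not selective).
#' @export
nested_F <- function(design, y) {
  y <- as.matrix(y)
  rss_f <- rss_against(y, design$q_full)
  fmat <- matrix(NA_real_, length(design$df), ncol(y),
                 dimnames = list(names(design$df), colnames(y)))
  for (f in names(design$df)) {
    rss_r <- rss_against(y, design$q_drop[[f]])
    fmat[f, ] <- ((rss_r - rss_f) / design$df[[f]]) /
      (rss_f / design$df_res)
  }
  fmat[, rss_f <= 1e-10 * pmax(colSums(y^2), 1)] <- NA_real_
  pmat <- fmat
  for (f in names(design$df))
    pmat[f, ] <- stats::pf(fmat[f, ], design$df[[f]], design$df_res,
                           lower.tail = FALSE)
  list(F = fmat, p = pmat, df = design$df, df_res = design$df_res)
}

#' One-way ANOVA F across stimulus groups, vectorized over responses
#'
#' Classical one-way decomposition: between-group over within-group mean
#' squares.  Used for the item screen (8 item-cue stimuli as the factor).
#'
#' @param y numeric matrix (trials x responses).
#' @param group factor of length `nrow(y)`.
#' @return list with vectors `F`, `p`, and dfs.  Zero within-group
#'   variance yields `NA` (not selective).
#' @export
anova1_F <- function(y, group) {
  y <- as.matrix(y)
  group <- factor(group)
  cnt <- as.vector(table(group))
  if (any(cnt < 2L))
    stop("group(s) with fewer than 2 trials: ",
         paste(levels(group)[cnt < 2L], collapse = ", "))
  n <- nrow(y); k <- nlevels(group)
  gsum <- rowsum(y, group)
  gmean <- gsum / cnt
  grand <- colMeans(y)
  ssb <- colSums(cnt * sweep(gmean, 2, grand)^2)
  sst <- colSums(sweep(y, 2, grand)^2)
  ssw <- pmax(sst - ssb, 0)
  fv <- (ssb / (k - 1)) / (ssw / (n - k))
  fv[ssw <= 1e-10 * pmax(sst, 1)] <- NA_real_
  list(F = fv, p = stats::pf(fv, k - 1, n - k, lower.tail = FALSE),
       df1 = k - 1, df2 = n - k)
}

#' Item-selectivity screen over the 8 analysis windows
#'
#' One-way ANOVA with the 8 item-cue stimuli as the main factor, applied
#' to each 300-ms window; the neuron is flagged item-selective when any
#' window's p falls below the Bonferroni-adjusted threshold
#' (`alpha / n_windows`).
#'
#' @param rates trials x windows matrix of firing rates for one neuron
#'   (correct trials only).
#' @param items item label per trial.
#' @param alpha family-wise level (default 0.01).
#' @return list with per-window `F`, `p`, `selective` flag and the
#'   per-window threshold used.
#' @export
anova1_item <- function(rates, items, alpha = 0.01) {
  res <- anova1_F(rates, items)
  thr <- alpha / ncol(as.matrix(rates))
  list(F = res$F, p = res$p, df1 = res$df1, df2 = res$df2,
       per_window_alpha = thr,
       selective = any(res$p < thr, na.rm = TRUE))
}

#' Nested three-way ANOVA screen over the 8 analysis windows
#'
#' @param rates trials x windows matrix for one neuron (correct trials
#'   with -90/0/90 deg backgrounds).
#' @param trials the matching trials table (same row order).
#' @param alpha family-wise level.
#' @param design optionally a precomputed [nested_design()].
#' @return list with factor x window `F` and `p` matrices, per-factor
#'   selectivity flags and the per-window threshold.
#' @export
nested_anova3 <- function(rates, trials, alpha = 0.01, design = NULL) {
  if (is.null(design)) design <- nested_design(trials)
  res <- nested_F(design, rates)
  thr <- alpha / ncol(as.matrix(rates))
  flags <- apply(res$p < thr, 1, any, na.rm = TRUE)
  c(res, list(per_window_alpha = thr, selective = flags))
}

#' Classify every neuron of a session
#'
#' Runs the item-cue-period one-way screen and the background-cue-period
#' nested three-way screen for all neurons, applying the 1 Hz mean-rate
#' inclusion floor first.  Item selectivity during the background period is
#' screened with the same one-way ANOVA applied to background-aligned
#' windows.
#'
#' @param session a `cmp_session`.
#' @param alpha family-wise level per screen (default 0.01, Bonferroni
#'   over the 8 windows).
#' @param min_rate inclusion floor on the across-trial mean rate, Hz.
#' @return data.frame (one row per neuron) with mean rate, inclusion flag,
#'   and the selectivity flags `item_icue`, `item_bcue`, `colocation`,
#'   `background`, `target`, `convergent` (= colocation & background).
#' @export
screen_neurons <- function(session, alpha = 0.01, min_rate = 1) {
  tr <- session$trials
  corr <- tr[tr$correct, , drop = FALSE]
  nested_tr <- corr[corr$orientation_deg %in% c(-90, 0, 90), , drop = FALSE]
  neuron_ids <- sort(unique(session$truth$neuron_id %||%
                              session$spikes$neuron_id))
  # inclusion: mean rate over the whole [-500, 2000) trial window
  whole <- binned_rates(session, "item_on", windows = cbind(-500, 2000))
  mean_hz <- rowMeans(whole$rates[, , 1, drop = TRUE])
  included <- mean_hz >= min_rate

  flag_any <- function(p, thr) apply(p < thr, 2, any, na.rm = TRUE)

  # item screen, item-cue period (all correct trials)
  b_i <- binned_rates(session, "item_on", trials = corr$trial_id)
  y_i <- flatten_binned(b_i)
  a_i <- anova1_F(y_i, corr$item[match(b_i$trial_id, corr$trial_id)])
  p_i <- matrix(a_i$p, nrow = dim(b_i$rates)[3])  # windows x neurons
  item_icue <- flag_any(p_i, alpha / dim(b_i$rates)[3])

  # item screen, background-cue period
  b_ib <- binned_rates(session, "bg_on", trials = corr$trial_id)
  a_ib <- anova1_F(flatten_binned(b_ib),
                   corr$item[match(b_ib$trial_id, corr$trial_id)])
  p_ib <- matrix(a_ib$p, nrow = dim(b_ib$rates)[3])
  item_bcue <- flag_any(p_ib, alpha / dim(b_ib$rates)[3])

  # nested screen, background-cue period (-90/0/90 only)
  b_n <- binned_rates(session, "bg_on", trials = nested_tr$trial_id)
  des <- nested_design(nested_tr[match(b_n$trial_id, nested_tr$trial_id), ])
  res_n <- nested_F(des, flatten_binned(b_n))
  nw <- dim(b_n$rates)[3]
  thr <- alpha / nw
  per_factor <- lapply(rownames(res_n$p), function(f) {
    flag_any(matrix(res_n$p[f, ], nrow = nw), thr)
  })
  names(per_factor) <- rownames(res_n$p)

  out <- data.frame(
    neuron_id = b_i$neuron_id,
    mean_rate_hz = mean_hz[as.character(b_i$neuron_id)],
    included = included[as.character(b_i$neuron_id)],
    item_icue = item_icue, item_bcue = item_bcue,
    colocation = per_factor$colocation,
    background = per_factor$background,
    target = per_factor$target,
    item_nested = per_factor$item,
    row.names = NULL)
  excl <- !out$included
  for (cl in c("item_icue", "item_bcue", "colocation", "background",
               "target", "item_nested"))
    out[[cl]][excl] <- FALSE
  out$convergent <- out$colocation & out$background
  attr(out, "alpha") <- alpha
  attr(out, "per_window_alpha") <- thr
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# trials x (window per neuron) matrix from a cmp_binned array, ordered so
# that matrix(x, nrow = n_windows) gives windows x neurons blocks
flatten_binned <- function(b) {
  a <- aperm(b$rates, c(2, 3, 1))  # trial x window x neuron
  dim(a) <- c(dim(a)[1], dim(a)[2] * dim(a)[3])
  a
}

#' Time-resolved F values on sliding windows
#'
#' Applies the nested three-way ANOVA to 100-ms windows whose starts move
#' in `step`-ms increments, for one neuron -- the instantaneous
#' signal-amplitude time courses of the task-related factors
#' (p uncorrected, default 0.01).
#'
#' @param session a `cmp_session`.
#' @param neuron neuron id.
#' @param width window width, ms.
#' @param step step between window starts, ms.
#' @param t_range range (relative to item-cue onset) covered by windows.
#' @param alpha uncorrected per-step level.
#' @return list with `starts`, factor x step matrices `F` and `p`, and the
#'   logical significance matrix `sig`.
#' @export
instantaneous_F <- function(session, neuron, width = 100, step = 1,
                            t_range = c(-500, 2000), alpha = 0.01) {
  tr <- session$trials
  use <- tr$correct & tr$orientation_deg %in% c(-90, 0, 90)
  tru <- tr[use, , drop = FALSE]
  sl <- sliding_rates(session, neuron, align = "item_on", width = width,
                      step = step, t_range = t_range,
                      trials = tru$trial_id)
  des <- nested_design(tru[match(sl$trial_id, tru$trial_id), , drop = FALSE])
  res <- nested_F(des, sl$rates)
  list(starts = sl$starts, F = res$F, p = res$p,
       sig = res$p < alpha, alpha = alpha, width = width)
}
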