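#' Standard analysis windows
#'
#' The classification screens use 8 consecutive 300-ms windows moving in
#' 100-ms steps, covering 0 to 1000 ms after the alignment event.  Windows
#' are half-open `[start, end)`.
#'
#' @param n number of windows.
#' @param width window width, ms.
#' @param step step between window starts, ms.
#' @param start first window start, ms.
#' @return 2-column matrix (`start`, `end`).
#' @export
analysis_windows <- function(n = 8L, width = 300, step = 100, start = 0) {
  s <- start + step * (seq_len(n) - 1L)
  cbind(start = s, end = s + width)
}

# count spikes per (neuron, trial) cell in [s, e), aligned per trial.
# spikes: data.frame(neuron_id, trial_id, t_ms); align_t: named by trial_id.
count_window <- function(spikes, align_t, s, e, neuron_levels, trial_levels) {
  t_rel <- spikes$t_ms - align_t[as.character(spikes$trial_id)]
  sel <- t_rel >= s & t_rel < e
  ni <- match(spikes$neuron_id[sel], neuron_levels)
  ti <- match(spikes$trial_id[sel], trial_levels)
  matrix(tabulate(ni + length(neuron_levels) * (ti - 1L),
                  nbins = length(neuron_levels) * length(trial_levels)),
         nrow = length(neuron_levels),
         dimnames = list(neuron_levels, trial_levels))
}

#' Windowed firing rates
#'
#' Converts a spikes table into a neuron x trial x window array of firing
#' rates (Hz): spike counts in each half-open `[start, end)` window divided
#' by the window length.  Alignment is to a named event of the trial
#' timeline (`"item_on"` or `"bg_on"`).
#'
#' @param session a `cmp_session`, or a list with `spikes` and `trials`.
#' @param align `"item_on"` or `"bg_on"`.
#' @param windows 2-column matrix from [analysis_windows()].
#' @param trials optional subset of trial ids (defaults to all).
#' @param neurons optional subset of neuron ids.
#' @return object of class `cmp_binned`: list with `rates` (3-d array,
#'   neuron x trial x window), `windows`, `align`, `trial_id`, `neuron_id`.
#' @export
binned_rates <- function(session, align = c("item_on", "bg_on"),
                         windows = analysis_windows(),
                         trials = NULL, neurons = NULL) {
  align <- match.arg(align)
  tr <- session$trials
  ev_col <- paste0(align, "_ms")
  if (!ev_col %in% names(tr))
    stop("alignment event `", align, "` missing from trials table")
  if (!is.null(trials)) tr <- tr[tr$trial_id %in% trials, , drop = FALSE]
  sp <- session$spikes
  sp <- sp[sp$trial_id %in% tr$trial_id, , drop = FALSE]
  if (!is.null(neurons)) sp <- sp[sp$neuron_id %in% neurons, , drop = FALSE]
  neuron_levels <- if (is.null(neurons)) sort(unique(session$spikes$neuron_id))
                   else sort(unique(neurons))
  trial_levels <- tr$trial_id
  align_t <- stats::setNames(tr[[ev_col]], tr$trial_id)
  arr <- array(0, dim = c(length(neuron_levels), length(trial_levels),
                          nrow(windows)),
               dimnames = list(neuron_levels, trial_levels, NULL))
  for (w in seq_len(nrow(windows))) {
    cnt <- count_window(sp, align_t, windows[w, 1], windows[w, 2],
                        neuron_levels, trial_levels)
    arr[, , w] <- cnt / ((windows[w, 2] - windows[w, 1]) / 1000)
  }
  structure(list(rates = arr, windows = windows, align = align,
                 trial_id = trial_levels, neuron_id = neuron_levels),
            class = "cmp_binned")
}

#' Mean firing rate in a single window
#'
#' The workhorse 60-1000 ms window after an alignment event, used to pick
#' optimal items, best co-locations and best targets.
#'
#' @inheritParams binned_rates
#' @param start,end window bounds, ms (half-open).
#' @return neuron x trial matrix of rates in Hz.
#' @export
mean_rate <- function(session, align = c("item_on", "bg_on"),
                      start = 60, end = 1000, trials = NULL, neurons = NULL) {
  b <- binned_rates(session, align, windows = cbind(start, end),
                    trials = trials, neurons = neurons)
  b$rates[, , 1, drop = TRUE]
}

#' Gaussian spike-density function
#'
#' Sum of Gaussian bumps (area one spike each, sigma in ms, truncated at
#' +/- 5 sigma) evaluated on a 1-ms grid, expressed in Hz.
#'
#' @param spike_times spike times, ms.
#' @param sigma kernel standard deviation, ms (> 0).
#' @param t_range grid range `c(from, to)`, ms.
#' @param step grid step, ms.
#' @return object of class `cmp_sdf`: list with `time` and `rate_hz`.
#' @export
sdf <- function(spike_times, sigma = 20, t_range = c(-500, 2000), step = 1) {
  if (sigma <= 0) stop("`sigma` must be positive")
  grid <- seq(t_range[1], t_range[2], by = step)
  rate <- numeric(length(grid))
  half <- 5 * sigma
  for (ts in spike_times) {
    lo <- max(1L, ceiling((ts - half - t_range[1]) / step) + 1L)
    hi <- min(length(grid), floor((ts + half - t_range[1]) / step) + 1L)
    if (lo > hi) next
    idx <- lo:hi
    rate[idx] <- rate[idx] + stats::dnorm(grid[idx], ts, sigma) * 1000
  }
  structure(list(time = grid, rate_hz = rate, sigma = sigma),
            class = "cmp_sdf")
}

#' Trial-averaged SDF for a set of trials of one neuron
#'
#' Averages per-trial SDFs (each aligned to the named event) across trials.
#'
#' @param session a `cmp_session`.
#' @param neuron neuron id.
#' @param trial_ids trials to average over.
#' @inheritParams sdf
#' @param align alignment event.
#' @return a `cmp_sdf` (the across-trial mean rate).
#' @export
mean_sdf <- function(session, neuron, trial_ids, sigma = 20,
                     t_range = c(-500, 2000), step = 1,
                     align = c("item_on", "bg_on")) {
  align <- match.arg(align)
  tr <- session$trials
  ev <- stats::setNames(tr[[paste0(align, "_ms")]], tr$trial_id)
  sp <- session$spikes
  sp <- sp[sp$neuron_id == neuron & sp$trial_id %in% trial_ids, ,
           drop = FALSE]
  t_rel <- sp$t_ms - ev[as.character(sp$trial_id)]
  s <- sdf(t_rel, sigma, t_range, step)
  s$rate_hz <- s$rate_hz / length(trial_ids)
  s
}

#' Sliding-window firing rates
#'
#' Rates in a dense family of half-open windows of the given width whose
#' starts move in `step`-ms increments -- the 100-ms / 1-ms sliding bins of
#' the time-resolved analyses.
#'
#' @inheritParams binned_rates
#' @param width window width, ms (> 0).
#' @param step step between window starts, ms.
#' @param t_range range covered: windows start at `t_range[1]` and the last
#'   window ends at or before `t_range[2]`.
#' @return list with `starts` (window start times), `rates` (trial x step
#'   matrix, Hz) for the single requested neuron, and `width`.
#' @export
sliding_rates <- function(session, neuron, align = c("item_on", "bg_on"),
                          width = 100, step = 1, t_range = c(0, 1000),
                          trials = NULL) {
  if (width <= 0) stop("`width` must be positive")
  align <- match.arg(align)
  tr <- session$trials
  if (!is.null(trials)) tr <- tr[tr$trial_id %in% trials, , drop = FALSE]
  ev <- stats::setNames(tr[[paste0(align, "_ms")]], tr$trial_id)
  starts <- seq(t_range[1], t_range[2] - width, by = step)
  sp <- session$spikes
  sp <- sp[sp$neuron_id == neuron & sp$trial_id %in% tr$trial_id, ,
           drop = FALSE]
  rates <- matrix(0, nrow(tr), length(starts),
                  dimnames = list(tr$trial_id, NULL))
  t_rel <- sp$t_ms - ev[as.character(sp$trial_id)]
  for (i in seq_len(nrow(tr))) {
    t_i <- sort(t_rel[sp$trial_id == tr$trial_id[i]])
    # count in [s, s+width) = #{t < s+width} - #{t < s}
    n_lo <- findInterval(starts, t_i, left.open = TRUE)
    n_hi <- findInterval(starts + width, t_i, left.open = TRUE)
    rates[i, ] <- (n_hi - n_lo) / (width / 1000)
  }
  list(starts = starts, rates = rates, width = width, align = align,
       trial_id = tr$trial_id)
}
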