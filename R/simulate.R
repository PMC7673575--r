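#' Ground-truth specification of a simulated neuron
#'
#' Each synthetic neuron belongs to one archetype mirroring the response
#' classes observed in the hippocampus during the CMP task:
#' \describe{
#'   \item{untuned}{constant baseline firing.}
#'   \item{item_unitized}{responds during the item-cue period and delay 1 to
#'     both items of its preferred co-location -- "unitized" coding of the
#'     retrieved location.  `unitization` scales the gain passed on to the
#'     non-driving (set-B) item of the pair.}
#'   \item{item_nonunitized}{as above with `unitization = 0`: a purely
#'     item-selective response without a co-location memory effect.}
#'   \item{background}{responds during the background-cue period whenever
#'     the background orientation matches its preferred orientation,
#'     irrespective of the item.}
#'   \item{convergent}{carries a co-location signal from the end of the
#'     item-cue period into the early background period and adds a
#'     background-orientation gain shortly after background onset, so both
#'     effects transiently overlap on the same cell.}
#'   \item{transferring}{fires when the instructed/chosen target equals its
#'     preferred target location *and* the background is rotated away from
#'     0 deg -- the retrieved location has been transferred onto its
#'     preferred position.}
#'   \item{targeting}{fires late in the background period whenever the
#'     target equals its preferred location regardless of the cues, plus an
#'     item-period component whenever the cued co-location's
#'     default-orientation (0 deg) position equals the preferred target.}
#'   \item{multiphase}{convergence, then transference, then targeting in
#'     successive windows of the background period, on top of an item-period
#'     co-location response.}
#' }
#'
#' For the target-coding archetypes the rate follows a `choice_weight`
#' (kappa) mixture of the instructed and the chosen target: kappa = 1 means
#' the cell's target signal tracks what the animal is about to choose (so
#' on error trials it follows the erroneous choice), kappa = 0 means it
#' tracks the instructed correct position.
#'
#' @param neuron_id integer id.
#' @param archetype one of [cmp_archetypes()].
#' @param preferred_colocation co-location label, for co-location-coding
#'   archetypes.
#' @param preferred_orientation background orientation (deg), for
#'   background-coding archetypes.
#' @param preferred_target screen angle (deg), for target-coding archetypes.
#' @param baseline_rate baseline firing rate in Hz (>= 1, matching the
#'   1 Hz inclusion floor applied to recorded cells).
#' @param gain rate in Hz added when the preferred condition holds;
#'   defaults to twice the baseline.
#' @param unitization fraction in `[0, 1]` of the gain shared by the paired
#'   co-location item.
#' @param choice_weight kappa in `[0, 1]`; only meaningful for
#'   target-coding archetypes.
#' @param windows optional named list overriding the archetype's response
#'   windows (ms relative to item-cue onset), each `c(start, end)` within
#'   `[0, 2000]`.
#' @return an object of class `cmp_neuron_spec`.
#' @export
neuron_spec <- function(neuron_id, archetype,
                        preferred_colocation = "I",
                        preferred_orientation = 90,
                        preferred_target = 315,
                        baseline_rate = 5,
                        gain = 2 * baseline_rate,
                        unitization = 1,
                        choice_weight = 1,
                        windows = NULL) {
  archetype <- match.arg(archetype, cmp_archetypes())
  if (baseline_rate < 1)
    stop("`baseline_rate` must be >= 1 Hz (recording inclusion floor)")
  if (unitization < 0 || unitization > 1)
    stop("`unitization` must lie in [0, 1]")
  if (choice_weight < 0 || choice_weight > 1)
    stop("`choice_weight` must lie in [0, 1]")
  win <- archetype_windows(archetype)
  if (!is.null(windows)) win[names(windows)] <- windows
  for (w in win) {
    if (w[1] < 0 || w[2] > 2000 || w[2] <= w[1])
      stop("response windows must be increasing and lie within [0, 2000] ms")
  }
  structure(list(neuron_id = as.integer(neuron_id), archetype = archetype,
                 preferred_colocation = preferred_colocation,
                 preferred_orientation = preferred_orientation,
                 preferred_target = as.integer(preferred_target) %% 360L,
                 baseline_rate = baseline_rate, gain = gain,
                 unitization = unitization, choice_weight = choice_weight,
                 windows = win),
            class = "cmp_neuron_spec")
}

#' @rdname neuron_spec
#' @export
cmp_archetypes <- function() {
  c("untuned", "item_unitized", "item_nonunitized", "background",
    "convergent", "transferring", "targeting", "multiphase")
}

# default response windows per archetype, ms from item-cue onset.
# The background cue appears at 1000 ms; the convergence window covers
# roughly 200-500 ms after background onset (where tuning similarity across
# co-locations is observed), transference the 300-800 ms epoch, targeting
# the late background period and delay 2.
archetype_windows <- function(archetype) {
  switch(archetype,
    untuned = list(),
    item_unitized = ,
    item_nonunitized = list(item = c(60, 1000)),
    background = list(background = c(1060, 2000)),
    convergent = list(colocation = c(700, 1500), background = c(1200, 1500)),
    transferring = list(transfer = c(1300, 1800)),
    targeting = list(item = c(60, 1000), target = c(1500, 2000)),
    multiphase = list(item = c(60, 1000), convergence = c(1200, 1400),
                      transfer = c(1400, 1700), target = c(1700, 2000)))
}

#' Piecewise-constant firing-rate profile of a neuron on one trial
#'
#' Applies the archetype rules of [neuron_spec()] to a fully specified trial
#' (including the animal's choice) and returns the trial's rate function
#' over `[-500, 2000]` ms as a piecewise-constant profile.  Rates are
#' clamped at zero.
#'
#' @param spec a [neuron_spec()].
#' @param trial one row of a trials table (list or data.frame row) with at
#'   least `item`, `colocation`, `orientation_deg`, `target_deg`,
#'   `choice_deg`.
#' @param layout the [cmp_layout()] used to generate the session.
#' @return object of class `cmp_rate_profile`: list with `breaks` (k+1
#'   boundaries, ms) and `rates` (k segment rates, Hz).
#' @export
rate_profile <- function(spec, trial, layout = cmp_layout()) {
  segs <- list()  # each c(start, end, delta_hz)
  add <- function(win, delta) {
    if (delta != 0) segs[[length(segs) + 1L]] <<- c(win[1], win[2], delta)
  }
  coloc <- as.character(trial$colocation)
  theta <- as.numeric(trial$orientation_deg)
  kappa <- spec$choice_weight
  # mixture weight on the preferred target: instructed vs chosen
  target_drive <- function() {
    instructed <- as.numeric(trial$target_deg) %% 360 == spec$preferred_target
    chosen <- !is.na(trial$choice_deg) &&
      as.numeric(trial$choice_deg) %% 360 == spec$preferred_target
    (1 - kappa) * instructed + kappa * chosen
  }
  # graded co-location tuning: the preferred co-location gets the full
  # gain, the others a decaying fraction by cyclic distance (recorded item
  # responses are graded over items, not all-or-none); within a
  # co-location the set-B item's share is scaled by `unitization`
  coloc_drive <- function() {
    colocs <- names(layout$default_angle)
    d <- (match(coloc, colocs) - match(spec$preferred_colocation, colocs)) %% 4L
    prof <- c(1, 0.4, 0.15, 0.05)[d + 1L]
    if (item_set(as.character(trial$item)) == "A") prof
    else prof * spec$unitization
  }
  w <- spec$windows
  switch(spec$archetype,
    untuned = NULL,
    item_unitized = ,
    item_nonunitized = add(w$item, spec$gain * coloc_drive()),
    background = add(w$background,
                     spec$gain * (theta == spec$preferred_orientation)),
    convergent = {
      add(w$colocation, spec$gain * coloc_drive())
      add(w$background,
          spec$gain * (theta == spec$preferred_orientation))
    },
    transferring = add(w$transfer,
                       spec$gain * target_drive() * (theta != 0)),
    targeting = {
      dflt <- target_location(coloc, 0, layout)
      add(w$item, spec$gain * (dflt == spec$preferred_target))
      add(w$target, spec$gain * target_drive())
    },
    multiphase = {
      add(w$item, spec$gain * coloc_drive())
      add(w$convergence, spec$gain * coloc_drive() +
            spec$gain * (theta == spec$preferred_orientation))
      add(w$transfer, spec$gain * target_drive() * (theta != 0))
      add(w$target, spec$gain * target_drive())
    })
  brk <- sort(unique(c(-500, 2000, unlist(lapply(segs, function(s) s[1:2])))))
  brk <- brk[brk >= -500 & brk <= 2000]
  rates <- rep(spec$baseline_rate, length(brk) - 1L)
  mid <- (brk[-length(brk)] + brk[-1]) / 2
  for (s in segs)
    rates <- rates + ifelse(mid >= s[1] & mid < s[2], s[3], 0)
  structure(list(breaks = brk, rates = pmax(rates, 0)),
            class = "cmp_rate_profile")
}

#' Evaluate a rate profile at time points
#' @param profile a `cmp_rate_profile`.
#' @param t times in ms.
#' @return rates in Hz (0 outside the profile's support).
#' @export
profile_rate <- function(profile, t) {
  i <- findInterval(t, profile$breaks, rightmost.closed = TRUE)
  out <- rep(0, length(t))
  ok <- i >= 1L & i <= length(profile$rates)
  out[ok] <- profile$rates[i[ok]]
  out
}

#' Sample an inhomogeneous Poisson spike train by thinning
#'
#' Candidate events are drawn from a homogeneous Poisson process at the
#' profile's maximum rate and accepted with probability
#' `rate(t) / max(rate)` -- exact for any bounded rate function, and in
#' particular for the piecewise-constant profiles of [rate_profile()].
#' Reproducibility comes from the R RNG state; seed before calling.
#'
#' @param profile a `cmp_rate_profile` (rates in Hz, times in ms).
#' @return sorted spike times in ms.
#' @export
generate_spikes <- function(profile) {
  if (any(profile$rates < 0)) stop("rate must be non-negative everywhere")
  rmax <- max(profile$rates)
  if (rmax == 0) return(numeric(0))
  t0 <- profile$breaks[1]; t1 <- profile$breaks[length(profile$breaks)]
  n <- stats::rpois(1L, rmax * (t1 - t0) / 1000)
  if (n == 0L) return(numeric(0))
  cand <- sort(stats::runif(n, t0, t1))
  keep <- stats::runif(n) < profile_rate(profile, cand) / rmax
  cand[keep]
}

#' Specification of a synthetic recording session
#'
#' @param counts named integer vector of neurons per archetype (names from
#'   [cmp_archetypes()]).  The default mix scales the recorded data set
#'   (456 cells) across the archetypes.
#' @param n_trials trials per session (the recordings averaged 128).
#' @param orientations background orientations sampled in the schedule.
#' @param error_rate probability that a completed trial ends in an
#'   erroneous choice; errors are uniform over the 3 distracter positions.
#' @param baseline_rate,gain,unitization,choice_weight defaults forwarded
#'   to [neuron_spec()].
#' @param layout a [cmp_layout()].
#' @param seed session seed; expands deterministically into per-neuron
#'   substreams, so adding neurons never perturbs existing ones.
#' @return object of class `cmp_session_spec`.
#' @export
session_spec <- function(counts = c(untuned = 200, item_unitized = 100,
                                    item_nonunitized = 20, background = 40,
                                    convergent = 32, transferring = 24,
                                    targeting = 30, multiphase = 10),
                         n_trials = 128,
                         orientations = c(-90, -45, 0, 45, 90),
                         error_rate = 0.15,
                         baseline_rate = 5, gain = 2 * baseline_rate,
                         unitization = 1, choice_weight = 1,
                         layout = cmp_layout(), seed = 1L) {
  counts <- counts[counts > 0]
  if (!length(counts) || sum(counts) < 1)
    stop("at least one neuron is required")
  bad <- setdiff(names(counts), cmp_archetypes())
  if (length(bad)) stop("unknown archetype(s): ", paste(bad, collapse = ", "))
  if (error_rate < 0 || error_rate >= 1)
    stop("`error_rate` must lie in [0, 1)")
  structure(list(counts = counts, n_trials = n_trials,
                 orientations = orientations, error_rate = error_rate,
                 baseline_rate = baseline_rate, gain = gain,
                 unitization = unitization, choice_weight = choice_weight,
                 layout = layout, seed = as.integer(seed)),
            class = "cmp_session_spec")
}

# deterministic neuron specs for a session spec: preferences cycle through
# co-locations / orientations / targets so the ensemble is balanced.
make_neuron_specs <- function(spec) {
  colocs <- names(spec$layout$default_angle)
  oris <- c(-90, 0, 90)
  targets <- as.integer(spec$layout$default_angle)
  out <- list(); id <- 0L
  for (a in names(spec$counts)) {
    for (k in seq_len(spec$counts[[a]])) {
      id <- id + 1L
      out[[id]] <- neuron_spec(
        neuron_id = id, archetype = a,
        preferred_colocation = colocs[(k - 1L) %% 4L + 1L],
        preferred_orientation = oris[(k - 1L) %% 3L + 1L],
        preferred_target = targets[(k - 1L) %% 4L + 1L],
        baseline_rate = spec$baseline_rate, gain = spec$gain,
        unitization = if (a == "item_nonunitized") 0 else spec$unitization,
        choice_weight = spec$choice_weight)
    }
  }
  out
}

# stable per-neuron substream seed below 2^31
neuron_seed <- function(session_seed, neuron_id) {
  as.integer((as.double(session_seed) %% 65536 * 32749 +
                as.double(neuron_id) * 7919 + 1) %% 2147483629)
}

#' Build a trials table from a schedule
#'
#' Completes a schedule of (item, orientation) configurations into full
#' trials: derives the co-location and target from the layout geometry,
#' draws the animal's choice (correct with probability `1 - error_rate`,
#' otherwise uniform over the 3 distracter positions, i.e. the on-screen
#' images of the other co-locations), and attaches the fixed event
#' timeline (item cue 0-300 ms, background cue 1000-1300 ms, choice onset
#' 2000 ms).
#'
#' @param schedule data.frame from [make_schedule()].
#' @param layout a [cmp_layout()].
#' @param error_rate probability of an erroneous choice.
#' @param seed RNG seed for the choices.
#' @return trials data.frame.
#' @export
build_trials <- function(schedule, layout = cmp_layout(), error_rate = 0,
                         seed = 1L) {
  n <- nrow(schedule)
  coloc <- item_colocation(schedule$item, layout)
  target <- target_location(coloc, schedule$orientation_deg, layout)
  colocs <- names(layout$default_angle)
  choice <- withr_seed(seed, {
    err <- stats::runif(n) < error_rate
    ch <- target
    for (i in which(err)) {
      others <- setdiff(
        target_location(colocs, schedule$orientation_deg[i], layout),
        target[i])
      ch[i] <- others[sample.int(3L, 1L)]
    }
    ch
  })
  ev <- cmp_events()
  data.frame(trial_id = seq_len(n), item = schedule$item,
             colocation = coloc,
             orientation_deg = as.integer(schedule$orientation_deg),
             target_deg = as.integer(target), choice_deg = as.integer(choice),
             correct = choice == target,
             item_on_ms = ev[["item_on"]], item_off_ms = ev[["item_off"]],
             bg_on_ms = ev[["bg_on"]], bg_off_ms = ev[["bg_off"]],
             choice_on_ms = ev[["choice_on"]],
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic session
#'
#' Generates the trial schedule and choices, then samples every neuron's
#' spike trains from its archetype rate profile via Poisson thinning.  The
#' returned session carries the ground-truth archetype table so downstream
#' statistics can be scored against a recoverable truth.
#'
#' @param spec a [session_spec()].
#' @return object of class `cmp_session`: list with `trials`, `spikes`
#'   (`neuron_id`, `trial_id`, `t_ms` aligned to item-cue onset),
#'   `truth` (one row per neuron mirroring its [neuron_spec()]),
#'   `layout`, and `spec`.
#' @export
simulate_session <- function(spec) {
  stopifnot(inherits(spec, "cmp_session_spec"))
  sched <- make_schedule(spec$n_trials, spec$orientations, seed = spec$seed,
                         layout = spec$layout)
  trials <- build_trials(sched, spec$layout, spec$error_rate,
                         seed = spec$seed + 1L)
  nspecs <- make_neuron_specs(spec)
  trial_rows <- lapply(seq_len(nrow(trials)), function(i) as.list(trials[i, ]))
  spk <- lapply(nspecs, function(ns) {
    withr_seed(neuron_seed(spec$seed, ns$neuron_id), {
      res <- lapply(trial_rows, function(tr) {
        generate_spikes(rate_profile(ns, tr, spec$layout))
      })
      # quantize to integer microseconds so CSV round trips are exact
      data.frame(neuron_id = ns$neuron_id,
                 trial_id = rep(trials$trial_id, lengths(res)),
                 t_ms = round(unlist(res) * 1000) / 1000)
    })
  })
  spikes <- do.call(rbind, spk)
  rownames(spikes) <- NULL
  truth <- do.call(rbind, lapply(nspecs, function(ns) {
    data.frame(neuron_id = ns$neuron_id, archetype = ns$archetype,
               preferred_colocation = ns$preferred_colocation,
               preferred_orientation = ns$preferred_orientation,
               preferred_target = ns$preferred_target,
               baseline_rate = ns$baseline_rate, gain = ns$gain,
               unitization = ns$unitization,
               choice_weight = ns$choice_weight,
               stringsAsFactors = FALSE)
  }))
  structure(list(trials = trials, spikes = spikes, truth = truth,
                 layout = spec$layout, spec = spec),
            class = "cmp_session")
}

#' @export
print.cmp_session <- function(x, ...) {
  cat(sprintf("CMP session: %d neurons, %d trials (%.1f%% correct), %d spikes\n",
              length(unique(x$truth$neuron_id)), nrow(x$trials),
              100 * mean(x$trials$correct), nrow(x$spikes)))
  invisible(x)
}
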