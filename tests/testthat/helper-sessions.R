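# Small synthetic sessions shared across test files.  Built once per test
# run; all seeds fixed.

small_session <- local({
  ses <- NULL
  function() {
    if (is.null(ses))
      ses <<- simulate_session(session_spec(
        counts = c(untuned = 4, item_unitized = 4, item_nonunitized = 2,
                   background = 3, convergent = 4, transferring = 3,
                   targeting = 4, multiphase = 2),
        n_trials = 128, seed = 42L))
    ses
  }
})

# a constant-rate profile helper
flat_profile <- function(rate_hz, t0 = 0, t1 = 1000) {
  structure(list(breaks = c(t0, t1), rates = rate_hz),
            class = "cmp_rate_profile")
}

# minimal single-neuron session from explicit per-trial spike lists
manual_session <- function(spike_times_by_trial, trials) {
  spikes <- do.call(rbind, lapply(seq_along(spike_times_by_trial), function(i) {
    ts <- spike_times_by_trial[[i]]
    if (!length(ts)) return(NULL)
    data.frame(neuron_id = 1L, trial_id = trials$trial_id[i], t_ms = ts)
  }))
  if (is.null(spikes))
    spikes <- data.frame(neuron_id = integer(0), trial_id = integer(0),
                         t_ms = numeric(0))
  structure(list(trials = trials, spikes = spikes, truth = NULL,
                 layout = cmp_layout(), spec = NULL),
            class = "cmp_session")
}

make_trials <- function(n, orientations = c(-90, 0, 90), seed = 1L,
                        error_rate = 0) {
  build_trials(make_schedule(n, orientations, seed = seed),
               error_rate = error_rate, seed = seed + 1L)
}
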