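#' Arithmetic of the classification report
#'
#' Small helpers behind the category-count summary: the number of
#' dual-effect neurons expected under independence of two screens, the
#' chance level of the 4-alternative saccade choice, and percentage
#' summaries of counts.
#'
#' @param n1,n2 numbers of neurons passing each screen.
#' @param total number of recorded/simulated neurons.
#' @return `expected_overlap()`: the count expected if the two screens
#'   were independent, `total * (n1/total) * (n2/total)`.
#' @export
expected_overlap <- function(n1, n2, total) {
  (n1 / total) * (n2 / total) * total
}

#' @rdname expected_overlap
#' @param n_alternatives number of choice positions presented.
#' @export
chance_level_pct <- function(n_alternatives = 4) 100 / n_alternatives

#' @rdname expected_overlap
#' @param overlap number of neurons passing both screens.
#' @return `either_effect_pct()`: percentage of neurons passing at least
#'   one of the two screens.
#' @export
either_effect_pct <- function(n1, n2, overlap, total) {
  100 * (n1 + n2 - overlap) / total
}

#' @rdname expected_overlap
#' @param k,n numerator and denominator counts.
#' @export
count_pct <- function(k, n) 100 * k / n

#' Number of distinct (item, orientation) configurations in a schedule
#'
#' @param schedule a data.frame from [make_schedule()].
#' @return integer count (40 for the 8 items x 5 recording orientations).
#' @export
count_configurations <- function(schedule) {
  nrow(unique(schedule[, c("item", "orientation_deg")]))
}

#' Category counts from a selectivity table
#'
#' @param screen data.frame from [screen_neurons()].
#' @return one-row data.frame of counts per category plus the derived
#'   independence-expected convergent count and either-effect percentage.
#' @export
classification_counts <- function(screen) {
  total <- sum(screen$included)
  n_cl <- sum(screen$colocation)
  n_bg <- sum(screen$background)
  n_both <- sum(screen$convergent)
  data.frame(
    n_neurons = nrow(screen), n_included = total,
    item_icue = sum(screen$item_icue), item_bcue = sum(screen$item_bcue),
    colocation = n_cl, background = n_bg, target = sum(screen$target),
    convergent = n_both,
    expected_convergent = expected_overlap(n_cl, n_bg, total),
    either_effect_pct = either_effect_pct(n_cl, n_bg, n_both, total))
}

# which selectivity flag each archetype is expected to trip
archetype_expected_flag <- function() {
  c(item_unitized = "item_icue", item_nonunitized = "item_icue",
    background = "background", convergent = "convergent",
    transferring = "target", targeting = "target", multiphase = "target")
}

#' Ground-truth recovery report for a synthetic session
#'
#' Per-archetype sensitivity of the classification screens (fraction of
#' neurons of each archetype whose expected flag was set) and the
#' specificity on untuned neurons (fraction with no flag at all), plus a
#' confusion table of archetype vs flags.
#'
#' @param screen data.frame from [screen_neurons()].
#' @param truth ground-truth table of the session.
#' @return list with `sensitivity` (named vector), `specificity_untuned`,
#'   and the `confusion` data.frame.
#' @export
recovery_report <- function(screen, truth) {
  m <- merge(screen, truth[, c("neuron_id", "archetype")], by = "neuron_id")
  exp_flag <- archetype_expected_flag()
  archs <- intersect(names(exp_flag), unique(m$archetype))
  sens <- vapply(archs, function(a) {
    rows <- m[m$archetype == a & m$included, , drop = FALSE]
    if (!nrow(rows)) return(NA_real_)
    mean(rows[[exp_flag[[a]]]])
  }, 1)
  flag_cols <- c("item_icue", "colocation", "background", "target")
  untuned <- m[m$archetype == "untuned" & m$included, , drop = FALSE]
  spec <- if (nrow(untuned)) mean(rowSums(untuned[, flag_cols]) == 0)
          else NA_real_
  confusion <- stats::aggregate(
    m[, c("item_icue", "item_bcue", "colocation", "background", "target",
          "convergent")],
    by = list(archetype = m$archetype), FUN = sum)
  list(sensitivity = sens, specificity_untuned = spec,
       confusion = confusion)
}
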