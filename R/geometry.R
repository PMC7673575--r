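#' Task layout: item-to-co-location assignment and default screen angles
#'
#' In the constructive memory-perception (CMP) task, 8 visual items (two
#' "sets" A and B) are assigned pairwise to 4 co-locations (I-IV) on a
#' background image.  Each co-location has a default on-screen angle -- its
#' position when the background is shown at its learned 0 deg orientation.
#' Angles are in degrees counterclockwise from east; the defaults are the
#' 4 diagonals (45, 135, 225, 315).
#'
#' The canonical layout places I at 45 (top-right), II at 315 (bottom-right),
#' III at 225 (bottom-left) and IV at 135 (top-left).  Both the assignment
#' and the angles are configurable because different animals can be trained
#' with different item-location association patterns.
#'
#' @param item_to_colocation named character vector mapping the 8 item
#'   labels to co-location labels `"I".."IV"`; exactly two items (one per
#'   set) must map to each co-location.
#' @param default_angle named integer vector mapping co-locations to their
#'   0-deg-background screen angles; must be a bijection onto
#'   `c(45, 135, 225, 315)`.
#' @return an object of class `cmp_layout`.
#' @export
cmp_layout <- function(item_to_colocation = NULL, default_angle = NULL) {
  colocs <- c("I", "II", "III", "IV")
  if (is.null(item_to_colocation)) {
    items <- c(paste0(colocs, "-A"), paste0(colocs, "-B"))
    item_to_colocation <- stats::setNames(rep(colocs, 2L), items)
  }
  if (is.null(default_angle)) {
    default_angle <- c(I = 45L, II = 315L, III = 225L, IV = 135L)
  }
  if (length(item_to_colocation) != 8L || is.null(names(item_to_colocation)))
    stop("`item_to_colocation` must be a named vector of the 8 item labels")
  if (!setequal(unique(item_to_colocation), colocs))
    stop("items must map onto the 4 co-locations I-IV")
  tab <- table(item_to_colocation)
  if (any(tab != 2L))
    stop("exactly 2 items must be assigned to each co-location")
  sets <- item_set(names(item_to_colocation))
  if (any(is.na(sets)))
    stop("item labels must end in '-A' or '-B'")
  for (cl in colocs) {
    if (!setequal(sets[item_to_colocation == cl], c("A", "B")))
      stop("each co-location needs one set-A and one set-B item")
  }
  if (!setequal(names(default_angle), colocs) ||
      !setequal(as.integer(default_angle), c(45L, 135L, 225L, 315L)))
    stop("`default_angle` must be a bijection from I-IV onto {45,135,225,315}")
  structure(list(item_to_colocation = item_to_colocation,
                 default_angle = as.integer(default_angle[colocs]) |>
                   stats::setNames(colocs)),
            class = "cmp_layout")
}

#' @export
print.cmp_layout <- function(x, ...) {
  cat("CMP task layout\n")
  for (cl in names(x$default_angle)) {
    its <- names(x$item_to_colocation)[x$item_to_colocation == cl]
    cat(sprintf("  co-location %-3s -> %3d deg  (items %s)\n",
                cl, x$default_angle[[cl]], paste(its, collapse = ", ")))
  }
  invisible(x)
}

item_set <- function(item) {
  out <- rep(NA_character_, length(item))
  out[endsWith(item, "-A")] <- "A"
  out[endsWith(item, "-B")] <- "B"
  out
}

#' Rotate a screen angle by a background orientation
#'
#' A positive background orientation displaces locations clockwise on the
#' display, i.e. `rotate_angle(a, theta) == (a - theta) mod 360`.
#'
#' @param angle screen angle(s) in degrees.
#' @param theta background orientation(s) in degrees (multiples of 45).
#' @return rotated angle(s) in `[0, 360)`.
#' @export
rotate_angle <- function(angle, theta) {
  (angle - theta) %% 360
}

#' On-screen target for a (co-location, background orientation) pair
#'
#' The target is the co-location's default angle carried along with the
#' rotated background: `target = (default_angle[colocation] - theta) mod 360`.
#' For example, with the canonical layout, co-location II (315 deg,
#' bottom-right) on a -90 deg background maps to 45 deg (top-right).
#'
#' @param colocation co-location label(s) `"I".."IV"`.
#' @param theta background orientation(s) in degrees; any multiple of 45.
#' @param layout a [cmp_layout()].
#' @return integer screen angle(s) in `{0, 45, ..., 315}`.
#' @export
target_location <- function(colocation, theta, layout = cmp_layout()) {
  colocation <- as.character(colocation)
  bad <- setdiff(unique(colocation), names(layout$default_angle))
  if (length(bad))
    stop("unknown co-location label(s): ", paste(bad, collapse = ", "))
  if (any(theta %% 45 != 0))
    stop("`theta` must be a multiple of 45 degrees")
  as.integer(rotate_angle(layout$default_angle[colocation], theta))
}

#' Co-location assigned to an item
#'
#' @param item item label(s), e.g. `"I-A"`.
#' @inheritParams target_location
#' @return co-location label(s).
#' @export
item_colocation <- function(item, layout = cmp_layout()) {
  item <- as.character(item)
  bad <- setdiff(unique(item), names(layout$item_to_colocation))
  if (length(bad))
    stop("unknown item label(s): ", paste(bad, collapse = ", "))
  unname(layout$item_to_colocation[item])
}

#' Pseudorandom balanced trial schedule
#'
#' Draws a sequence of (item, orientation) configurations using a shuffled
#' balanced-block design: the full set of `8 x length(orientations)`
#' configurations is shuffled and emitted block by block, so configuration
#' counts never differ by more than one.  With `n_trials = 40` and the 5
#' recording-session orientations every configuration appears exactly once.
#'
#' @param n_trials number of trials (>= 1).
#' @param orientations background orientations in degrees; the recording
#'   sessions used `c(-90, -45, 0, 45, 90)`.
#' @param seed integer seed making the schedule reproducible.
#' @param layout a [cmp_layout()]; supplies the item labels.
#' @return data.frame with columns `item`, `orientation_deg`.
#' @export
make_schedule <- function(n_trials, orientations = c(-90, -45, 0, 45, 90),
                          seed = 1L, layout = cmp_layout()) {
  if (length(n_trials) != 1L || n_trials < 1)
    stop("`n_trials` must be a single count >= 1")
  if (length(orientations) == 0L)
    stop("`orientations` must be non-empty")
  items <- names(layout$item_to_colocation)
  grid <- expand.grid(item = items, orientation_deg = orientations,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  k <- nrow(grid)
  n_blocks <- ceiling(n_trials / k)
  idx <- withr_seed(seed, {
    unlist(lapply(seq_len(n_blocks), function(b) sample.int(k)))
  })[seq_len(n_trials)]
  out <- grid[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# fixed trial timeline (ms relative to item-cue onset)
cmp_events <- function() {
  c(item_on = 0L, item_off = 300L, bg_on = 1000L, bg_off = 1300L,
    choice_on = 2000L)
}
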