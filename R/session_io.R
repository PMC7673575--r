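#' Write a session to a directory of CSV files
#'
#' Emits `trials.csv`, `spikes.csv`, `ground_truth.csv` (when ground truth
#' is present) and `manifest.json`.  Spike times are written at
#' microsecond resolution (`t_ms` with 3 decimals), which round-trips
#' exactly because the generator quantizes spike times to integer
#' microseconds.  The manifest records the layout, generation parameters,
#' seed and an md5 hash of the configuration, so re-running with the same
#' seed reproduces byte-identical files and the hash changes iff the
#' configuration changes.
#'
#' @param session a `cmp_session`.
#' @param dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  tr <- session$trials
  utils::write.csv(tr, file.path(dir, "trials.csv"), row.names = FALSE)
  sp <- session$spikes
  sp$t_ms <- sprintf("%.3f", sp$t_ms)
  utils::write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE,
                   quote = FALSE)
  if (!is.null(session$truth))
    utils::write.csv(session$truth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
  config <- session_config(session)
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(config = config,
                   config_hash = unname(tools::md5sum(cfg_path)),
                   n_trials = nrow(tr), n_spikes = nrow(sp),
                   has_ground_truth = !is.null(session$truth))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# serializable configuration of a session (layout + generator parameters)
session_config <- function(session) {
  cfg <- list(layout = list(
    item_to_colocation = as.list(session$layout$item_to_colocation),
    default_angle = as.list(session$layout$default_angle)))
  if (!is.null(session$spec)) {
    sp <- session$spec
    cfg$session <- list(counts = as.list(sp$counts), n_trials = sp$n_trials,
                        orientations = sp$orientations,
                        error_rate = sp$error_rate,
                        baseline_rate = sp$baseline_rate, gain = sp$gain,
                        unitization = sp$unitization,
                        choice_weight = sp$choice_weight, seed = sp$seed)
  }
  cfg
}

#' Load and validate a session from a directory
#'
#' Re-checks every invariant on load: spike trial ids must exist in the
#' trials table, event times must increase, the target must equal the
#' geometric prediction `target_location(colocation, orientation)`, and
#' `correct` must match `choice == target`.  Violations raise errors that
#' name the offending row; loading never silently drops rows.
#'
#' @param dir directory written by [write_session()].
#' @param layout optional [cmp_layout()]; defaults to the layout recorded
#'   in the manifest.
#' @return a `cmp_session`.
#' @export
load_session <- function(dir, layout = NULL) {
  need <- file.path(dir, c("trials.csv", "spikes.csv"))
  miss <- need[!file.exists(need)]
  if (length(miss)) stop("missing session file(s): ",
                         paste(miss, collapse = ", "))
  trials <- utils::read.csv(file.path(dir, "trials.csv"),
                            stringsAsFactors = FALSE)
  spikes <- utils::read.csv(file.path(dir, "spikes.csv"),
                            stringsAsFactors = FALSE)
  truth <- NULL
  if (file.exists(file.path(dir, "ground_truth.csv")))
    truth <- utils::read.csv(file.path(dir, "ground_truth.csv"),
                             stringsAsFactors = FALSE)
  if (is.null(layout)) {
    mpath <- file.path(dir, "manifest.json")
    if (file.exists(mpath)) {
      m <- jsonlite::read_json(mpath, simplifyVector = TRUE)
      layout <- cmp_layout(unlist(m$config$layout$item_to_colocation),
                           unlist(m$config$layout$default_angle))
    } else layout <- cmp_layout()
  }
  validate_session_tables(trials, spikes, layout)
  structure(list(trials = trials, spikes = spikes, truth = truth,
                 layout = layout, spec = NULL),
            class = "cmp_session")
}

validate_session_tables <- function(trials, spikes, layout) {
  req <- c("trial_id", "item", "colocation", "orientation_deg", "target_deg",
           "choice_deg", "correct", "item_on_ms", "bg_on_ms", "choice_on_ms")
  miss <- setdiff(req, names(trials))
  if (length(miss))
    stop("trials table schema mismatch; missing column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(trials$trial_id))
    stop("duplicated trial_id in trials table")
  tgt <- target_location(item_colocation(trials$item, layout),
                         trials$orientation_deg, layout)
  bad <- which(tgt != trials$target_deg)
  if (length(bad))
    stop("geometry mismatch: stored target disagrees with ",
         "target_location(colocation, orientation) at trial row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  badc <- which(item_colocation(trials$item, layout) != trials$colocation)
  if (length(badc))
    stop("co-location column disagrees with the layout at row(s) ",
         paste(utils::head(badc, 5), collapse = ", "))
  completed <- !is.na(trials$choice_deg)
  badx <- which(completed &
                  (trials$choice_deg == trials$target_deg) != trials$correct)
  if (length(badx))
    stop("`correct` flag disagrees with choice == target at row(s) ",
         paste(utils::head(badx, 5), collapse = ", "))
  ev <- cbind(trials$item_on_ms, trials$bg_on_ms, trials$choice_on_ms)
  if (any(ev[, 1] >= ev[, 2] | ev[, 2] >= ev[, 3]))
    stop("event times must be strictly increasing")
  orphan <- which(!spikes$trial_id %in% trials$trial_id)
  if (length(orphan))
    stop("spike row(s) reference unknown trial_id, e.g. row ",
         orphan[1], " (trial_id ", spikes$trial_id[orphan[1]], ")")
  invisible(TRUE)
}
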