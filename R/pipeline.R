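#' Default pipeline configuration
#'
#' Two profiles: `"full"` runs at the recorded scale (456 neurons, 128
#' trials, 10,000 permutations); `"ci"` is a reduced preset for fast,
#' fully deterministic runs (smaller ensemble, 1,000 permutations) with
#' identical effect sizes.
#'
#' @param profile `"full"` or `"ci"`.
#' @param seed session seed.
#' @return nested configuration list (sections `session` and `analysis`).
#' @export
default_config <- function(profile = c("ci", "full"), seed = 1L) {
  profile <- match.arg(profile)
  counts <- if (profile == "full")
    c(untuned = 200, item_unitized = 100, item_nonunitized = 20,
      background = 40, convergent = 32, transferring = 24,
      targeting = 30, multiphase = 10)
  else
    c(untuned = 20, item_unitized = 10, item_nonunitized = 3,
      background = 6, convergent = 6, transferring = 4,
      targeting = 6, multiphase = 2)
  list(profile = profile,
       session = list(counts = as.list(counts), n_trials = 128,
                      orientations = c(-90, -45, 0, 45, 90),
                      error_rate = 0.15, baseline_rate = 5, gain = 10,
                      unitization = 1, choice_weight = 1, seed = seed),
       analysis = list(alpha = 0.01, n_perm = if (profile == "full")
         10000 else 1000, high_index_threshold = 0.6, min_errors = 10,
         sdf_step = if (profile == "full") 1 else 5,
         timecourse_step = if (profile == "full") 1 else 10))
}

#' Read a pipeline configuration from a YAML file
#'
#' Values present in the file override the profile defaults section by
#' section.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config(cfg$profile %||% "ci",
                         seed = cfg$session$seed %||% 1L)
  for (sec in c("session", "analysis"))
    for (k in names(cfg[[sec]])) base[[sec]][[k]] <- cfg[[sec]][[k]]
  base
}

#' Build a [session_spec()] from a configuration list
#' @param config configuration from [default_config()] or [load_config()].
#' @return a `cmp_session_spec`.
#' @export
session_spec_from_config <- function(config) {
  s <- config$session
  session_spec(counts = unlist(s$counts), n_trials = s$n_trials,
               orientations = unlist(s$orientations),
               error_rate = s$error_rate, baseline_rate = s$baseline_rate,
               gain = s$gain, unitization = s$unitization,
               choice_weight = s$choice_weight, seed = s$seed)
}

write_stage_csv <- function(df, out_dir, name) {
  if (is.null(df) || !nrow(as.data.frame(df))) {
    utils::write.csv(data.frame(), file.path(out_dir, name),
                     row.names = FALSE)
  } else {
    utils::write.csv(as.data.frame(df), file.path(out_dir, name),
                     row.names = FALSE)
  }
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline on a synthetic or loaded session
#'
#' simulate -> screen -> indices -> construction -> error analysis ->
#' report, writing one CSV per result table under `out_dir` plus a JSON
#' summary.  Every stage is a pure function of (inputs, config, seed), so
#' re-running with the same configuration reproduces identical tables.
#'
#' @param config configuration from [default_config()] or [load_config()].
#' @param out_dir output directory.
#' @param session optional pre-built `cmp_session`; when NULL one is
#'   simulated from the config.
#' @return list with the session, all stage results, and the summary.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile(),
                         session = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  alpha <- config$analysis$alpha
  n_perm <- config$analysis$n_perm
  seed <- config$session$seed

  if (is.null(session))
    session <- stage("simulate",
                     simulate_session(session_spec_from_config(config)))
  stage("simulate", write_session(session, file.path(out_dir, "session")))

  screen <- stage("screen", screen_neurons(session, alpha = alpha))
  write_stage_csv(screen, out_dir, "selectivity.csv")

  # co-location index + ROC for the item-selective neurons
  indices <- stage("indices", {
    sel <- screen$neuron_id[screen$item_icue & screen$included]
    rows <- lapply(sel, function(nr) {
      ca <- colocation_analysis(session, nr, n_perm = n_perm,
                                seed = seed + nr)
      data.frame(neuron_id = nr, rbar = ca$rbar, p = ca$p,
                 n_sig_windows = sum(ca$sig_windows))
    })
    idx <- do.call(rbind, rows)
    roc <- NULL
    if (!is.null(idx)) {
      high <- idx$neuron_id[!is.na(idx$rbar) &
                              idx$rbar > config$analysis$high_index_threshold]
      roc <- do.call(rbind, lapply(high, function(nr) {
        ra <- roc_analysis(session, nr, n_perm = n_perm, seed = seed + nr)
        data.frame(neuron_id = nr,
                   optimal_item = ra$optimal_item, pair_item = ra$pair_item,
                   auc_item = ra$item_discrimination$auc,
                   p_item = ra$item_discrimination$p,
                   auc_colocation = ra$colocation_discrimination$auc,
                   p_colocation = ra$colocation_discrimination$p)
      }))
    }
    list(colocation = idx, roc = roc)
  })
  write_stage_csv(indices$colocation, out_dir, "colocation_index.csv")
  write_stage_csv(indices$roc, out_dir, "roc.csv")

  construct <- stage("construct", {
    coloc_sel <- screen$neuron_id[screen$colocation & screen$included]
    tuning <- if (length(coloc_sel) >= 3)
      tuning_similarity_timecourse(session, coloc_sel,
                                   step = config$analysis$timecourse_step)
    else NULL
    match_sel <- screen$neuron_id[screen$item_icue & screen$target &
                                    screen$included]
    matching <- if (length(match_sel) >= 3)
      matching_population(session, match_sel) else NULL
    target_sel <- screen$neuron_id[screen$target & screen$included]
    pop_sdf <- if (length(target_sel) >= 3)
      suppressWarnings(
        target_population_sdf(session, target_sel,
                              step = config$analysis$sdf_step))
    else NULL
    list(tuning = tuning, matching = matching, pop_sdf = pop_sdf)
  })
  if (!is.null(construct$tuning))
    write_stage_csv(data.frame(t_ms = construct$tuning$starts,
                               mean_r = construct$tuning$mean,
                               sem = construct$tuning$sem,
                               p = construct$tuning$p),
                    out_dir, "tuning_similarity.csv")
  if (!is.null(construct$matching))
    write_stage_csv(as.data.frame(construct$matching$r), out_dir,
                    "matching_index.csv")
  if (!is.null(construct$pop_sdf))
    write_stage_csv(data.frame(t_ms = construct$pop_sdf$time,
                               mean_deg0 = construct$pop_sdf$deg0$mean,
                               mean_rot = construct$pop_sdf$rot$mean),
                    out_dir, "target_population_sdf.csv")

  errors <- stage("errors", {
    target_sel <- screen$neuron_id[screen$target & screen$included]
    if (length(target_sel)) {
      error_population(session, target_sel,
                       min_errors = config$analysis$min_errors)
    } else list(per_neuron = NULL, p = NA_real_)
  })
  write_stage_csv(errors$per_neuron, out_dir, "error_analysis.csv")

  report <- stage("report", {
    counts <- classification_counts(screen)
    rec <- if (!is.null(session$truth))
      recovery_report(screen, session$truth) else NULL
    list(counts = counts, recovery = rec)
  })
  write_stage_csv(report$counts, out_dir, "category_counts.csv")
  if (!is.null(report$recovery)) {
    write_stage_csv(report$recovery$confusion, out_dir, "confusion.csv")
    write_stage_csv(
      data.frame(archetype = names(report$recovery$sensitivity),
                 sensitivity = unname(report$recovery$sensitivity)),
      out_dir, "recovery.csv")
  }
  summary <- list(
    profile = config$profile, seed = seed, n_perm = n_perm,
    counts = as.list(report$counts),
    median_rbar = if (!is.null(indices$colocation))
      stats::median(indices$colocation$rbar, na.rm = TRUE) else NA,
    error_p = errors$p)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(session = session, screen = screen, indices = indices,
                 construct = construct, errors = errors, report = report,
                 summary = summary, out_dir = out_dir))
}
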