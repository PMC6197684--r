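.trial_schema <- c("subject_id", "group", "trial", "block", "matrix_id",
                   "prev_stim", "stim", "correct", "valid", "rt_ms")

#' Write subjects' trial tables to CSV
#'
#' One row per trial with columns \code{subject_id, group, trial, block,
#' matrix_id, prev_stim, stim, correct, valid, rt_ms}; missing RTs
#' (invalid trials) are written as empty fields.
#'
#' @param subjects one \code{srtt_subject} or a list of them.
#' @param path output file path.
#' @export
write_trials <- function(subjects, path) {
  if (inherits(subjects, "srtt_subject")) subjects <- list(subjects)
  tab <- do.call(rbind, lapply(subjects, function(s)
    cbind(subject_id = s$subject_id, group = s$group, s$trials)))
  tab <- tab[, .trial_schema]
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read subjects' trial tables from CSV
#'
#' Validates the schema and per-subject invariants (contiguous 1-based
#' trial indices; an RT is present exactly when the trial is valid).
#'
#' @param path CSV file written by \code{\link{write_trials}} (or
#'   conforming to its schema).
#' @return list of \code{srtt_subject} objects (covariates empty; the
#'   trial table does not carry them).
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(subject_id = "character",
                                        group = "character"))
  missing_cols <- setdiff(.trial_schema, names(tab))
  if (length(missing_cols) > 0L)
    stop("trial table schema mismatch; missing column(s): ",
         paste(missing_cols, collapse = ", "))
  tab$correct <- as.logical(tab$correct)
  tab$valid <- as.logical(tab$valid)
  lapply(split(tab, factor(tab$subject_id, levels = unique(tab$subject_id))),
         function(d) {
           d <- d[order(d$trial), ]
           if (!identical(as.integer(d$trial), seq_len(nrow(d))))
             stop("validation error for subject ", d$subject_id[1L],
                  ": trial indices must be contiguous from 1")
           if (any(d$valid & is.na(d$rt_ms)))
             stop("validation error for subject ", d$subject_id[1L],
                  ": column rt_ms empty on a valid trial")
           if (any(!d$valid & !is.na(d$rt_ms)))
             stop("validation error for subject ", d$subject_id[1L],
                  ": column rt_ms present on an invalid trial")
           trials <- d[, setdiff(.trial_schema, c("subject_id", "group"))]
           rownames(trials) <- NULL
           structure(list(subject_id = d$subject_id[1L],
                          group = d$group[1L], covariates = list(),
                          trials = trials),
                     class = "srtt_subject")
         }) |> unname()
}

#' Write a belief/prediction trajectory as TSV
#'
#' @param traj trajectory data.frame (from \code{\link{fom_filter}} or
#'   \code{\link{hgf_filter}}\code{$traj}).
#' @param path output file path.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(traj, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

.default_config <- function() {
  list(seed = 1L, n_subjects = 4L,
       task = list(p_high = 0.7, block_length = 50L,
                   repeats_per_matrix = 3L),
       generative = list(lambda = 0.303, gamma = 1, beta0 = 6.671,
                         beta1 = -1.248, beta2 = 0.0445),
       noise = list(sigma = 0.2, p_error = 0.05, p_invalid = 0.02),
       fitting = list(gamma = 1, belief_measure = "normalized",
                      fit_hgf = FALSE),
       analysis = list(n_iter = 1000L, positions = 1:4),
       out_dir = ".")
}

# merge user config over defaults, rejecting unknown keys at both levels
.resolve_config <- function(config) {
  base <- .default_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(config)) {
    if (is.list(base[[k]]) && is.list(config[[k]])) {
      bad <- setdiff(names(config[[k]]), names(base[[k]]))
      if (length(bad) > 0L)
        stop("unknown config key(s) under '", k, "': ",
             paste(bad, collapse = ", "))
      base[[k]][names(config[[k]])] <- config[[k]]
    } else base[[k]] <- config[[k]]
  }
  base
}

#' Run the full simulate-fit-analyse pipeline
#'
#' Executes the standard analysis end to end under one explicit seed:
#' simulate a cohort from the forgetful observer model, fit the model(s)
#' per subject, and run the block-half speeding permutation analysis on
#' the pooled runs.  Every artifact is written alongside the resolved
#' configuration so a rerun with the same config reproduces all
#' stochastic outputs exactly.
#'
#' @param config a named list (or path to a YAML file) overriding the
#'   defaults: \code{seed}, \code{n_subjects}, \code{task},
#'   \code{generative}, \code{noise}, \code{fitting}, \code{analysis},
#'   \code{out_dir}.  Unknown keys are rejected.
#' @param verbose print stage progress.
#' @return invisibly, a list with \code{config}, \code{subjects},
#'   \code{fits}, \code{speeding} and output file paths.
#' @export
run_pipeline <- function(config = list(), verbose = TRUE) {
  cfg <- .resolve_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  if (!dir.exists(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE)
    say("created output directory %s", cfg$out_dir)
  }
  paths <- list(
    config = file.path(cfg$out_dir, "config.json"),
    trials = file.path(cfg$out_dir, "trials.csv"),
    fits = file.path(cfg$out_dir, "fits.json"),
    speeding = file.path(cfg$out_dir, "speeding.tsv"))
  jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  say("stage simulate: %d subjects, seed %d", cfg$n_subjects, cfg$seed)
  design <- task_design(p_high = cfg$task$p_high,
                        block_length = cfg$task$block_length,
                        repeats_per_matrix = cfg$task$repeats_per_matrix)
  gen <- fom_params(lambda = cfg$generative$lambda,
                    gamma = cfg$generative$gamma,
                    beta0 = cfg$generative$beta0,
                    beta1 = cfg$generative$beta1,
                    beta2 = cfg$generative$beta2)
  subjects <- tryCatch(
    simulate_cohort(cfg$n_subjects, design, gen,
                    sigma = cfg$noise$sigma, p_error = cfg$noise$p_error,
                    p_invalid = cfg$noise$p_invalid, seed = cfg$seed),
    error = function(e) stop("stage simulate failed: ",
                             conditionMessage(e)))
  write_trials(subjects, paths$trials)

  say("stage fit: FOM%s", if (cfg$fitting$fit_hgf) " + HGF" else "")
  fits <- tryCatch(lapply(subjects, function(s) {
    f <- list(fom = fit_fom(s, gamma = cfg$fitting$gamma,
                            belief_measure = cfg$fitting$belief_measure))
    if (cfg$fitting$fit_hgf) f$hgf <- fit_hgf(s)
    f
  }), error = function(e) stop("stage fit failed: ", conditionMessage(e)))
  fit_records <- do.call(rbind, lapply(seq_along(fits), function(i) {
    do.call(rbind, lapply(fits[[i]], function(f)
      data.frame(subject_id = subjects[[i]]$subject_id, model = f$model,
                 log_likelihood = f$log_likelihood, bic = f$bic,
                 n_trials = f$n_trials,
                 lambda = if (f$model == "FOM") f$params$lambda else NA,
                 beta0 = if (f$model == "FOM") f$params$beta0 else
                   f$params$beta[1],
                 beta1 = if (f$model == "FOM") f$params$beta1 else
                   f$params$beta[2],
                 beta2 = if (f$model == "FOM") f$params$beta2 else
                   f$params$beta[3])))
  }))
  jsonlite::write_json(fit_records, paths$fits, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  say("stage speeding: permutation tests, %d iterations",
      cfg$analysis$n_iter)
  set.seed(cfg$seed + 1L)
  runs <- do.call(rbind, lapply(subjects, function(s)
    extract_runs(s, design, values = zscore_log_rt(s, design))))
  speed <- do.call(rbind, lapply(cfg$analysis$positions, function(pos) {
    res <- halves_permutation_test(runs, pos, n_iter = cfg$analysis$n_iter)
    data.frame(position = pos, statistic = res$statistic,
               p_value = res$p_value, n_first = res$n_first,
               n_second = res$n_second, testable = res$testable)
  }))
  utils::write.table(speed, paths$speeding, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  say("pipeline complete: outputs in %s", cfg$out_dir)
  invisible(list(config = cfg, subjects = subjects, fits = fits,
                 speeding = speed, paths = paths))
}
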