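#' Sample a block schedule without immediate repeats
#'
#' Draws a pseudo-random order of matrix ids in which every matrix appears
#' exactly \code{repeats_per_matrix} times and no matrix directly follows
#' itself.  Sampling is by bounded rejection: uniformly random permutations
#' of the multiset are drawn until one satisfies the adjacency constraint.
#'
#' @param design a \code{\link{task_design}}.
#' @param max_tries rejection bound before an error is raised.
#' @return integer vector of matrix ids, one per block.
#' @export
sample_schedule <- function(design, max_tries = 10000L) {
  ids <- vapply(design$matrices, `[[`, integer(1), "id")
  pool <- rep(ids, each = design$repeats_per_matrix)
  if (length(ids) == 1L && design$repeats_per_matrix > 1L)
    stop("schedule infeasible: a single matrix cannot avoid immediate repeats")
  for (k in seq_len(max_tries)) {
    cand <- sample(pool)
    if (length(cand) < 2L || !any(cand[-1L] == cand[-length(cand)]))
      return(cand)
  }
  stop("schedule infeasible: no repeat-free ordering found within retry bound")
}

#' Generate a stimulus sequence for a scheduled session
#'
#' Generates the full session stimulus stream.  Within each block the next
#' stimulus is drawn from the active matrix's row for the previous
#' stimulus; the chain is continuous across block boundaries (the last
#' stimulus of a block conditions the first draw of the next block, since
#' subjects receive no boundary signal).  The very first stimulus of the
#' session is drawn uniformly.
#'
#' @param schedule integer vector of matrix ids (one per block).
#' @param design a \code{\link{task_design}}.
#' @return data.frame with columns \code{trial}, \code{block},
#'   \code{matrix_id}, \code{prev_stim} (NA on trial 1), \code{stim}.
#' @export
generate_sequence <- function(schedule, design) {
  n_block <- length(schedule)
  len <- design$block_length
  n <- n_block * len
  stim <- integer(n)
  block <- rep(seq_len(n_block), each = len)
  matrix_id <- rep(as.integer(schedule), each = len)
  prev <- 0L
  for (t in seq_len(n)) {
    Tmat <- .design_matrix(design, matrix_id[t])$T
    p <- if (t == 1L) rep(0.25, 4L) else Tmat[prev, ]
    stim[t] <- sample.int(4L, 1L, prob = p)
    prev <- stim[t]
  }
  data.frame(trial = seq_len(n), block = block, matrix_id = matrix_id,
             prev_stim = c(NA_integer_, stim[-n]), stim = stim)
}

#' Simulate one subject's reaction times on a stimulus sequence
#'
#' Runs the forgetful observer filter over the stimulus stream and draws
#' each trial's log RT from the linear response model plus Gaussian noise
#' with SD \code{sigma}.  Response errors are injected i.i.d. with
#' probability \code{p_error} and feed the post-error regressor of the
#' following trial; invalid trials (misses or anticipations, recorded as
#' incorrect) occur i.i.d. with probability \code{p_invalid} and carry no
#' RT.  The first trial of the session, which has no predecessor, is
#' simulated at the uniform pre-observation belief.
#'
#' @param sequence data.frame from \code{\link{generate_sequence}}.
#' @param params a \code{\link{fom_params}} object (generative values).
#' @param sigma log-RT noise SD (default 0.2).
#' @param p_error per-trial probability of an incorrect response.
#' @param p_invalid per-trial probability of a miss/anticipation.
#' @param subject_id,group,covariates dataset labels; \code{covariates}
#'   is a named list (e.g. \code{body_weight}, \code{alertness}).
#' @return an object of class \code{srtt_subject}: a list with fields
#'   \code{subject_id}, \code{group}, \code{covariates} and \code{trials}
#'   (a data.frame with columns \code{trial}, \code{block},
#'   \code{matrix_id}, \code{prev_stim}, \code{stim}, \code{correct},
#'   \code{valid}, \code{rt_ms}).
#' @export
simulate_subject <- function(sequence, params, sigma = 0.2,
                             p_error = 0.05, p_invalid = 0.02,
                             subject_id = "s1", group = "placebo",
                             covariates = list()) {
  stopifnot(inherits(params, "fom_params"))
  if (sigma < 0) stop("sigma must be >= 0")
  if (p_error < 0 || p_error > 1 || p_invalid < 0 || p_invalid > 1)
    stop("p_error and p_invalid must be probabilities")
  n <- nrow(sequence)
  error <- stats::runif(n) < p_error
  valid <- stats::runif(n) >= p_invalid
  correct <- !error & valid
  traj <- fom_filter(sequence, params, correct = correct)
  mean_log_rt <- c(
    predict_mean_log_rt(params, 0.25, FALSE),  # trial 1: uniform belief
    traj$pred_log_rt)
  log_rt <- mean_log_rt + stats::rnorm(n, 0, sigma)
  rt_ms <- exp(log_rt)
  rt_ms[!valid] <- NA_real_
  trials <- data.frame(trial = sequence$trial, block = sequence$block,
                       matrix_id = sequence$matrix_id,
                       prev_stim = sequence$prev_stim, stim = sequence$stim,
                       correct = correct, valid = valid, rt_ms = rt_ms)
  structure(list(subject_id = subject_id, group = group,
                 covariates = covariates, trials = trials),
            class = "srtt_subject")
}

#' @export
print.srtt_subject <- function(x, ...) {
  cat(sprintf("pSRTT subject %s (group %s): %d trials, %d blocks, %.1f%% correct\n",
              x$subject_id, x$group, nrow(x$trials), max(x$trials$block),
              100 * mean(x$trials$correct)))
  invisible(x)
}

#' Simulate a cohort of synthetic subjects
#'
#' Each subject receives an independently sampled block schedule and
#' stimulus sequence from the same task design, then RTs are simulated
#' under the forgetful observer response model.  Generative parameters may
#' vary per subject.
#'
#' @param n_subjects number of subjects.
#' @param design a \code{\link{task_design}}.
#' @param params a single \code{\link{fom_params}} object or a list of one
#'   per subject.
#' @param group group label (scalar or per-subject vector).
#' @param seed optional integer seed for reproducibility.
#' @inheritParams simulate_subject
#' @return list of \code{srtt_subject} objects.
#' @export
simulate_cohort <- function(n_subjects, design = task_design(), params,
                            sigma = 0.2, p_error = 0.05, p_invalid = 0.02,
                            group = "placebo", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(params, "fom_params"))
    params <- rep(list(params), n_subjects)
  group <- rep_len(group, n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    sched <- sample_schedule(design)
    seq_i <- generate_sequence(sched, design)
    simulate_subject(seq_i, params[[i]], sigma = sigma, p_error = p_error,
                     p_invalid = p_invalid,
                     subject_id = sprintf("s%03d", i), group = group[i],
                     covariates = list(body_weight = stats::rnorm(1, 75, 10),
                                       alertness = stats::rnorm(1, 0, 1)))
  })
}
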