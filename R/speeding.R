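# is each trial's realized transition the active matrix's predominant
# (high-probability) transition?
.is_high_prob <- function(trials, design) {
  n <- nrow(trials)
  out <- logical(n)
  for (t in seq_len(n)) {
    p <- trials$prev_stim[t]
    if (is.na(p)) next
    T <- .design_matrix(design, trials$matrix_id[t])$T
    out[t] <- T[p, trials$stim[t]] >= max(T[p, ]) - 1e-12 &&
      max(T[p, ]) > min(T[p, ]) + 1e-12
  }
  out
}

#' Extract uninterrupted high-probability runs
#'
#' A run is a maximal streak of consecutive trials (within one block)
#' whose realised transition is the active matrix's predominant
#' transition; the entering transition from a rare stimulus counts as
#' run position 1.  Runs are labelled by the block half containing their
#' start (within-block position \code{<= block_length/2} is the first
#' half).
#'
#' @param subject an \code{srtt_subject}, or a trial data.frame.
#' @param design the generating \code{\link{task_design}}.
#' @param values optional numeric vector aligned with the trial table
#'   (e.g. z-scored log RTs or model predictions) copied into the run
#'   rows as \code{zlogrt}.
#' @param source label for the value source (\code{"data"} or
#'   \code{"model_prediction"}).
#' @return data.frame with one row per run trial: \code{subject_id},
#'   \code{block}, \code{run} (session-wide run counter),
#'   \code{start_trial}, \code{half}, \code{pos} (1-based position in
#'   the run), \code{trial}, and \code{zlogrt} if values were supplied.
#' @export
extract_runs <- function(subject, design = task_design(), values = NULL,
                         source = "data") {
  sid <- if (inherits(subject, "srtt_subject")) subject$subject_id else "s1"
  trials <- if (inherits(subject, "srtt_subject")) subject$trials else subject
  hp <- .is_high_prob(trials, design)
  n <- nrow(trials)
  # a streak breaks at block boundaries and at non-contiguous trial indices
  new_run <- hp & !c(FALSE, hp[-n]  &
                       trials$block[-1L] == trials$block[-n] &
                       trials$trial[-1L] == trials$trial[-n] + 1L)
  run_id <- cumsum(new_run)
  run_id[!hp] <- NA_integer_
  keep <- which(hp)
  if (length(keep) == 0L)
    return(data.frame(subject_id = character(0), block = integer(0),
                      run = integer(0), start_trial = integer(0),
                      half = character(0), pos = integer(0),
                      trial = integer(0)))
  rid <- run_id[keep]
  pos <- stats::ave(rep(1L, length(keep)), rid, FUN = cumsum)
  start_trial <- stats::ave(trials$trial[keep], rid, FUN = min)
  block <- trials$block[keep]
  within_block <- trials$trial[keep] - (block - 1L) * design$block_length
  start_within <- stats::ave(within_block, rid, FUN = min)
  out <- data.frame(subject_id = sid, block = block, run = rid,
                    start_trial = start_trial,
                    half = ifelse(start_within <= design$block_length / 2,
                                  "first", "second"),
                    pos = pos, trial = trials$trial[keep],
                    source = source)
  if (!is.null(values)) out$zlogrt <- values[keep]
  out
}

#' Z-score log RTs on a restricted basis of trials
#'
#' Per-subject z-scoring where mean and SD are computed only on the
#' basis trials (by default, trials inside uninterrupted
#' high-probability runs of zeroth-order blocks) but applied to the
#' whole session.  Model-predicted log RTs are transformed with the same
#' convention by passing them as \code{values}.
#'
#' @param subject an \code{srtt_subject} or trial data.frame.
#' @param design the generating \code{\link{task_design}}.
#' @param values numeric vector to transform, aligned with the trial
#'   table; defaults to \code{log(rt_ms)}.
#' @param basis logical vector selecting the basis trials; defaults to
#'   run trials within zeroth-order blocks that carry an observed RT.
#' @param reference numeric vector from which the basis mean and SD are
#'   taken (defaults to \code{values}).  Pass the observed log RTs here
#'   when transforming model predictions, so that data and predictions
#'   share one standardisation and their speeding curves are directly
#'   comparable.
#' @return numeric vector of z-scored values (NA where the input is NA).
#' @export
zscore_log_rt <- function(subject, design = task_design(), values = NULL,
                          basis = NULL, reference = NULL) {
  trials <- if (inherits(subject, "srtt_subject")) subject$trials else subject
  if (is.null(values)) values <- log(trials$rt_ms)
  if (is.null(reference)) reference <- values
  if (length(values) != nrow(trials) || length(reference) != nrow(trials))
    stop("values must align with the trial table")
  if (is.null(basis)) {
    runs <- extract_runs(subject, design)
    ids <- vapply(design$matrices, `[[`, integer(1), "id")
    dyn <- vapply(design$matrices, `[[`, character(1), "dynamics")
    zeroth_blocks <- trials$block[dyn[match(trials$matrix_id, ids)] == "zeroth"]
    # valid-RT run trials only, so data and model predictions share a basis
    basis <- trials$trial %in% runs$trial[runs$block %in% zeroth_blocks] &
      !is.na(trials$rt_ms)
  }
  b <- basis & !is.na(reference)
  if (sum(b) < 2L || stats::sd(reference[b]) == 0)
    stop("degenerate z-score basis: fewer than 2 distinct values")
  (values - mean(reference[b])) / stats::sd(reference[b])
}

# per-(subject, half) speeding differences zlogrt[pos+1] - zlogrt[pos],
# one row per run long enough to contribute
.speeding_diffs <- function(runs, position) {
  a <- runs[runs$pos == position, c("subject_id", "run", "half", "zlogrt")]
  b <- runs[runs$pos == position + 1L, c("run", "zlogrt")]
  m <- merge(a, b, by = "run", suffixes = c("", "_next"))
  m$diff <- m$zlogrt_next - m$zlogrt
  m[!is.na(m$diff), c("subject_id", "run", "half", "diff")]
}

#' Permutation test for speeding differences between block halves
#'
#' Compares the mean one-step speeding (zlogRT at run position
#' \code{t+1} minus position \code{t}) between runs starting in the
#' first versus second half of blocks.  The null distribution is built
#' by shuffling half labels among each subject's runs; the two-sided
#' p-value uses the add-one estimator
#' \code{(#(|null| >= |observed|) + 1) / (n_iter + 1)}.
#'
#' @param runs run data.frame from \code{\link{extract_runs}} with a
#'   \code{zlogrt} column (typically pooled over subjects).
#' @param position run position \code{t} tested (the difference is
#'   \code{t+1} minus \code{t}).
#' @param n_iter number of label shuffles (default 10000).
#' @return list with \code{statistic} (second minus first half mean
#'   difference), \code{p_value}, \code{n_first}, \code{n_second} and
#'   \code{testable}; when one half contributes no run the test is
#'   flagged not testable and \code{p_value} is NA.
#' @export
halves_permutation_test <- function(runs, position, n_iter = 10000) {
  d <- .speeding_diffs(runs, position)
  n1 <- sum(d$half == "first"); n2 <- sum(d$half == "second")
  if (n1 == 0L || n2 == 0L)
    return(list(statistic = NA_real_, p_value = NA_real_,
                n_first = n1, n_second = n2, testable = FALSE))
  stat <- function(lab) mean(d$diff[lab == "second"]) -
    mean(d$diff[lab == "first"])
  obs <- stat(d$half)
  subj <- factor(d$subject_id)
  null <- vapply(seq_len(n_iter), function(i) {
    lab <- d$half
    for (s in levels(subj)) {
      idx <- which(subj == s)
      lab[idx] <- lab[idx][sample.int(length(idx))]
    }
    stat(lab)
  }, numeric(1))
  p <- (sum(abs(null) >= abs(obs) - 1e-15) + 1) / (n_iter + 1)
  list(statistic = obs, p_value = p, n_first = n1, n_second = n2,
       testable = TRUE)
}

# subject-by-half mean speeding difference at a position
.subject_half_diffs <- function(runs, position) {
  d <- .speeding_diffs(runs, position)
  if (nrow(d) == 0L) return(d)
  stats::aggregate(diff ~ subject_id + half, data = d, FUN = mean)
}

#' Permutation test on the relative magnitude of model-data mismatches
#'
#' Assesses whether one model's speeding-curve differences deviate more
#' from the data's than another's.  For each subject (and block half)
#' the mean speeding difference at the tested position is computed from
#' the data runs and from each model's predicted runs; the statistic is
#' the mean over subjects of |model A - data| - |model B - data|.  The
#' null distribution swaps the two models' labels independently within
#' subjects (a sign flip of each subject's contribution); the two-sided
#' p-value uses the add-one estimator.
#'
#' @param model_runs_a,model_runs_b run data.frames of z-scored model
#'   predictions (\code{\link{extract_runs}} with prediction values).
#' @param data_runs run data.frame of z-scored observed log RTs.
#' @param position run position tested.
#' @param n_iter number of sign-flip iterations.
#' @return list with \code{statistic}, \code{p_value}, \code{n_subjects}
#'   and \code{testable}.
#' @export
mismatch_magnitude_test <- function(model_runs_a, model_runs_b, data_runs,
                                    position, n_iter = 10000) {
  da <- .subject_half_diffs(model_runs_a, position)
  db <- .subject_half_diffs(model_runs_b, position)
  dd <- .subject_half_diffs(data_runs, position)
  m <- merge(merge(dd, da, by = c("subject_id", "half"),
                   suffixes = c("_data", "_a")),
             db, by = c("subject_id", "half"))
  names(m)[names(m) == "diff"] <- "diff_b"
  if (nrow(m) == 0L)
    return(list(statistic = NA_real_, p_value = NA_real_,
                n_subjects = 0L, testable = FALSE))
  m$gap <- abs(m$diff_a - m$diff_data) - abs(m$diff_b - m$diff_data)
  per_subj <- stats::aggregate(gap ~ subject_id, data = m, FUN = mean)
  g <- per_subj$gap
  obs <- mean(g)
  ns <- length(g)
  null <- vapply(seq_len(n_iter), function(i)
    mean(g * sample(c(-1, 1), ns, replace = TRUE)), numeric(1))
  p <- (sum(abs(null) >= abs(obs) - 1e-15) + 1) / (n_iter + 1)
  list(statistic = obs, p_value = p, n_subjects = ns, testable = TRUE)
}

#' Average speeding curves by block half
#'
#' @param runs run data.frame with \code{zlogrt}.
#' @param max_pos largest run position to include.
#' @return data.frame with \code{half}, \code{pos}, \code{mean_zlogrt},
#'   \code{n_runs}.
#' @export
speeding_curves <- function(runs, max_pos = 6L) {
  r <- runs[runs$pos <= max_pos & !is.na(runs$zlogrt), ]
  if (nrow(r) == 0L)
    return(data.frame(half = character(0), pos = integer(0),
                      mean_zlogrt = numeric(0), n_runs = integer(0)))
  agg <- stats::aggregate(zlogrt ~ half + pos, data = r, FUN = mean)
  cnt <- stats::aggregate(zlogrt ~ half + pos, data = r, FUN = length)
  names(agg)[3] <- "mean_zlogrt"
  agg$n_runs <- cnt$zlogrt
  agg[order(agg$half, agg$pos), ]
}
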