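#' Parameters of the forgetful observer model
#'
#' The forgetful observer tracks a 4x4 array of effective transition
#' counts \code{U} (Dirichlet parameters, one row per predecessor
#' stimulus).  After each observed transition all counts decay towards an
#' asymptotic prior \code{gamma} at forgetting rate \code{lambda}, and the
#' observed cell gains \code{count_weight}.  Log RTs are modelled as
#' \deqn{\log RT^t = \beta_0 + \beta_1 \bar U^t_{s^{t-1} s^t}
#'   + \beta_2 \chi(e^{t-1}) + \epsilon, \quad \epsilon \sim N(0,\sigma^2)}
#' where \eqn{\bar U} is the posterior-mean (normalised) belief in the
#' realised transition and \eqn{\chi(e^{t-1})} indicates an error on the
#' previous trial.
#'
#' @param lambda forgetting rate in \code{[0, 1]}: 0 is perfect memory
#'   (pure counting), 1 a complete reset every trial.
#' @param gamma asymptotic prior (>= 0), the target of forgetting.
#'   \code{gamma = 0} gives stable relative beliefs with growing
#'   uncertainty; \code{gamma > 0} makes beliefs converge to uniform
#'   absent evidence.
#' @param beta0,beta1,beta2 response coefficients: baseline log RT
#'   (log-millisecond units), belief weight (negative means speeding with
#'   expectation) and post-error slowing.
#' @param sigma residual SD of log RT (> 0).
#' @param belief_measure \code{"normalized"} uses the posterior-mean
#'   transition probability as the RT regressor; \code{"count"} uses the
#'   raw effective count (the unnormalised variant).
#' @param count_weight weight of the count added per observation
#'   (default 1; frees an extra learning-strength parameter when fitted).
#' @param reset_at_block if TRUE, beliefs are reinitialised to
#'   \code{gamma} at every block start (used when fitting separate matrix
#'   types).
#' @return an object of class \code{fom_params}.
#' @export
fom_params <- function(lambda, gamma = 1, beta0 = 6.7, beta1 = -1.2,
                       beta2 = 0.045, sigma = 0.2,
                       belief_measure = c("normalized", "count"),
                       count_weight = 1, reset_at_block = FALSE) {
  belief_measure <- match.arg(belief_measure)
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  if (gamma < 0) stop("gamma must be >= 0")
  if (sigma <= 0) stop("sigma must be > 0")
  if (count_weight <= 0) stop("count_weight must be > 0")
  structure(list(lambda = lambda, gamma = gamma, beta0 = beta0,
                 beta1 = beta1, beta2 = beta2, sigma = sigma,
                 belief_measure = belief_measure,
                 count_weight = count_weight,
                 reset_at_block = isTRUE(reset_at_block)),
            class = "fom_params")
}

#' @export
print.fom_params <- function(x, ...) {
  cat(sprintf(
    "Forgetful observer parameters (%s beliefs%s):\n", x$belief_measure,
    if (x$reset_at_block) ", block reset" else ""))
  cat(sprintf("  lambda = %.4g, gamma = %.4g, count_weight = %.4g\n",
              x$lambda, x$gamma, x$count_weight))
  cat(sprintf("  beta0 = %.4g, beta1 = %.4g, beta2 = %.4g, sigma = %.4g\n",
              x$beta0, x$beta1, x$beta2, x$sigma))
  invisible(x)
}

#' Initialise the belief state
#'
#' All 16 Dirichlet parameters start at the asymptotic prior
#' \code{gamma}, so the initial normalised predictive for any transition
#' is uniform (0.25) whenever \code{gamma > 0}.
#'
#' @param gamma asymptotic prior (>= 0).
#' @return 4x4 numeric matrix of effective counts.
#' @export
init_beliefs <- function(gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) || gamma < 0)
    stop("gamma must be a nonnegative number")
  matrix(gamma, 4L, 4L)
}

#' One forgetful Dirichlet update
#'
#' Applies the update
#' \deqn{U_{ij}^{t+1} = (1-\lambda)(U_{ij}^t - \gamma) + \gamma +
#'   w\,\delta((s^{t-1}, s^t), (i, j))}
#' to every cell: all counts decay towards \code{gamma}, and only the
#' observed transition cell gains the count weight \code{w}.
#'
#' @param U 4x4 belief (effective count) matrix.
#' @param prev,cur previous and current stimulus (1-4).
#' @param lambda forgetting rate.
#' @param gamma asymptotic prior.
#' @param count_weight weight added to the observed cell.
#' @return updated 4x4 matrix.
#' @export
update_beliefs <- function(U, prev, cur, lambda, gamma, count_weight = 1) {
  if (!prev %in% 1:4 || !cur %in% 1:4)
    stop("stimuli must be symbols 1-4")
  U <- (1 - lambda) * (U - gamma) + gamma
  U[prev, cur] <- U[prev, cur] + count_weight
  U
}

#' Predictive belief over the next stimulus
#'
#' Given the previous stimulus, returns the model's belief about each
#' possible successor: the posterior Dirichlet mean (row normalised to a
#' probability simplex) or the raw effective counts.
#'
#' @param U 4x4 belief matrix.
#' @param prev previous stimulus (1-4).
#' @param belief_measure \code{"normalized"} or \code{"count"}.
#' @return numeric vector of length 4.
#' @export
predictive_beliefs <- function(U, prev,
                               belief_measure = c("normalized", "count")) {
  belief_measure <- match.arg(belief_measure)
  if (!prev %in% 1:4) stop("prev must be a symbol 1-4")
  row <- U[prev, ]
  if (belief_measure == "count") return(row)
  s <- sum(row)
  if (s <= 0)
    stop("degenerate belief: all-zero count row has no normalised predictive")
  row / s
}

#' Mean predicted log RT under the linear response model
#'
#' @param params a \code{\link{fom_params}} object.
#' @param belief scalar belief in the realised transition (normalised
#'   probability or raw count, matching \code{params$belief_measure}).
#' @param prev_error TRUE if the previous response was incorrect.
#' @return mean log RT in log-millisecond units.
#' @export
predict_mean_log_rt <- function(params, belief, prev_error = FALSE) {
  if (!is.finite(belief)) stop("belief must be finite")
  params$beta0 + params$beta1 * belief + params$beta2 * as.numeric(prev_error)
}

# prev_error regressor: previous row's recorded incorrectness, but only when
# that row is the true session predecessor (contiguous trial index)
.prev_error <- function(trial, correct) {
  n <- length(trial)
  if (n == 0L) return(logical(0))
  pe <- c(FALSE, !correct[-n])
  contiguous <- c(FALSE, trial[-1L] == trial[-n] + 1L)
  pe & contiguous
}

#' Run the forgetful observer filter over a stimulus stream
#'
#' Sequentially applies the decay-and-count belief update to every trial
#' of the stream (stimuli are observed regardless of response validity)
#' and records, for every trial with a predecessor, the pre-update
#' (predictive) belief in the realised transition and the mean log RT
#' predicted by the response model.  With \code{reset_at_block}, beliefs
#' are reinitialised to \code{gamma} at each block start.
#'
#' An all-zero count row (reachable only with \code{gamma = 0} before any
#' observation from that predecessor) yields the uniform predictive 0.25,
#' the symmetric limit of the Dirichlet mean.
#'
#' @param trials data.frame with columns \code{trial}, \code{block},
#'   \code{prev_stim}, \code{stim} and optionally \code{correct} (a
#'   \code{\link{simulate_subject}} trial table or the \code{trials} field
#'   of an \code{srtt_subject}).
#' @param params a \code{\link{fom_params}} object.
#' @param correct optional logical vector overriding
#'   \code{trials$correct}; defaults to all-correct if absent.
#' @return data.frame with one row per trial with a predecessor:
#'   \code{trial}, \code{block}, \code{prev_stim}, \code{stim},
#'   \code{belief}, \code{prev_error}, \code{pred_log_rt}.
#' @export
fom_filter <- function(trials, params, correct = NULL) {
  stopifnot(inherits(params, "fom_params"))
  if (inherits(trials, "srtt_subject")) trials <- trials$trials
  n <- nrow(trials)
  if (is.null(correct))
    correct <- if ("correct" %in% names(trials)) trials$correct else
      rep(TRUE, n)
  prev_err <- .prev_error(trials$trial, correct)
  U <- init_beliefs(params$gamma)
  belief <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    if (params$reset_at_block &&
        (t == 1L || trials$block[t] != trials$block[t - 1L]))
      U <- init_beliefs(params$gamma)
    p <- trials$prev_stim[t]
    s <- trials$stim[t]
    if (!is.na(p)) {
      if (params$belief_measure == "normalized") {
        rs <- sum(U[p, ])
        belief[t] <- if (rs > 0) U[p, s] / rs else 0.25
      } else {
        belief[t] <- U[p, s]
      }
      U <- update_beliefs(U, p, s, params$lambda, params$gamma,
                          params$count_weight)
    }
  }
  keep <- !is.na(trials$prev_stim)
  data.frame(trial = trials$trial[keep], block = trials$block[keep],
             prev_stim = trials$prev_stim[keep], stim = trials$stim[keep],
             belief = belief[keep], prev_error = prev_err[keep],
             pred_log_rt = params$beta0 + params$beta1 * belief[keep] +
               params$beta2 * as.numeric(prev_err[keep]))
}

# rows of a trial table that contribute likelihood terms:
# valid response, observed RT, and a session predecessor
.likelihood_rows <- function(trials) {
  !is.na(trials$prev_stim) & trials$valid & !is.na(trials$rt_ms)
}

#' Log likelihood of a subject's RTs under the forgetful observer model
#'
#' Sums the Gaussian log density of observed log RT (ms) at the response
#' model's predicted mean, with SD \code{params$sigma}, over all valid
#' trials that have a predecessor.  Invalid trials (misses,
#' anticipations) update beliefs but contribute no likelihood term.
#'
#' @param subject an \code{srtt_subject} or its trial data.frame.
#' @param params a \code{\link{fom_params}} object.
#' @return scalar log likelihood.
#' @export
fom_log_likelihood <- function(subject, params) {
  trials <- if (inherits(subject, "srtt_subject")) subject$trials else subject
  traj <- fom_filter(trials, params)
  keep <- .likelihood_rows(trials)
  if (!any(keep)) stop("no valid trials with a predecessor and an RT")
  idx <- match(trials$trial[keep], traj$trial)
  sum(stats::dnorm(log(trials$rt_ms[keep]), traj$pred_log_rt[idx],
                   params$sigma, log = TRUE))
}
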