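#' Parameters of the hierarchical Gaussian filter comparator
#'
#' A three-level filter: 16 independent binary random-walk nodes (one per
#' transition cell, not normalised by row), whose propensities are
#' sigmoid-transformed level-2 states, coupled to a single shared level-3
#' volatility node.  The response model is a linear combination of a
#' post-error indicator, the precision-weighted prediction errors at
#' levels 1 and 2, and the current volatility estimate, with Gaussian
#' response noise of variance \code{exp(zeta)}.
#'
#' The 10 subject-specific parameters are \code{mu3_0}, \code{sigma3_0}
#' (prior mean and variance of initial volatility), \code{theta}
#' (metavolatility, level-3 step size, bounded above by
#' \code{theta_max}), \code{omega} (tonic level-2 step size),
#' \code{beta} (five response coefficients) and \code{zeta}.
#'
#' @param mu3_0 initial volatility mean.
#' @param sigma3_0 initial volatility variance (> 0).
#' @param theta metavolatility in \code{(0, theta_max]}.
#' @param omega tonic log step size of the level-2 walks.
#' @param beta numeric vector of 5 response coefficients
#'   (intercept, post-error, level-1 PWPE, level-2 PWPE, volatility).
#' @param zeta log response variance; prior N(-3, 100) in relaxed mode,
#'   N(-3, 0.01) in restrictive mode.
#' @param theta_max upper bound on \code{theta} (default 0.5).
#' @param zeta_prior \code{"relaxed"} (default) or \code{"restrictive"}.
#' @return an object of class \code{hgf_params}.
#' @export
hgf_params <- function(mu3_0 = 1, sigma3_0 = 1, theta = 0.2, omega = -4,
                       beta = c(6.6, 0.05, 0.5, 0.2, 0.05), zeta = -3.2,
                       theta_max = 0.5,
                       zeta_prior = c("relaxed", "restrictive")) {
  zeta_prior <- match.arg(zeta_prior)
  if (sigma3_0 <= 0) stop("sigma3_0 must be > 0")
  if (theta <= 0 || theta > theta_max)
    stop("theta must lie in (0, theta_max]")
  if (length(beta) != 5L) stop("beta must have 5 coefficients")
  structure(list(mu3_0 = mu3_0, sigma3_0 = sigma3_0, theta = theta,
                 omega = omega, beta = as.numeric(beta), zeta = zeta,
                 theta_max = theta_max, zeta_prior = zeta_prior),
            class = "hgf_params")
}

#' @export
print.hgf_params <- function(x, ...) {
  cat("Hierarchical Gaussian filter parameters:\n")
  cat(sprintf("  mu3_0 = %.4g, sigma3_0 = %.4g, theta = %.4g (max %.3g), omega = %.4g\n",
              x$mu3_0, x$sigma3_0, x$theta, x$theta_max, x$omega))
  cat(sprintf("  beta = (%s), zeta = %.4g (%s prior)\n",
              paste(sprintf("%.4g", x$beta), collapse = ", "),
              x$zeta, x$zeta_prior))
  invisible(x)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Run the hierarchical Gaussian filter over a stimulus stream
#'
#' On each trial the four transition cells whose source matches the
#' previous stimulus receive a binary observation (1 for the realised
#' successor, 0 for the others) and are updated by precision-weighted
#' prediction errors; all 16 cells propagate predictive variance using
#' the shared volatility state, which is itself updated from the informed
#' cells' level-2 volatility prediction errors.  Level-2 states start at
#' \code{logit(0.25)} (uniform propensity) with unit variance.
#'
#' @param trials trial table (as for \code{\link{fom_filter}}) or an
#'   \code{srtt_subject}.
#' @param params an \code{\link{hgf_params}} object.
#' @param correct optional logical vector of response correctness.
#' @return list with \code{traj}, a data.frame over trials with a
#'   predecessor (\code{trial}, \code{block}, \code{prev_stim},
#'   \code{stim}, \code{p_real} predicted propensity of the realised
#'   cell, \code{row_sum} sum of the active row's four propensities,
#'   \code{pwpe1}, \code{pwpe2}, \code{vol}, \code{prev_error},
#'   \code{pred_log_rt}), and \code{final_state} (\code{mu2},
#'   \code{sigma2}, \code{mu3}, \code{sigma3}).
#' @export
hgf_filter <- function(trials, params, correct = NULL) {
  stopifnot(inherits(params, "hgf_params"))
  if (inherits(trials, "srtt_subject")) trials <- trials$trials
  n <- nrow(trials)
  if (is.null(correct))
    correct <- if ("correct" %in% names(trials)) trials$correct else
      rep(TRUE, n)
  prev_err <- .prev_error(trials$trial, correct)

  mu2 <- matrix(stats::qlogis(0.25), 4L, 4L)
  sigma2 <- matrix(1, 4L, 4L)
  mu3 <- params$mu3_0
  sigma3 <- params$sigma3_0
  b <- params$beta

  p_real <- row_sum <- pwpe1 <- pwpe2 <- vol <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    i <- trials$prev_stim[t]
    if (is.na(i)) next
    j <- trials$stim[t]
    nu <- exp(mu3 + params$omega)              # level-2 process variance
    sigmahat2 <- sigma2 + nu
    muhat1 <- .sigmoid(mu2[i, ])
    p_real[t] <- muhat1[j]
    row_sum[t] <- sum(muhat1)
    u <- as.numeric(1:4 == j)
    delta1 <- u - muhat1
    sigmahat1 <- muhat1 * (1 - muhat1)
    pihat2 <- 1 / sigmahat2[i, ]
    pi2 <- pihat2 + sigmahat1
    eps2 <- delta1 / pi2                       # level-1 PWPE (mu2 increment)
    mu2[i, ] <- mu2[i, ] + eps2
    # volatility prediction errors of the informed cells
    delta2 <- (1 / pi2 + eps2^2) * pihat2 - 1
    pihat3 <- 1 / (sigma3 + params$theta)
    w2 <- nu * pihat2
    r2 <- (nu - sigma2[i, ]) * pihat2
    pi3 <- pihat3 + sum(0.5 * w2 * (w2 + r2 * delta2))
    if (!is.finite(pi3) || pi3 <= 0)
      stop(sprintf("filter instability: non-positive level-3 precision at trial %d",
                   trials$trial[t]))
    mu3_new <- mu3 + sum(w2 / (2 * pi3) * delta2)
    pwpe1[t] <- eps2[j]
    pwpe2[t] <- mu3_new - mu3
    vol[t] <- mu3
    sigma2 <- sigmahat2
    sigma2[i, ] <- 1 / pi2
    sigma3 <- 1 / pi3
    mu3 <- mu3_new
    if (any(sigma2 <= 0) || sigma3 <= 0)
      stop(sprintf("filter instability: non-positive variance at trial %d",
                   trials$trial[t]))
  }
  keep <- !is.na(trials$prev_stim)
  traj <- data.frame(
    trial = trials$trial[keep], block = trials$block[keep],
    prev_stim = trials$prev_stim[keep], stim = trials$stim[keep],
    p_real = p_real[keep], row_sum = row_sum[keep],
    pwpe1 = pwpe1[keep], pwpe2 = pwpe2[keep], vol = vol[keep],
    prev_error = prev_err[keep])
  traj$pred_log_rt <- b[1] + b[2] * as.numeric(traj$prev_error) +
    b[3] * traj$pwpe1 + b[4] * traj$pwpe2 + b[5] * traj$vol
  list(traj = traj,
       final_state = list(mu2 = mu2, sigma2 = sigma2, mu3 = mu3,
                          sigma3 = sigma3))
}

#' Mean and SD of predicted log RT under the HGF response model
#'
#' @param params an \code{\link{hgf_params}} object.
#' @param trial_state one row of the trajectory returned by
#'   \code{\link{hgf_filter}} (fields \code{pwpe1}, \code{pwpe2},
#'   \code{vol}).
#' @param prev_error TRUE if the previous response was incorrect.
#' @return list with \code{mean} and \code{sd} of log RT.
#' @export
hgf_predict_log_rt <- function(params, trial_state, prev_error = FALSE) {
  b <- params$beta
  m <- b[1] + b[2] * as.numeric(prev_error) + b[3] * trial_state$pwpe1 +
    b[4] * trial_state$pwpe2 + b[5] * trial_state$vol
  list(mean = m, sd = exp(params$zeta / 2))
}

# response-free sequence log score: normalised predicted probability of the
# realised transition (normalisation is for scoring only; the filter's
# propensities stay unnormalised)
.hgf_sequence_score <- function(trials, params) {
  out <- tryCatch(hgf_filter(trials, params), error = function(e) NULL)
  if (is.null(out)) return(-Inf)
  p <- out$traj$p_real / out$traj$row_sum
  if (any(!is.finite(log(p)))) return(-Inf)
  sum(log(p))
}

#' Response-free perceptual priors from the stimulus sequence
#'
#' Fits the perceptual component to the stimulus stream alone
#' (independent of responses) by maximising the summed log probability of
#' each realised transition under the filter's one-step predictions, and
#' returns the optimum as prior means for the subsequent joint fit.
#' The optimiser (Nelder-Mead over transformed parameters) is
#' deterministic given the same start point.
#'
#' @param trials trial table containing the stimulus stream.
#' @param theta_max upper bound on theta.
#' @param start named start values (\code{mu3_0}, \code{theta},
#'   \code{omega}).
#' @param sigma3_0 initial volatility variance held at its configured
#'   value (returned unchanged as its prior mean).
#' @return named list of prior means (\code{mu3_0}, \code{sigma3_0},
#'   \code{theta}, \code{omega}) plus optimiser diagnostics
#'   (\code{value}, \code{convergence}).
#' @export
optimal_perceptual_priors <- function(trials, theta_max = 0.5,
                                      start = c(mu3_0 = 1, theta = 0.1,
                                                omega = -4),
                                      sigma3_0 = 1) {
  if (inherits(trials, "srtt_subject")) trials <- trials$trials
  to_theta <- function(x) theta_max * .sigmoid(x)
  x0 <- c(start[["mu3_0"]],
          stats::qlogis(min(start[["theta"]] / theta_max, 0.999)),
          start[["omega"]])
  # weak hand-specified regularisers keep the search off the plateaus of
  # the sequence score (theta in particular is weakly identified from the
  # stimulus stream alone)
  obj <- function(x) {
    p <- hgf_params(mu3_0 = x[1], sigma3_0 = sigma3_0,
                    theta = to_theta(x[2]), omega = x[3],
                    theta_max = theta_max)
    -(.hgf_sequence_score(trials, p) +
        stats::dnorm(x[1], 1, 2, log = TRUE) +
        stats::dnorm(x[2], 0, 2, log = TRUE) +
        stats::dnorm(x[3], -4, 3, log = TRUE))
  }
  opt <- stats::optim(x0, obj, method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-7))
  if (!is.finite(opt$value))
    stop("perceptual prior optimisation failed: no finite sequence score")
  list(mu3_0 = opt$par[1], sigma3_0 = sigma3_0,
       theta = to_theta(opt$par[2]), omega = opt$par[3],
       value = -opt$value, convergence = opt$convergence)
}

#' Simulate a subject's RTs from the HGF response model
#'
#' Runs the HGF filter over a stimulus sequence and draws log RTs from
#' the linear response model with SD \code{exp(zeta/2)}.  Error and
#' invalid-trial injection mirror \code{\link{simulate_subject}}.
#'
#' @inheritParams simulate_subject
#' @param params an \code{\link{hgf_params}} object.
#' @return an \code{srtt_subject}.
#' @export
simulate_subject_hgf <- function(sequence, params, p_error = 0.05,
                                 p_invalid = 0.02, subject_id = "s1",
                                 group = "placebo", covariates = list()) {
  stopifnot(inherits(params, "hgf_params"))
  n <- nrow(sequence)
  error <- stats::runif(n) < p_error
  valid <- stats::runif(n) >= p_invalid
  correct <- !error & valid
  out <- hgf_filter(sequence, params, correct = correct)
  mean_log_rt <- c(params$beta[1], out$traj$pred_log_rt)
  log_rt <- mean_log_rt + stats::rnorm(n, 0, exp(params$zeta / 2))
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
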