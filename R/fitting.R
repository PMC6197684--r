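#' Bayesian Information Criterion
#'
#' \code{-2 LL + k log(n)}; lower is better.
#'
#' @param log_likelihood scalar log likelihood.
#' @param k number of free parameters.
#' @param n number of likelihood trials.
#' @return scalar BIC.
#' @export
bic <- function(log_likelihood, k, n) {
  if (n < 1) stop("BIC needs at least one likelihood trial")
  if (k < 0) stop("k must be >= 0")
  -2 * log_likelihood + k * log(n)
}

.new_fit <- function(model, params, ll, k, n, predicted, converged,
                     diagnostics = list()) {
  structure(list(model = model, params = params, log_likelihood = ll,
                 bic = bic(ll, k, n), k = k, n_trials = n,
                 predicted = predicted, converged = converged,
                 diagnostics = diagnostics),
            class = "psrtt_fit")
}

#' @export
print.psrtt_fit <- function(x, ...) {
  cat(sprintf("%s fit: LL = %.2f, BIC = %.2f (k = %d, n = %d trials)%s\n",
              x$model, x$log_likelihood, x$bic, x$k, x$n_trials,
              if (x$converged) "" else " [not converged]"))
  if (x$model == "FOM")
    cat(sprintf("  lambda = %.4f, beta = (%.4f, %.4f, %.4f), sigma = %.4f\n",
                x$params$lambda, x$params$beta0, x$params$beta1,
                x$params$beta2, x$params$sigma))
  invisible(x)
}

# profile log likelihood of the FOM at fixed (lambda, count_weight):
# run the filter, solve the response coefficients by OLS and profile sigma
# at its ML value
.fom_profile <- function(trials, lambda, gamma, belief_measure,
                         count_weight, reset_at_block) {
  params <- fom_params(lambda = lambda, gamma = gamma,
                       belief_measure = belief_measure,
                       count_weight = count_weight,
                       reset_at_block = reset_at_block)
  traj <- fom_filter(trials, params)
  keep <- .likelihood_rows(trials)
  idx <- match(trials$trial[keep], traj$trial)
  y <- log(trials$rt_ms[keep])
  X <- cbind(1, traj$belief[idx], as.numeric(traj$prev_error[idx]))
  fit <- stats::lm.fit(X, y)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0  # an all-zero regressor (e.g. no errors occurred)
  rss <- sum(fit$residuals^2)
  n <- length(y)
  sigma2 <- rss / n
  if (sigma2 <= 0)
    stop("degenerate variance: all RTs identical to the model prediction")
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  list(ll = ll, beta = unname(coefs), sigma = sqrt(sigma2),
       n = n, traj = traj, idx = idx)
}

#' Fit the forgetful observer model to one subject
#'
#' Nested profile-likelihood estimation: for each candidate forgetting
#' rate \code{lambda} the belief filter is run, the response coefficients
#' \code{beta0}-\code{beta2} are solved by ordinary least squares of
#' observed log RT on (1, belief, post-error indicator) and the residual
#' SD profiles out \code{sigma}; the outer search over \code{lambda} in
#' [0, 1] evaluates a grid of restart points and refines the best
#' bracket by golden-section/parabolic search.  \code{gamma} is fixed
#' (default 1), so the free-parameter count is 4 (\code{lambda},
#' \code{beta0}-\code{beta2}); \code{sigma} is a profiled nuisance.
#'
#' @param subject an \code{srtt_subject} or trial data.frame.
#' @param gamma fixed asymptotic prior (default 1).
#' @param belief_measure \code{"normalized"} (default) or \code{"count"}.
#' @param reset_at_block reset beliefs to \code{gamma} at block starts.
#' @param free_count_weight also estimate the count weight added per
#'   observation (adds one free parameter).
#' @param grid restart values for the outer \code{lambda} search.
#' @return a \code{psrtt_fit} with \code{model = "FOM"}.
#' @export
fit_fom <- function(subject, gamma = 1,
                    belief_measure = c("normalized", "count"),
                    reset_at_block = FALSE, free_count_weight = FALSE,
                    grid = c(0.05, 0.25, 0.45, 0.65, 0.85)) {
  belief_measure <- match.arg(belief_measure)
  trials <- if (inherits(subject, "srtt_subject")) subject$trials else subject
  n_like <- sum(.likelihood_rows(trials))
  if (n_like < 10L)
    stop("too few valid likelihood trials (need >= 10)")
  if (stats::sd(log(trials$rt_ms[.likelihood_rows(trials)])) == 0)
    stop("degenerate variance: all observed RTs identical")

  n_evals <- 0L
  prof_ll <- function(lambda, w = 1) {
    n_evals <<- n_evals + 1L
    .fom_profile(trials, lambda, gamma, belief_measure, w,
                 reset_at_block)$ll
  }

  if (!free_count_weight) {
    lams <- sort(unique(c(0, grid, seq(0, 1, by = 0.05), 1)))
    lls <- vapply(lams, prof_ll, numeric(1))
    best <- which.max(lls)
    lo <- lams[max(1L, best - 1L)]
    hi <- lams[min(length(lams), best + 1L)]
    opt <- stats::optimize(prof_ll, lower = lo, upper = hi, maximum = TRUE,
                           tol = 1e-7)
    lambda_hat <- if (opt$objective >= lls[best]) opt$maximum else lams[best]
    w_hat <- 1
    converged <- TRUE
  } else {
    # 2-D Nelder-Mead over (logit lambda, log count weight), restarted
    # from the lambda grid
    obj <- function(x) -prof_ll(.sigmoid(x[1]), exp(x[2]))
    best_val <- Inf; best_par <- NULL; converged <- FALSE
    for (l0 in grid) {
      o <- stats::optim(c(stats::qlogis(l0), 0), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 200, reltol = 1e-8))
      if (o$value < best_val) {
        best_val <- o$value; best_par <- o$par
        converged <- o$convergence == 0
      }
    }
    lambda_hat <- .sigmoid(best_par[1])
    w_hat <- exp(best_par[2])
  }

  prof <- .fom_profile(trials, lambda_hat, gamma, belief_measure, w_hat,
                       reset_at_block)
  params <- fom_params(lambda = lambda_hat, gamma = gamma,
                       beta0 = prof$beta[1], beta1 = prof$beta[2],
                       beta2 = prof$beta[3], sigma = prof$sigma,
                       belief_measure = belief_measure,
                       count_weight = w_hat,
                       reset_at_block = reset_at_block)
  k <- 4L + as.integer(free_count_weight)
  .new_fit("FOM", params, prof$ll, k, prof$n,
           predicted = prof$traj[, c("trial", "pred_log_rt")],
           converged = converged,
           diagnostics = list(n_profile_evals = n_evals))
}

# HGF inner step at fixed perceptual parameters: OLS for the response
# coefficients (flat priors) and a 1-D MAP for zeta under its prior
.hgf_profile <- function(trials, mu3_0, sigma3_0, theta, omega, theta_max,
                         zeta_prior) {
  params <- hgf_params(mu3_0 = mu3_0, sigma3_0 = sigma3_0, theta = theta,
                       omega = omega, theta_max = theta_max,
                       zeta_prior = zeta_prior)
  out <- hgf_filter(trials, params)
  traj <- out$traj
  keep <- .likelihood_rows(trials)
  idx <- match(trials$trial[keep], traj$trial)
  y <- log(trials$rt_ms[keep])
  X <- cbind(1, as.numeric(traj$prev_error[idx]), traj$pwpe1[idx],
             traj$pwpe2[idx], traj$vol[idx])
  fit <- stats::lm.fit(X, y)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  rss <- sum(fit$residuals^2)
  n <- length(y)
  zeta_sd <- if (zeta_prior == "relaxed") 10 else 0.1
  zobj <- function(z)
    -n / 2 * (log(2 * pi) + z) - rss / (2 * exp(z)) +
      stats::dnorm(z, -3, zeta_sd, log = TRUE)
  zopt <- stats::optimize(zobj, lower = -12, upper = 5, maximum = TRUE)
  zeta <- zopt$maximum
  ll <- -n / 2 * (log(2 * pi) + zeta) - rss / (2 * exp(zeta))
  list(ll = ll, penalised = ll + stats::dnorm(zeta, -3, zeta_sd, log = TRUE),
       beta = unname(coefs), zeta = zeta, n = n, traj = traj)
}

#' Fit the hierarchical Gaussian filter to one subject
#'
#' Stepwise fitting: prior means for the perceptual parameters are first
#' obtained by fitting the perceptual component to the stimulus sequence
#' alone (\code{\link{optimal_perceptual_priors}}); the perceptual and
#' response components are then fit jointly to the RTs by maximising the
#' penalised likelihood (Gaussian priors on the perceptual parameters
#' centred at those means, the \code{zeta} prior, and the bound on
#' \code{theta}).  The response coefficients carry flat priors and are
#' profiled by least squares.  The reported \code{log_likelihood} is
#' unpenalised; the free-parameter count is 10.
#'
#' @param subject an \code{srtt_subject} or trial data.frame.
#' @param theta_max upper bound on the metavolatility.
#' @param zeta_prior \code{"relaxed"} (default) or \code{"restrictive"}.
#' @param prior_sd named prior SDs for the perceptual parameters around
#'   their sequence-derived means.
#' @param maxit Nelder-Mead iteration cap for the joint fit.
#' @return a \code{psrtt_fit} with \code{model = "HGF"}.
#' @export
fit_hgf <- function(subject, theta_max = 0.5,
                    zeta_prior = c("relaxed", "restrictive"),
                    prior_sd = c(mu3_0 = 2, log_sigma3_0 = 1, theta = 0.2,
                                 omega = 2),
                    maxit = 400) {
  zeta_prior <- match.arg(zeta_prior)
  trials <- if (inherits(subject, "srtt_subject")) subject$trials else subject
  if (sum(.likelihood_rows(trials)) < 10L)
    stop("too few valid likelihood trials (need >= 10)")

  pri <- optimal_perceptual_priors(trials, theta_max = theta_max)
  to_theta <- function(x) theta_max * .sigmoid(x)
  x0 <- c(pri$mu3_0, log(pri$sigma3_0),
          stats::qlogis(min(max(pri$theta / theta_max, 1e-3), 0.999)),
          pri$omega)
  obj <- function(x) {
    prof <- tryCatch(
      .hgf_profile(trials, mu3_0 = x[1], sigma3_0 = exp(x[2]),
                   theta = to_theta(x[3]), omega = x[4],
                   theta_max = theta_max, zeta_prior = zeta_prior),
      error = function(e) NULL)
    if (is.null(prof)) return(1e10)
    pen <- stats::dnorm(x[1], pri$mu3_0, prior_sd[["mu3_0"]], log = TRUE) +
      stats::dnorm(x[2], log(pri$sigma3_0), prior_sd[["log_sigma3_0"]],
                   log = TRUE) +
      stats::dnorm(to_theta(x[3]), pri$theta, prior_sd[["theta"]],
                   log = TRUE) +
      stats::dnorm(x[4], pri$omega, prior_sd[["omega"]], log = TRUE)
    -(prof$penalised + pen)
  }
  opt <- stats::optim(x0, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-7))
  prof <- .hgf_profile(trials, mu3_0 = opt$par[1], sigma3_0 = exp(opt$par[2]),
                       theta = to_theta(opt$par[3]), omega = opt$par[4],
                       theta_max = theta_max, zeta_prior = zeta_prior)
  params <- hgf_params(mu3_0 = opt$par[1], sigma3_0 = exp(opt$par[2]),
                       theta = to_theta(opt$par[3]), omega = opt$par[4],
                       beta = prof$beta, zeta = prof$zeta,
                       theta_max = theta_max, zeta_prior = zeta_prior)
  .new_fit("HGF", params, prof$ll, 10L, prof$n,
           predicted = prof$traj[, c("trial", "pred_log_rt")],
           converged = opt$convergence == 0,
           diagnostics = list(priors = pri, optim_value = opt$value,
                              optim_convergence = opt$convergence))
}
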