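#' Model confusion analysis
#'
#' Simulates datasets from each candidate model, fits both models to
#' every dataset, selects per dataset by the higher (unpenalised) log
#' likelihood, and tabulates how often the generating model wins.  A low
#' misclassification fraction shows that log-likelihood selection can
#' tell the two model classes apart on this task.
#'
#' @param n_per_model datasets simulated per generating model.
#' @param fom_gen generative \code{\link{fom_params}}.
#' @param hgf_gen generative \code{\link{hgf_params}}.
#' @param design a \code{\link{task_design}}.
#' @param n_blocks number of blocks per simulated dataset (a random
#'   repeat-free sub-schedule of the design; default the full schedule).
#' @param sigma,p_error,p_invalid simulation noise settings for the FOM
#'   datasets (the HGF's response noise comes from its \code{zeta}).
#' @param seed optional integer seed.
#' @return an object of class \code{confusion_result}: per generating
#'   model the number simulated, number correctly selected, number of
#'   fit failures, and misclassification fraction.
#' @export
confusion_analysis <- function(n_per_model, fom_gen, hgf_gen,
                               design = task_design(), n_blocks = NULL,
                               sigma = 0.2, p_error = 0.05,
                               p_invalid = 0.02, seed = NULL) {
  if (n_per_model < 1) stop("n_per_model must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  sim_one <- function(model, i) {
    sched <- sample_schedule(design)
    if (!is.null(n_blocks)) sched <- sched[seq_len(n_blocks)]
    seq_i <- generate_sequence(sched, design)
    if (model == "FOM")
      simulate_subject(seq_i, fom_gen, sigma = sigma, p_error = p_error,
                       p_invalid = p_invalid,
                       subject_id = sprintf("fom%03d", i))
    else
      simulate_subject_hgf(seq_i, hgf_gen, p_error = p_error,
                           p_invalid = p_invalid,
                           subject_id = sprintf("hgf%03d", i))
  }
  res <- lapply(c("FOM", "HGF"), function(gen) {
    correct <- 0L; failed <- 0L
    for (i in seq_len(n_per_model)) {
      subj <- sim_one(gen, i)
      lls <- tryCatch({
        c(FOM = fit_fom(subj)$log_likelihood,
          HGF = fit_hgf(subj)$log_likelihood)
      }, error = function(e) {
        warning(sprintf("fit failure on %s-generated dataset %d: %s",
                        gen, i, conditionMessage(e)))
        NULL
      })
      if (is.null(lls)) { failed <- failed + 1L; next }
      if (names(which.max(lls)) == gen) correct <- correct + 1L
    }
    n_eval <- n_per_model - failed
    data.frame(generating_model = gen, n_simulated = n_per_model,
               n_evaluated = n_eval, n_correct = correct,
               n_failed = failed,
               misclassification = if (n_eval > 0)
                 (n_eval - correct) / n_eval else NA_real_)
  })
  structure(list(table = do.call(rbind, res)), class = "confusion_result")
}

#' @export
print.confusion_result <- function(x, ...) {
  cat("Model confusion analysis (selection by higher log likelihood):\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Parameter recovery for the forgetful observer model
#'
#' Simulates one dataset per generative parameter set, refits the model,
#' and pairs true with recovered values.  Reports correlation, bias and
#' mean absolute error per parameter.
#'
#' @param true_params list of generative \code{\link{fom_params}}
#'   (at least 2).
#' @param design a \code{\link{task_design}}.
#' @param sigma,p_error,p_invalid simulation settings.
#' @param seed optional integer seed.
#' @return an object of class \code{recovery_result} with \code{pairs}
#'   (one row per parameter set: true and recovered lambda, beta0-beta2)
#'   and \code{summary} (correlation, bias, MAE per parameter).
#' @export
parameter_recovery <- function(true_params, design = task_design(),
                               sigma = 0.2, p_error = 0.05,
                               p_invalid = 0.02, seed = NULL) {
  if (length(true_params) < 2L) stop("need at least 2 parameter sets")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_along(true_params), function(i) {
    gen <- true_params[[i]]
    sched <- sample_schedule(design)
    subj <- simulate_subject(generate_sequence(sched, design), gen,
                             sigma = sigma, p_error = p_error,
                             p_invalid = p_invalid,
                             subject_id = sprintf("r%03d", i))
    fit <- tryCatch(fit_fom(subj, gamma = gen$gamma,
                            belief_measure = gen$belief_measure),
                    error = function(e) {
                      warning(sprintf("fit failure for set %d: %s", i,
                                      conditionMessage(e)))
                      NULL
                    })
    if (is.null(fit)) return(NULL)
    data.frame(set = i,
               true_lambda = gen$lambda, est_lambda = fit$params$lambda,
               true_beta0 = gen$beta0, est_beta0 = fit$params$beta0,
               true_beta1 = gen$beta1, est_beta1 = fit$params$beta1,
               true_beta2 = gen$beta2, est_beta2 = fit$params$beta2)
  })
  pairs <- do.call(rbind, rows)
  pars <- c("lambda", "beta0", "beta1", "beta2")
  summ <- do.call(rbind, lapply(pars, function(p) {
    tr <- pairs[[paste0("true_", p)]]
    es <- pairs[[paste0("est_", p)]]
    data.frame(parameter = p,
               correlation = if (stats::sd(tr) > 0)
                 stats::cor(tr, es) else NA_real_,
               bias = mean(es - tr), mae = mean(abs(es - tr)))
  }))
  structure(list(pairs = pairs, summary = summ), class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d simulated datasets:\n",
              nrow(x$pairs)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Group contrasts on a fitted parameter with covariate adjustment
#'
#' Two-stage summary-statistics analysis: each subject's point estimate
#' of the chosen parameter is regressed on group indicators plus
#' z-scored covariates; each drug group is contrasted against placebo
#' and p-values are Bonferroni-corrected for the number of drug groups.
#'
#' @param fits list of \code{psrtt_fit} objects (one per subject).
#' @param subjects list of the corresponding \code{srtt_subject} objects
#'   (source of group labels and covariates).
#' @param parameter name of the parameter to contrast (a field of the
#'   fitted parameter object, e.g. \code{"lambda"}, \code{"beta1"}).
#' @param reference reference group label (default \code{"placebo"}).
#' @param covariate_names covariates entered into the linear model
#'   (z-scored); missing covariates are dropped with a message.
#' @return data.frame of class \code{group_contrasts}: one row per
#'   drug-vs-reference contrast with the adjusted effect estimate, raw
#'   and Bonferroni-corrected p-values, and the covariates used.
#' @export
compare_groups <- function(fits, subjects, parameter = "lambda",
                           reference = "placebo",
                           covariate_names = c("body_weight", "alertness")) {
  stopifnot(length(fits) == length(subjects))
  value <- vapply(fits, function(f) f$params[[parameter]], numeric(1))
  group <- vapply(subjects, `[[`, character(1), "group")
  if (length(unique(group)) < 2L) stop("need at least 2 groups")
  if (min(table(group)) < 3L) stop("need >= 3 subjects per group")
  covs <- lapply(covariate_names, function(nm) {
    v <- vapply(subjects, function(s)
      if (is.null(s$covariates[[nm]])) NA_real_ else s$covariates[[nm]],
      numeric(1))
    if (anyNA(v)) { message("dropping covariate with missing values: ", nm);
                    NULL } else as.numeric(scale(v))
  })
  names(covs) <- covariate_names
  covs <- Filter(Negate(is.null), covs)
  df <- data.frame(value = value,
                   group = stats::relevel(factor(group), ref = reference))
  for (nm in names(covs)) df[[nm]] <- covs[[nm]]
  form <- stats::reformulate(c("group", names(covs)), response = "value")
  X <- stats::model.matrix(form, df)
  if (qr(X)$rank < ncol(X)) {
    bad <- colnames(X)[qr(X)$pivot[-seq_len(qr(X)$rank)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(form, data = df)
  coefs <- summary(fit)$coefficients
  rows <- grep("^group", rownames(coefs), value = TRUE)
  n_contrasts <- length(rows)
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(parameter = parameter,
               contrast = paste(sub("^group", "", r), "vs", reference),
               estimate = coefs[r, "Estimate"],
               p_raw = coefs[r, "Pr(>|t|)"],
               p_bonferroni = min(1, n_contrasts * coefs[r, "Pr(>|t|)"]),
               covariates = paste(names(covs), collapse = ","))
  }))
  class(out) <- c("group_contrasts", class(out))
  out
}

#' Fit the forgetful observer model separately per matrix type
#'
#' Partitions a subject's trials by the dynamics class of the active
#' matrix (zeroth / first / alternating) and fits an independent model to
#' each partition with beliefs reset to uniform at every block start
#' (the block sequence within a class is disrupted, so carrying beliefs
#' across the gaps would be meaningless).
#'
#' @param subject an \code{srtt_subject}.
#' @param design the \code{\link{task_design}} that generated the data
#'   (source of each matrix's dynamics class).
#' @param ... passed to \code{\link{fit_fom}}.
#' @return named list of \code{psrtt_fit} objects, one per dynamics
#'   class present; empty partitions are skipped with a warning.
#' @export
fit_by_matrix_type <- function(subject, design = task_design(), ...) {
  trials <- subject$trials
  ids <- vapply(design$matrices, `[[`, integer(1), "id")
  dyn <- vapply(design$matrices, `[[`, character(1), "dynamics")
  cls <- dyn[match(trials$matrix_id, ids)]
  out <- list()
  for (type in c("zeroth", "first", "alternating")) {
    sub <- trials[cls == type, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("no trials for matrix type ", type, "; skipped")
      next
    }
    fit <- tryCatch(fit_fom(sub, reset_at_block = TRUE, ...),
                    error = function(e) {
                      warning(sprintf("fit failed for type %s: %s", type,
                                      conditionMessage(e)))
                      NULL
                    })
    if (!is.null(fit)) out[[type]] <- fit
  }
  out
}
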