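#' Monte-Carlo bias of a set of replicated estimates
#'
#' Mean of the replicated estimates minus the finite-population truth.
#'
#' @param estimates Numeric vector of per-replication estimates.
#' @param truth The finite-population parameter.
#' @return `mean(estimates) - truth`.
#' @export
estimate_bias <- function(estimates, truth) {
  if (!length(estimates)) stop("`estimates` is empty", call. = FALSE)
  mean(estimates) - truth
}

#' Monte-Carlo mean squared error of a set of replicated estimates
#'
#' Sample variance of the estimates (divisor M - 1) plus the squared
#' bias, the usual decomposition of the MSE of a replicated study.
#'
#' @inheritParams estimate_bias
#' @return `var(estimates) + estimate_bias(estimates, truth)^2`.
#' @export
estimate_mse <- function(estimates, truth) {
  if (length(estimates) < 2L)
    stop("at least two replications are required", call. = FALSE)
  var(estimates) + estimate_bias(estimates, truth)^2
}

#' Configure a replicated simulation scenario
#'
#' Collects everything [run_scenario()] needs: the population size, the
#' convenience-sampling scheme, sample sizes, the number of
#' replications, the propensity estimators to compare, the weighting
#' scheme and the master seed. Defaults reproduce the reference
#' setting: a population of 50,000, a reference sample of 500 drawn by
#' SRSWOR, 500 replications, Hajek weighting.
#'
#' @param scheme Convenience-sampling scheme: `"srswor"`,
#'   `"logit_linear"` or `"logit_sine"`.
#' @param n_vs Convenience (volunteer) sample size; the reference study
#'   varies it over 500, 750, 1000, 2000, 5000, 7500, 10000.
#' @param n_rs Reference sample size (default 500).
#' @param n_pop Population size (default 50,000).
#' @param reps Number of Monte-Carlo replications (default 500).
#' @param estimators A [propensity_spec()], or a named list of them.
#' @param weighting `"hajek"` (default) or `"ht_class"`.
#' @param n_classes Propensity classes for `"ht_class"` weighting.
#' @param parties Subset of `c("p1", "p2", "p3")`.
#' @param covariates Covariate columns used by the propensity models.
#' @param master_seed Single integer seeding the population, every
#'   sample draw and every stochastic fit through named substreams.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(scheme = c("srswor", "logit_linear", "logit_sine"),
                            n_vs = 1000L, n_rs = 500L, n_pop = 50000L,
                            reps = 500L,
                            estimators = propensity_spec("logistic"),
                            weighting = c("hajek", "ht_class"),
                            n_classes = 5L,
                            parties = c("p1", "p2", "p3"),
                            covariates = c("age", "gender", "nationality",
                                           "education"),
                            master_seed = 1L) {
  scheme <- match.arg(scheme)
  weighting <- match.arg(weighting)
  parties <- match.arg(parties, several.ok = TRUE)
  if (reps < 1L) stop("`reps` must be >= 1", call. = FALSE)
  if (inherits(estimators, "propensity_spec")) estimators <- list(estimators)
  if (!length(estimators) || !all(vapply(estimators, inherits, logical(1),
                                         "propensity_spec")))
    stop("`estimators` must be propensity_spec objects", call. = FALSE)
  if (is.null(names(estimators)) || any(!nzchar(names(estimators)))) {
    names(estimators) <- make.unique(vapply(estimators, `[[`, "", "algorithm"))
  }
  structure(list(scheme = scheme, n_vs = as.integer(n_vs),
                 n_rs = as.integer(n_rs), n_pop = as.integer(n_pop),
                 reps = as.integer(reps), estimators = estimators,
                 weighting = weighting, n_classes = as.integer(n_classes),
                 parties = parties, covariates = covariates,
                 master_seed = as.integer(master_seed)),
            class = "scenario_config")
}

#' Run a replicated bias/MSE study
#'
#' Generates (or reuses) one finite population, then for each
#' replication draws a fresh SRSWOR reference sample from the full
#' population and a fresh convenience sample from the internet
#' subpopulation, fits every configured propensity estimator on the
#' stacked sample, reweights the volunteer units, and estimates each
#' party proportion alongside the unadjusted volunteer mean. Estimates
#' are summarised as bias and MSE against the empirical truth of the
#' realised population. Estimator seeds are derived per (replication,
#' estimator), so all estimators see identical samples (a paired
#' design). Everything is reproducible from `master_seed`.
#'
#' @param config A [scenario_config()].
#' @param population Optional pre-generated population (so several
#'   scenarios can share one realisation); defaults to a fresh
#'   [generate_population()] seeded from the master seed.
#' @return A `scenario_result`: list with `estimates` (replications x
#'   estimators-plus-unadjusted x parties array), `truth`, and
#'   `summary`, a long data frame with columns scheme, algorithm,
#'   n_vs, party, bias, mse.
#' @export
run_scenario <- function(config, population = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(population)) {
    population <- generate_population(
      config$n_pop, substream_seed(config$master_seed, "population"))
  }
  internet_pop <- population[population$internet, , drop = FALSE]
  if (config$n_vs > nrow(internet_pop))
    stop("`n_vs` exceeds the internet subpopulation size", call. = FALSE)
  truth <- vapply(config$parties, function(pt)
    true_proportion(population, pt), numeric(1))

  arms <- c(names(config$estimators), "unadjusted")
  est <- array(NA_real_,
               dim = c(config$reps, length(arms), length(config$parties)),
               dimnames = list(NULL, arms, config$parties))

  for (m in seq_len(config$reps)) {
    ref <- srswor(population, config$n_rs,
                  substream_seed(config$master_seed, "reference", m))
    vol <- draw_convenience(internet_pop, config$scheme, config$n_vs,
                            substream_seed(config$master_seed, "convenience", m))
    smp <- combine_samples(ref, vol, config$covariates)
    y <- vol$data[paste0("vote_", config$parties)]
    for (pt in config$parties)
      est[m, "unadjusted", pt] <- mean(y[[paste0("vote_", pt)]])
    for (a in names(config$estimators)) {
      spec <- config$estimators[[a]]
      spec$seed <- substream_seed(config$master_seed, paste0("fit_", a), m)
      fit <- tryCatch(fit_propensity(smp, spec),
                      error = function(e)
                        stop("replication ", m, ", estimator ", a, ": ",
                             conditionMessage(e), call. = FALSE))
      w <- if (config$weighting == "hajek") {
        p_vol <- clip_propensities(fit$propensities)[smp$z == 1L]
        hajek_weights(p_vol)
      } else {
        cl <- stratify_by_propensity(smp, clip_propensities(fit$propensities),
                                     config$n_classes)
        ht_class_weights(smp, cl)
      }
      for (pt in config$parties)
        est[m, a, pt] <- weighted_proportion(y[[paste0("vote_", pt)]], w)
    }
  }

  summary <- do.call(rbind, lapply(config$parties, function(pt) {
    do.call(rbind, lapply(arms, function(a) {
      e <- est[, a, pt]
      data.frame(scheme = config$scheme, algorithm = a,
                 weighting = config$weighting,
                 n_vs = config$n_vs, n_rs = config$n_rs,
                 party = pt, truth = unname(truth[pt]),
                 mean_estimate = mean(e),
                 bias = estimate_bias(e, truth[pt]),
                 mse = if (config$reps >= 2L)
                   estimate_mse(e, truth[pt]) else NA_real_)
    }))
  }))
  rownames(summary) <- NULL
  structure(list(config = config, truth = truth, estimates = est,
                 summary = summary),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Scenario:", x$config$scheme, "convenience sampling, n_vs =",
      x$config$n_vs, ", n_rs =", x$config$n_rs, ",", x$config$reps,
      "replications,", x$config$weighting, "weighting\n\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Tune estimator hyperparameters by repeated cross-validated log-loss
#'
#' Repeated k-fold cross-validation of each candidate specification on
#' the combined sample, scored by the mean Bernoulli log-loss of the
#' out-of-fold propensities against the membership indicator,
#' -(1/n) sum(z log p + (1 - z) log(1 - p)), with predictions clipped
#' to (1e-15, 1 - 1e-15). The grid point with the smallest mean
#' log-loss wins; ties go to the earlier grid entry.
#'
#' @param sample A [combine_samples()] result.
#' @param grid List of [propensity_spec()] candidates (e.g. from
#'   [propensity_grid()]).
#' @param folds Number of folds (default 10).
#' @param repeats Number of random fold assignments (default 10).
#' @param seed Integer seed for the fold assignments.
#' @return List with `best` (the winning spec), `best_logloss`, and
#'   `results`, a data frame of mean log-loss per grid point.
#' @export
tune_cv <- function(sample, grid, folds = 10L, repeats = 10L, seed = 1L) {
  stopifnot(inherits(sample, "combined_sample"))
  if (!length(grid)) stop("`grid` is empty", call. = FALSE)
  if (inherits(grid, "propensity_spec")) grid <- list(grid)
  n <- sample$n
  if (n < folds) stop("fewer units than folds", call. = FALSE)
  losses <- matrix(NA_real_, nrow = length(grid), ncol = repeats)
  for (r in seq_len(repeats)) {
    fold <- with_seed(substream_seed(seed, "cv_fold", r),
                      sample(rep_len(seq_len(folds), n)))
    for (g in seq_along(grid)) {
      ll <- 0
      for (f in seq_len(folds)) {
        test <- fold == f
        sub <- subset_combined(sample, !test)
        fit <- fit_propensity(sub, grid[[g]])
        p <- predict(fit, sample$data[test, , drop = FALSE])
        p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
        zt <- sample$z[test]
        ll <- ll - sum(zt * log(p) + (1 - zt) * log(1 - p))
      }
      losses[g, r] <- ll / n
    }
  }
  mean_ll <- rowMeans(losses)
  best <- which.min(mean_ll) # which.min takes the first minimum: grid order
  results <- data.frame(
    grid_point = seq_along(grid),
    algorithm = vapply(grid, `[[`, "", "algorithm"),
    hyperparameters = vapply(grid, function(s)
      paste(names(s$hyperparameters), unlist(s$hyperparameters),
            sep = "=", collapse = ", "), ""),
    mean_logloss = mean_ll)
  list(best = grid[[best]], best_logloss = mean_ll[best], results = results)
}

# restrict a combined sample to a logical row subset, keeping the
# encoder (category sets and scaling ranges) of the full sample
subset_combined <- function(sample, keep) {
  z <- sample$z[keep]
  if (length(unique(z)) < 2L)
    stop("degenerate sample: both z = 0 and z = 1 units are required",
         call. = FALSE)
  structure(list(data = sample$data[keep, , drop = FALSE],
                 x = sample$x[keep, , drop = FALSE],
                 z = z, d = sample$d[keep],
                 n = sum(keep), n_vs = sum(z), n_rs = sum(z == 0L),
                 encoder = sample$encoder),
            class = "combined_sample")
}
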