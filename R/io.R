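# Tabular I/O: one dialect everywhere — comma-separated, UTF-8, header
# row, booleans encoded 0/1.

#' Read a CSV with schema checking
#'
#' @param path Path to a comma-separated file with a header row.
#' @param schema Optional named character vector mapping column names
#'   to types among `"numeric"`, `"categorical"`, `"boolean"`; listed
#'   columns must exist and are coerced (booleans from 0/1 or
#'   TRUE/FALSE), unlisted columns are left as read.
#' @return A data frame.
#' @export
load_tabular <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty input file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no data rows in ", path, call. = FALSE)
  for (col in names(schema)) {
    if (!col %in% names(df))
      stop("missing column `", col, "` in ", path, call. = FALSE)
    df[[col]] <- switch(schema[[col]],
      numeric = {
        v <- suppressWarnings(as.numeric(df[[col]]))
        if (anyNA(v) && !anyNA(df[[col]])) {
          bad <- which(is.na(v))[1]
          stop("unparseable numeric value in column `", col, "`, data row ",
               bad, " of ", path, call. = FALSE)
        }
        v
      },
      categorical = factor(df[[col]]),
      boolean = {
        raw <- as.character(df[[col]])
        v <- rep(NA, length(raw))
        v[raw %in% c("1", "TRUE", "true")] <- TRUE
        v[raw %in% c("0", "FALSE", "false")] <- FALSE
        if (anyNA(v)) {
          bad <- which(is.na(v))[1]
          stop("unparseable boolean value in column `", col, "`, data row ",
               bad, " of ", path, call. = FALSE)
        }
        v
      },
      stop("unknown schema type: ", schema[[col]], call. = FALSE))
  }
  df
}

population_schema <- c(age = "numeric", gender = "categorical",
                       nationality = "categorical", education = "categorical",
                       internet = "boolean", vote_p1 = "boolean",
                       vote_p2 = "boolean", vote_p3 = "boolean")

#' Write / read a simulated population as CSV
#'
#' Booleans are written as 0/1; [read_population()] restores the factor
#' levels and logical columns, so a round trip reproduces the table.
#'
#' @param pop A population from [generate_population()].
#' @param path Output (input) CSV path.
#' @return `write_population` the path, invisibly; `read_population`
#'   the population table.
#' @export
write_population <- function(pop, path) {
  out <- as.data.frame(pop)
  for (col in names(out)) if (is.logical(out[[col]]))
    out[[col]] <- as.integer(out[[col]])
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  df <- load_tabular(path, population_schema)
  df$gender <- factor(df$gender, levels = c("female", "male"))
  df$nationality <- factor(df$nationality, levels = c("native", "non-native"))
  df$education <- factor(df$education,
                         levels = c("primary", "secondary", "higher"))
  class(df) <- c("psa_population", "data.frame")
  df
}

#' Export fitted propensities or PSA weights as CSV
#'
#' @param fit A [fit_propensity()] result.
#' @param sample The [combine_samples()] result it was fitted on.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_propensities <- function(fit, sample, path) {
  p <- fit$propensities
  write.csv(data.frame(id = seq_along(p), z = sample$z,
                       propensity_raw = p,
                       propensity_clipped = as.numeric(clip_propensities(p))),
            path, row.names = FALSE)
  invisible(path)
}

#' @param weights A `psa_weights` object over the volunteer units.
#' @rdname write_propensities
#' @export
write_weights <- function(weights, path) {
  write.csv(data.frame(volunteer_id = seq_along(weights$w),
                       method = weights$method, w = weights$w),
            path, row.names = FALSE)
  invisible(path)
}

#' PSA weighting of two external samples (generic mode)
#'
#' The end-to-end adjustment for user-supplied data: stacks a volunteer
#' data frame and a reference data frame sharing covariate columns,
#' fits the requested propensity estimator, reweights the volunteer
#' units and (optionally) estimates the mean of a target column
#' measured only on the volunteer sample.
#'
#' @param volunteer,reference Data frames sharing `covariates`.
#' @param covariates Character vector of covariate column names.
#' @param target Optional name of the volunteer-only outcome column
#'   (binary or numeric).
#' @param reference_weights Optional name of a design-weight column of
#'   `reference`; by default every reference unit gets the same weight.
#' @param spec A [propensity_spec()] (default: logistic regression).
#' @param weighting `"hajek"` (default) or `"ht_class"`.
#' @param n_classes Propensity classes for `"ht_class"`.
#' @return List with `weights` (a `psa_weights`), `fit`, `sample`, and
#'   `estimate` (NULL when no target is given).
#' @export
psa_weight <- function(volunteer, reference, covariates, target = NULL,
                       reference_weights = NULL,
                       spec = propensity_spec("logistic"),
                       weighting = c("hajek", "ht_class"), n_classes = 5L) {
  weighting <- match.arg(weighting)
  d_ref <- if (is.null(reference_weights)) {
    rep(1, nrow(reference))
  } else {
    if (!reference_weights %in% names(reference))
      stop("missing design-weight column `", reference_weights, "`",
           call. = FALSE)
    w <- reference[[reference_weights]]
    if (any(!is.finite(w) | w <= 0))
      stop("design weights must be positive", call. = FALSE)
    w
  }
  ref <- as_psa_sample(reference, "reference", d_ref)
  vol <- as_psa_sample(volunteer, "volunteer")
  smp <- combine_samples(ref, vol, covariates)
  fit <- fit_propensity(smp, spec)
  p <- clip_propensities(fit$propensities)
  weights <- if (weighting == "hajek") {
    hajek_weights(p[smp$z == 1L])
  } else {
    ht_class_weights(smp, stratify_by_propensity(smp, p, n_classes))
  }
  estimate <- NULL
  if (!is.null(target)) {
    if (!target %in% names(volunteer))
      stop("missing target column `", target, "` in the volunteer sample",
           call. = FALSE)
    estimate <- weighted_proportion(volunteer[[target]], weights)
  }
  list(weights = weights, fit = fit, sample = smp, estimate = estimate)
}

#' Deterministic toy datasets for examples and oracle tests
#'
#' \describe{
#'   \item{`toy_combined`}{12-unit combined sample (6 volunteer, 6
#'     reference) with one binary factor covariate, the setting of the
#'     exhaustive k-NN and naive-Bayes hand computations.}
#'   \item{`toy_separable`}{combined sample with two pure covariate
#'     cells: every volunteer has `x = "a"`, every reference unit
#'     `x = "b"`.}
#'   \item{`mini_population`}{`generate_population(2000, seed)`.}
#' }
#'
#' @param kind One of `"toy_combined"`, `"toy_separable"`,
#'   `"mini_population"`.
#' @param seed Integer seed.
#' @return A `combined_sample` for the toy kinds, a population table
#'   for `mini_population`.
#' @export
make_fixture <- function(kind = c("toy_combined", "toy_separable",
                                  "mini_population"), seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "mini_population") return(generate_population(2000L, seed))
  if (kind == "toy_combined") {
    xlev <- with_seed(seed, sample(rep(c("a", "b"), 6)))
    df <- data.frame(x = factor(xlev, levels = c("a", "b")))
    ref <- new_psa_sample(df[1:6, , drop = FALSE], 1:6, rep(1, 6), "reference")
    vol <- new_psa_sample(df[7:12, , drop = FALSE], 7:12, rep(1, 6), "volunteer")
    return(combine_samples(ref, vol, "x"))
  }
  df <- data.frame(x = factor(rep(c("b", "a"), each = 6),
                              levels = c("a", "b")))
  ref <- new_psa_sample(df[1:6, , drop = FALSE], 1:6, rep(1, 6), "reference")
  vol <- new_psa_sample(df[7:12, , drop = FALSE], 7:12, rep(1, 6), "volunteer")
  combine_samples(ref, vol, "x")
}

#' Write a scenario summary as long-format CSV
#'
#' @param result A [run_scenario()] result.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_scenario_csv <- function(result, path) {
  stopifnot(inherits(result, "scenario_result"))
  write.csv(result$summary, path, row.names = FALSE)
  invisible(path)
}
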