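#' Specify a propensity estimator
#'
#' Bundles an algorithm name, its hyperparameters and a seed into a
#' specification consumed by [fit_propensity()] and [tune_cv()].
#' Hyperparameters not supplied take the first value of the reference
#' tuning grid (see [propensity_grid()]):
#' \describe{
#'   \item{logistic}{no hyperparameters.}
#'   \item{tree}{`impurity` ("entropy" ~ C4.5/C5.0, "gini" ~ CART),
#'     `prune_confidence` in \{0.1, 0.25, 0.5\}, `min_node_fraction` in
#'     \{0.005, 0.01, 0.05\}.}
#'   \item{knn}{`k` in \{3, 5, 7, 9, 11, 13\}.}
#'   \item{naive_bayes}{`laplace` in \{0, 1, 2, 5, 10\}.}
#'   \item{random_forest}{`n_trees` (500 in the reference setting),
#'     `mtry` in \{1, 2, 4\}.}
#'   \item{gbm}{`interaction_depth` in \{4, 6, 8\}, `learning_rate` in
#'     \{0.1, 0.01, 0.001\}, plus `n_trees` (default 100) and
#'     `bag_fraction` (default 0.5).}
#' }
#'
#' @param algorithm One of `"logistic"`, `"tree"`, `"knn"`,
#'   `"naive_bayes"`, `"random_forest"`, `"gbm"`.
#' @param ... Hyperparameter overrides, by name.
#' @param seed Integer seed consumed by stochastic fits (forest, gbm);
#'   deterministic algorithms ignore it.
#' @return A `propensity_spec` object.
#' @export
propensity_spec <- function(algorithm = c("logistic", "tree", "knn",
                                          "naive_bayes", "random_forest", "gbm"),
                            ..., seed = 1L) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    logistic = list(),
    tree = list(impurity = "entropy", prune_confidence = 0.25,
                min_node_fraction = 0.01),
    knn = list(k = 3L),
    naive_bayes = list(laplace = 0),
    random_forest = list(n_trees = 500L, mtry = 1L),
    gbm = list(interaction_depth = 4L, learning_rate = 0.1,
               n_trees = 100L, bag_fraction = 0.5))
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    stop("unknown hyperparameter(s) for ", algorithm, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  hp <- utils::modifyList(defaults, override)
  structure(list(algorithm = algorithm, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "propensity_spec")
}

#' @export
print.propensity_spec <- function(x, ...) {
  hp <- x$hyperparameters
  cat("Propensity estimator:", x$algorithm,
      if (length(hp)) paste0("(", paste(names(hp), unlist(hp), sep = " = ",
                                        collapse = ", "), ")") else "",
      "\n")
  invisible(x)
}

#' Reference hyperparameter grid of one algorithm
#'
#' Expands the reference tuning grid of one algorithm into a list of
#' [propensity_spec()] objects, as consumed by [tune_cv()]. For the
#' random forest, `mtry_relative = TRUE` switches the candidate values
#' from \{1, 2, 4\} to \{sqrt(p), p/2, p\} for `p` covariate columns.
#'
#' @inheritParams propensity_spec
#' @param p Number of encoded covariate columns (needed for
#'   `mtry_relative`).
#' @param mtry_relative Use the dimension-relative forest grid.
#' @param seed Seed attached to every grid point.
#' @return List of `propensity_spec` objects.
#' @export
propensity_grid <- function(algorithm, p = NULL, mtry_relative = FALSE,
                            seed = 1L) {
  grid <- switch(algorithm,
    logistic = list(list()),
    tree = expand.grid(impurity = c("entropy", "gini"),
                       prune_confidence = c(0.1, 0.25, 0.5),
                       min_node_fraction = c(0.005, 0.01, 0.05),
                       stringsAsFactors = FALSE),
    knn = expand.grid(k = c(3L, 5L, 7L, 9L, 11L, 13L)),
    naive_bayes = expand.grid(laplace = c(0, 1, 2, 5, 10)),
    random_forest = if (mtry_relative) {
      if (is.null(p)) stop("`p` is required when mtry_relative = TRUE",
                           call. = FALSE)
      expand.grid(mtry = unique(pmax(1L, round(c(sqrt(p), p / 2, p)))))
    } else expand.grid(mtry = c(1L, 2L, 4L)),
    gbm = expand.grid(interaction_depth = c(4L, 6L, 8L),
                      learning_rate = c(0.1, 0.01, 0.001)),
    stop("unknown algorithm: ", algorithm, call. = FALSE))
  if (algorithm == "logistic")
    return(list(propensity_spec("logistic", seed = seed)))
  lapply(seq_len(nrow(grid)), function(i) {
    do.call(propensity_spec,
            c(list(algorithm = algorithm, seed = seed),
              as.list(grid[i, , drop = FALSE])))
  })
}

#' Fit a propensity estimator on the combined sample
#'
#' Dispatches to the requested algorithm and returns both the fitted
#' model and the in-sample participation propensities, the estimated
#' probabilities that each unit of the stacked sample belongs to the
#' volunteer sample given its covariates. The fit is deterministic
#' given `(sample, spec)` including `spec$seed`. Base design weights do
#' not enter the fit; they are used only at the weighting stage.
#'
#' @param sample A [combine_samples()] result.
#' @param spec A [propensity_spec()].
#' @return A `psa_propensity_fit`: list with `spec`, `model`, and
#'   `propensities` (raw, in \[0, 1\], aligned with the sample rows).
#' @export
fit_propensity <- function(sample, spec) {
  stopifnot(inherits(sample, "combined_sample"),
            inherits(spec, "propensity_spec"))
  if (length(unique(sample$z)) < 2L)
    stop("degenerate sample: both z = 0 and z = 1 units are required",
         call. = FALSE)
  hp <- spec$hyperparameters
  fit <- switch(spec$algorithm,
    logistic = engine_logistic(sample),
    tree = engine_tree(sample, hp$impurity, hp$prune_confidence,
                       hp$min_node_fraction),
    knn = engine_knn(sample, hp$k),
    naive_bayes = engine_nb(sample, hp$laplace),
    random_forest = engine_forest(sample, hp$n_trees, hp$mtry, spec$seed),
    gbm = engine_gbm(sample, hp$interaction_depth, hp$learning_rate,
                     hp$n_trees, hp$bag_fraction, spec$seed))
  structure(list(spec = spec, model = fit$model,
                 propensities = fit$propensities,
                 encoder = sample$encoder),
            class = "psa_propensity_fit")
}

#' @export
print.psa_propensity_fit <- function(x, ...) {
  print(x$spec)
  cat("In-sample propensities: n =", length(x$propensities),
      " range [", format(min(x$propensities), digits = 4), ",",
      format(max(x$propensities), digits = 4), "]\n")
  invisible(x)
}

#' Predict participation propensities for new units
#'
#' @param object A [fit_propensity()] result.
#' @param newdata Data frame with the covariate columns of the training
#'   sample (raw, not encoded).
#' @param ... Unused.
#' @return Vector of propensities in \[0, 1\].
#' @export
predict.psa_propensity_fit <- function(object, newdata, ...) {
  x <- encode_covariates(object$encoder, newdata)
  predict_engine(object$model, x, newdata)
}

# ---- clipping ------------------------------------------------------------

#' Pull propensities away from 0 and 1
#'
#' Applies the transformation (1000 x + 0.5) / 1001, mapping \[0, 1\]
#' into (0, 1) while leaving 0.5 fixed. Hajek-type inverse-odds weights
#' are undefined at propensity 0 or 1, which tree-based estimators
#' produce readily; clipping makes every propensity usable.
#'
#' @param p Numeric vector of raw propensities in \[0, 1\].
#' @return The clipped vector, with attribute `clipped = TRUE`.
#' @export
clip_propensities <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p))
    stop("propensities must lie in [0, 1]", call. = FALSE)
  structure((1000 * p + 0.5) / 1001, clipped = TRUE)
}

# ---- engines -------------------------------------------------------------
# Each engine returns list(model, propensities); predict_engine() scores
# new encoded rows. Raw (unencoded) rows are also passed for naive
# Bayes, which models the original categorical covariates directly.

predict_engine <- function(model, x, data) UseMethod("predict_engine")

engine_logistic <- function(sample) {
  x <- sample$x
  # drop constant columns, then let the pivoted QR in glm.fit handle
  # the aliasing that full one-hot encoding introduces
  keep <- apply(x, 2, function(col) diff(range(col)) > 0)
  xk <- cbind(`(intercept)` = 1, x[, keep, drop = FALSE])
  fit <- withCallingHandlers(
    glm.fit(xk, sample$z, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        warning("possible separation: propensities at machine 0/1; ",
                "clip before Hajek weighting", call. = FALSE)
      invokeRestart("muffleWarning")
    })
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  model <- structure(list(coef = coefs, keep = keep),
                     class = "psa_logistic")
  list(model = model, propensities = as.numeric(fit$fitted.values))
}

predict_engine.psa_logistic <- function(model, x, data) {
  eta <- cbind(1, x[, model$keep, drop = FALSE]) %*% model$coef
  as.numeric(1 / (1 + exp(-eta)))
}

engine_tree <- function(sample, impurity, prune_confidence,
                        min_node_fraction) {
  min_node <- max(1L, ceiling(min_node_fraction * sample$n))
  tree <- grow_tree(sample$x, sample$z, criterion = impurity,
                    min_node = min_node)
  tree <- prune_tree(tree, prune_confidence)
  model <- structure(list(tree = tree), class = "psa_tree_model")
  list(model = model, propensities = predict_tree(tree, sample$x))
}

predict_engine.psa_tree_model <- function(model, x, data) {
  predict_tree(model$tree, x)
}

engine_knn <- function(sample, k) {
  n <- sample$n
  if (k >= n) stop("`k` must be at most n - 1", call. = FALSE)
  xs <- scale_unit(sample$x, sample$x)
  d2 <- dist2_matrix(xs, xs)
  diag(d2) <- Inf # a unit is not its own neighbour
  prop <- knn_vote(d2, sample$z, k)
  model <- structure(list(x_train = sample$x, xs_train = xs,
                          z = sample$z, k = k),
                     class = "psa_knn")
  list(model = model, propensities = prop)
}

predict_engine.psa_knn <- function(model, x, data) {
  xs_new <- scale_unit(x, model$x_train)
  d2 <- dist2_matrix(xs_new, model$xs_train)
  knn_vote(d2, model$z, model$k)
}

# min-max scale numeric columns to [0,1] using the reference matrix's
# range; one-hot columns are already in [0,1] and their range is {0,1},
# so the same rule applies uniformly
scale_unit <- function(x, ref) {
  lo <- apply(ref, 2, min)
  hi <- apply(ref, 2, max)
  rng <- ifelse(hi > lo, hi - lo, 1)
  sweep(sweep(x, 2, lo, "-"), 2, rng, "/")
}

dist2_matrix <- function(a, b) {
  # squared Euclidean distances, rows of a vs rows of b
  outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
}

# exactly k neighbours; distance ties at the k-th neighbour are broken
# by lowest column (training-row) index, which is order()'s stable
# default, so the estimate never exceeds 1
knn_vote <- function(d2, z, k) {
  apply(d2, 1, function(di) mean(z[order(di)[seq_len(k)]]))
}

engine_nb <- function(sample, laplace) {
  if (laplace < 0) stop("`laplace` must be >= 0", call. = FALSE)
  data <- sample$data
  z <- sample$z
  prior1 <- mean(z)
  tables <- lapply(names(data), function(v) {
    col <- data[[v]]
    if (is.numeric(col)) {
      # Gaussian class-conditional; degenerate spread floored so a
      # constant-within-class covariate stays usable
      list(type = "numeric", name = v,
           mean = c(mean(col[z == 0]), mean(col[z == 1])),
           sd = pmax(c(sd(col[z == 0]), sd(col[z == 1])), 1e-9))
    } else {
      lev <- if (is.factor(col)) levels(col) else sort(unique(as.character(col)))
      chr <- as.character(col)
      cnt0 <- table(factor(chr[z == 0], levels = lev))
      cnt1 <- table(factor(chr[z == 1], levels = lev))
      L <- length(lev)
      list(type = "categorical", name = v, levels = lev,
           p0 = (as.numeric(cnt0) + laplace) / (sum(cnt0) + laplace * L),
           p1 = (as.numeric(cnt1) + laplace) / (sum(cnt1) + laplace * L))
    }
  })
  model <- structure(list(prior1 = prior1, tables = tables),
                     class = "psa_nb")
  list(model = model, propensities = predict_engine(model, NULL, data))
}

predict_engine.psa_nb <- function(model, x, data) {
  n <- nrow(data)
  log1 <- rep(log(model$prior1), n)
  log0 <- rep(log(1 - model$prior1), n)
  for (tb in model$tables) {
    col <- data[[tb$name]]
    if (tb$type == "numeric") {
      log0 <- log0 + dnorm(col, tb$mean[1], tb$sd[1], log = TRUE)
      log1 <- log1 + dnorm(col, tb$mean[2], tb$sd[2], log = TRUE)
    } else {
      i <- match(as.character(col), tb$levels)
      # a level unseen at training time contributes the smoothed mass
      # of an empty cell (or is skipped entirely when laplace = 0)
      p0 <- tb$p0[i]; p1 <- tb$p1[i]
      ok <- !is.na(p0) & p0 > 0 & !is.na(p1) & p1 > 0
      log0[ok] <- log0[ok] + log(p0[ok])
      log1[ok] <- log1[ok] + log(p1[ok])
    }
  }
  1 / (1 + exp(log0 - log1))
}
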