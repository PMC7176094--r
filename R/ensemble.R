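# Random forest and gradient boosting engines built on the in-package
# tree grower. Both consume the spec seed and keep no global RNG state.

engine_forest <- function(sample, n_trees, mtry, seed) {
  p <- ncol(sample$x)
  if (mtry < 1 || mtry > p)
    stop("`mtry` must lie in [1, ", p, "]", call. = FALSE)
  n <- sample$n
  z <- sample$z
  votes <- numeric(n)
  trees <- vector("list", n_trees)
  with_seed(seed, {
    for (j in seq_len(n_trees)) {
      rows <- sample.int(n, n, replace = TRUE)
      vars <- sort(sample.int(p, mtry)) # covariates sampled per tree
      tr <- grow_tree(sample$x[rows, vars, drop = FALSE], z[rows],
                      criterion = "gini", min_node = 1L)
      trees[[j]] <- list(tree = tr, vars = vars)
      # a tree votes 1 for units landing in a majority-volunteer leaf
      votes <- votes +
        (predict_tree(tr, sample$x[, vars, drop = FALSE]) >= 0.5)
    }
  })
  model <- structure(list(trees = trees, n_trees = n_trees),
                     class = "psa_forest")
  list(model = model, propensities = votes / n_trees)
}

predict_engine.psa_forest <- function(model, x, data) {
  votes <- numeric(nrow(x))
  for (tr in model$trees) {
    votes <- votes + (predict_tree(tr$tree, x[, tr$vars, drop = FALSE]) >= 0.5)
  }
  votes / model$n_trees
}

# Stochastic gradient boosting of depth-limited regression trees on the
# Bernoulli deviance. Each iteration fits a tree to the gradient
# residuals z - p on a random `bag_fraction` subsample and replaces the
# leaf means by the one-step Newton value sum(r) / sum(p (1 - p)),
# shrunk by the learning rate.
engine_gbm <- function(sample, interaction_depth, learning_rate, n_trees,
                       bag_fraction, seed) {
  if (learning_rate <= 0) stop("`learning_rate` must be > 0", call. = FALSE)
  if (n_trees < 0) stop("`n_trees` must be >= 0", call. = FALSE)
  n <- sample$n
  z <- sample$z
  pbar <- mean(z)
  f0 <- log(pbar / (1 - pbar))
  f <- rep(f0, n)
  trees <- vector("list", n_trees)
  deviance <- numeric(n_trees)
  min_node <- max(1L, min(10L, floor(n / 20)))
  with_seed(seed, {
    for (j in seq_len(n_trees)) {
      p <- 1 / (1 + exp(-f))
      r <- z - p
      bag <- sort(sample.int(n, max(2L, round(bag_fraction * n))))
      tr <- grow_tree(sample$x[bag, , drop = FALSE], r[bag],
                      criterion = "variance", min_node = min_node,
                      max_depth = interaction_depth)
      leaf_bag <- tree_leaf_of(tr, sample$x[bag, , drop = FALSE])
      num <- tapply(r[bag], leaf_bag, sum)
      den <- tapply(p[bag] * (1 - p[bag]), leaf_bag, sum)
      gamma <- rep(0, nrow(tr$nodes))
      gamma[as.integer(names(num))] <- as.numeric(num) / pmax(as.numeric(den), 1e-12)
      gamma <- pmin(pmax(gamma, -4), 4) # cap Newton steps in pure leaves
      leaf_all <- tree_leaf_of(tr, sample$x)
      f <- f + learning_rate * gamma[leaf_all]
      trees[[j]] <- list(tree = tr, gamma = gamma)
      pj <- 1 / (1 + exp(-f))
      pj <- pmin(pmax(pj, 1e-15), 1 - 1e-15)
      deviance[j] <- -2 * sum(z * log(pj) + (1 - z) * log(1 - pj))
    }
  })
  model <- structure(list(f0 = f0, learning_rate = learning_rate,
                          trees = trees, deviance = deviance),
                     class = "psa_gbm")
  list(model = model, propensities = 1 / (1 + exp(-f)))
}

predict_engine.psa_gbm <- function(model, x, data) {
  f <- rep(model$f0, nrow(x))
  for (tr in model$trees) {
    f <- f + model$learning_rate * tr$gamma[tree_leaf_of(tr$tree, x)]
  }
  1 / (1 + exp(-f))
}
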