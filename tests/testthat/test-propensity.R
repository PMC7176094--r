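test_that("every estimator returns in-range, deterministic propensities", {
  pop <- make_fixture("mini_population", seed = 6)
  ip <- pop[pop$internet, ]
  smp <- combine_samples(
    srswor(pop, 80, seed = 1),
    draw_convenience(ip, "srswor", 120, seed = 2),
    c("age", "gender", "nationality", "education"))
  specs <- list(
    propensity_spec("logistic"),
    propensity_spec("tree"),
    propensity_spec("knn", k = 5),
    propensity_spec("naive_bayes", laplace = 1),
    propensity_spec("random_forest", n_trees = 15, mtry = 2, seed = 3),
    propensity_spec("gbm", n_trees = 20, seed = 3))
  for (spec in specs) {
    p1 <- fit_propensity(smp, spec)$propensities
    p2 <- fit_propensity(smp, spec)$propensities
    expect_length(p1, smp$n)
    expect_true(all(p1 >= 0 & p1 <= 1))
    expect_identical(p1, p2) # bitwise determinism incl. stochastic fits
  }
  # degenerate membership
  all_vol <- smp
  all_vol$z <- rep(1L, smp$n)
  expect_error(fit_propensity(all_vol, specs[[1]]), "degenerate")
})

test_that("uninformative covariates give the volunteer base rate", {
  df <- data.frame(x = factor(rep("a", 6)))
  smp <- make_combined(df, df)
  for (spec in list(propensity_spec("logistic"),
                    propensity_spec("tree"),
                    propensity_spec("naive_bayes"),
                    propensity_spec("gbm", bag_fraction = 1, seed = 1))) {
    expect_equal(fit_propensity(smp, spec)$propensities, rep(0.5, 12),
                 tolerance = 1e-12)
  }
  # unbalanced: base rate n_vs / n
  smp2 <- make_combined(df[rep(1, 9), , drop = FALSE], df[1:3, , drop = FALSE])
  expect_equal(fit_propensity(smp2, propensity_spec("logistic"))$propensities,
               rep(0.25, 12), tolerance = 1e-9)
})

test_that("logistic propensities equal the closed-form 2x2 MLE", {
  # z=1: 30 at x=a, 10 at x=b; z=0: 10 at x=a, 30 at x=b
  smp <- binary_combined(ref_a = 10, ref_b = 30, vol_a = 30, vol_b = 10)
  p <- fit_propensity(smp, propensity_spec("logistic"))$propensities
  is_a <- smp$data$x == "a"
  expect_equal(unique(round(p[is_a], 10)), 0.75)
  expect_equal(unique(round(p[!is_a], 10)), 0.25)
  # score equation: mean propensity equals the volunteer share
  expect_equal(mean(p), smp$n_vs / smp$n, tolerance = 1e-8)
})

test_that("logistic recovers the sign of age-driven self-selection", {
  pop <- generate_population(20000, seed = 13)
  ip <- pop[pop$internet, ]
  smp <- combine_samples(
    srswor(pop, 500, seed = 4),
    draw_convenience(ip, "logit_linear", 2000, seed = 5),
    c("age", "gender", "nationality", "education"))
  fit <- fit_propensity(smp, propensity_spec("logistic"))
  expect_lt(fit$model$coef[["age"]], 0)
})

test_that("tree propensities are per-leaf volunteer fractions", {
  # stump data: x=a has 8 vol / 2 ref, x=b has 3 vol / 7 ref
  smp <- binary_combined(ref_a = 2, ref_b = 7, vol_a = 8, vol_b = 3)
  for (imp in c("gini", "entropy")) {
    p <- fit_propensity(smp, propensity_spec(
      "tree", impurity = imp, prune_confidence = 0.5,
      min_node_fraction = 0.05))$propensities
    # direct leaf-tally oracle
    is_a <- smp$data$x == "a"
    expect_equal(unique(p[is_a]), mean(smp$z[is_a]))
    expect_equal(unique(p[!is_a]), mean(smp$z[!is_a]))
  }
  # pure leaves reach raw 1 (and 0) on separable cells
  sep <- make_fixture("toy_separable")
  psep <- fit_propensity(sep, propensity_spec("tree"))$propensities
  expect_setequal(unique(psep), c(0, 1))
})

test_that("random forest votes are tree-share fractions", {
  smp <- binary_combined(ref_a = 2, ref_b = 7, vol_a = 8, vol_b = 3)
  p1 <- fit_propensity(smp, propensity_spec("random_forest", n_trees = 1,
                                            mtry = 1, seed = 4))$propensities
  expect_true(all(p1 %in% c(0, 1)))
  p5 <- fit_propensity(smp, propensity_spec("random_forest", n_trees = 5,
                                            mtry = 1, seed = 4))$propensities
  expect_true(all(p5 %in% seq(0, 1, by = 0.2)))
  expect_error(fit_propensity(smp, propensity_spec("random_forest", mtry = 9)),
               "mtry")
})

test_that("k-NN matches the exhaustive distance-sort oracle", {
  # 6 points on a line: volunteers at 0,1,2; reference at 10,11,12.
  # With k = 3 and self excluded, the third neighbour always crosses
  # clusters, so the exact values are 2/3 (volunteer side) and 1/3.
  smp <- make_combined(data.frame(v = c(10, 11, 12)),
                       data.frame(v = c(0, 1, 2)))
  p <- fit_propensity(smp, propensity_spec("knn", k = 3))$propensities
  expect_equal(p, c(1, 1, 1, 2, 2, 2) / 3)
  expect_equal(p, oracle_knn(smp$data$v, smp$z, 3))
  # k = n - 1: everyone else counted
  p_all <- fit_propensity(smp, propensity_spec("knn", k = 5))$propensities
  expect_equal(p_all, ifelse(smp$z == 1, 2 / 5, 3 / 5))
  expect_error(fit_propensity(smp, propensity_spec("knn", k = 6)), "k")
  # random small samples vs the O(n^2) oracle
  for (s in 1:20) {
    set.seed(700 + s)
    n1 <- sample(2:6, 1)
    n0 <- sample(2:6, 1)
    xs <- runif(n0 + n1)
    sm <- make_combined(data.frame(v = xs[seq_len(n0)]),
                        data.frame(v = xs[-seq_len(n0)]))
    for (k in c(1, 3, min(5, n0 + n1 - 1))) {
      expect_equal(
        fit_propensity(sm, propensity_spec("knn", k = k))$propensities,
        oracle_knn(sm$data$v, sm$z, k))
    }
  }
})

test_that("k-NN agrees with FNN on tie-free data", {
  set.seed(31)
  train <- data.frame(v = runif(40), w = runif(40))
  z <- rep(c(0L, 1L), each = 20)
  smp <- make_combined(train[z == 0, ], train[z == 1, ])
  fit <- fit_propensity(smp, propensity_spec("knn", k = 5))
  newdata <- data.frame(v = runif(10), w = runif(10))
  p_new <- predict(fit, newdata)
  # FNN neighbour indices on the identically scaled coordinates
  xs_train <- (as.matrix(smp$data) -
    matrix(apply(smp$x, 2, min), 40, 2, byrow = TRUE)) /
    matrix(apply(smp$x, 2, max) - apply(smp$x, 2, min), 40, 2, byrow = TRUE)
  xs_new <- (as.matrix(newdata) -
    matrix(apply(smp$x, 2, min), 10, 2, byrow = TRUE)) /
    matrix(apply(smp$x, 2, max) - apply(smp$x, 2, min), 10, 2, byrow = TRUE)
  idx <- FNN::get.knnx(xs_train, xs_new, k = 5)$nn.index
  expect_equal(p_new, rowMeans(matrix(smp$z[idx], nrow = 10)))
})

test_that("naive Bayes reproduces the hand Bayes computation", {
  # z=1: 6 at a, 4 at b; z=0: 2 at a, 8 at b; lambda = 0
  smp <- binary_combined(ref_a = 2, ref_b = 8, vol_a = 6, vol_b = 4)
  p <- fit_propensity(smp, propensity_spec("naive_bayes",
                                           laplace = 0))$propensities
  is_a <- smp$data$x == "a"
  expect_equal(unique(round(p[is_a], 12)), 0.75)
  expect_equal(unique(round(p[!is_a], 12)), 1 / 3)
  expect_equal(p, oracle_nb(as.character(smp$data$x), smp$z, 0))
  # smoothing matches the oracle on every lambda of the reference grid
  for (lam in c(1, 2, 5, 10)) {
    plam <- fit_propensity(smp, propensity_spec("naive_bayes",
                                                laplace = lam))$propensities
    expect_equal(plam, oracle_nb(as.character(smp$data$x), smp$z, lam))
  }
  # covariate independent of z: base rate for any lambda
  ind <- binary_combined(ref_a = 5, ref_b = 5, vol_a = 5, vol_b = 5)
  for (lam in c(0, 2)) {
    expect_equal(fit_propensity(ind, propensity_spec("naive_bayes",
                                                     laplace = lam))$propensities,
                 rep(0.5, 20))
  }
  # infinite-smoothing limit flattens the conditionals
  psat <- fit_propensity(smp, propensity_spec("naive_bayes",
                                              laplace = 1e9))$propensities
  expect_equal(psat, rep(0.5, 20), tolerance = 1e-8)
})

test_that("gbm contracts: null model, monotone deviance, separation", {
  sep <- make_fixture("toy_separable")
  p0 <- fit_propensity(sep, propensity_spec("gbm", n_trees = 0))$propensities
  expect_equal(p0, rep(0.5, 12))
  fit <- fit_propensity(sep, propensity_spec("gbm", n_trees = 50,
                                             learning_rate = 0.1,
                                             bag_fraction = 1, seed = 2))
  expect_true(all(diff(fit$model$deviance) <= 1e-9))
  deep <- fit_propensity(sep, propensity_spec("gbm", n_trees = 200,
                                              learning_rate = 0.1,
                                              bag_fraction = 1, seed = 2))
  expect_true(all(deep$propensities[sep$z == 1] > 0.9))
  expect_true(all(deep$propensities[sep$z == 0] < 0.1))
})

test_that("all estimators discriminate under informative selection", {
  pop <- generate_population(20000, seed = 17)
  ip <- pop[pop$internet, ]
  smp <- combine_samples(
    srswor(pop, 500, seed = 6),
    draw_convenience(ip, "logit_linear", 2000, seed = 7),
    c("age", "gender", "nationality", "education"))
  specs <- list(
    logistic = propensity_spec("logistic"),
    tree = propensity_spec("tree"),
    knn = propensity_spec("knn", k = 13),
    naive_bayes = propensity_spec("naive_bayes", laplace = 1),
    random_forest = propensity_spec("random_forest", n_trees = 50,
                                    mtry = 2, seed = 8),
    gbm = propensity_spec("gbm", n_trees = 50, seed = 8))
  for (nm in names(specs)) {
    p <- fit_propensity(smp, specs[[nm]])$propensities
    expect_gt(mean(p[smp$z == 1]), mean(p[smp$z == 0]))
  }
})

test_that("clipping maps [0,1] into (0,1), keeps 0.5, preserves order", {
  expect_equal(as.numeric(clip_propensities(0)), 0.5 / 1001)
  expect_equal(as.numeric(clip_propensities(1)), 1000.5 / 1001)
  expect_equal(as.numeric(clip_propensities(0.5)), 0.5)
  p <- seq(0, 1, by = 0.05)
  cp <- clip_propensities(p)
  expect_true(all(cp > 0 & cp < 1))
  expect_true(all(diff(cp) > 0))
  expect_true(attr(cp, "clipped"))
  expect_error(clip_propensities(c(0.2, 1.3)), "0, 1")
})

test_that("fitted models score held-out units consistently", {
  pop <- make_fixture("mini_population", seed = 21)
  ip <- pop[pop$internet, ]
  smp <- combine_samples(
    srswor(pop, 60, seed = 9),
    draw_convenience(ip, "srswor", 90, seed = 10),
    c("age", "gender", "education"))
  newdata <- pop[1:25, c("age", "gender", "education")]
  for (spec in list(propensity_spec("logistic"),
                    propensity_spec("tree"),
                    propensity_spec("knn", k = 7),
                    propensity_spec("naive_bayes", laplace = 1),
                    propensity_spec("random_forest", n_trees = 10, seed = 3),
                    propensity_spec("gbm", n_trees = 15, seed = 3))) {
    fit <- fit_propensity(smp, spec)
    p_new <- predict(fit, newdata)
    expect_length(p_new, 25)
    expect_true(all(p_new >= 0 & p_new <= 1))
    # scoring the training rows reproduces the in-sample values
    # (k-NN differs by design: in-sample excludes self)
    if (spec$algorithm != "knn")
      expect_equal(predict(fit, smp$data), fit$propensities)
  }
})
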