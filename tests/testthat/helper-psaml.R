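# Shared helpers: tiny combined samples built in code, and independent
# brute-force oracles for the k-NN and naive-Bayes estimators.

make_combined <- function(ref_df, vol_df, covariates = names(ref_df)) {
  combine_samples(as_psa_sample(ref_df, "reference"),
                  as_psa_sample(vol_df, "volunteer"),
                  covariates)
}

# combined sample with one binary factor covariate given per-cell counts
# (reference rows first, as combine_samples stacks them)
binary_combined <- function(ref_a, ref_b, vol_a, vol_b) {
  lv <- c("a", "b")
  ref <- data.frame(x = factor(c(rep("a", ref_a), rep("b", ref_b)), levels = lv))
  vol <- data.frame(x = factor(c(rep("a", vol_a), rep("b", vol_b)), levels = lv))
  make_combined(ref, vol)
}

# exhaustive k-NN oracle: squared distances, stable sort, exactly k
# neighbours, self excluded — independent of the package's vectorised path
oracle_knn <- function(x, z, k) {
  n <- length(z)
  vapply(seq_len(n), function(i) {
    d <- (x - x[i])^2
    d[i] <- Inf
    mean(z[order(d)[seq_len(k)]])
  }, numeric(1))
}

# hand naive-Bayes oracle for one categorical covariate with add-lambda
# smoothing, computed straight from the Bayes formula on counts
oracle_nb <- function(xchr, z, lambda) {
  lev <- sort(unique(xchr))
  L <- length(lev)
  n1 <- sum(z); n0 <- sum(z == 0)
  p1 <- (vapply(lev, function(l) sum(xchr == l & z == 1), 0) + lambda) /
    (n1 + lambda * L)
  p0 <- (vapply(lev, function(l) sum(xchr == l & z == 0), 0) + lambda) /
    (n0 + lambda * L)
  i <- match(xchr, lev)
  num <- (n1 / length(z)) * p1[i]
  den <- num + (n0 / length(z)) * p0[i]
  unname(num / den)
}

# binomial standard error of an observed proportion
binom_se <- function(p, n) sqrt(p * (1 - p) / n)
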