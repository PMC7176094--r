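#' Simple random sampling without replacement
#'
#' Draws a fixed-size SRSWOR reference sample. Each drawn unit carries
#' the design weight N/n, the inverse of its inclusion probability.
#'
#' @param table Data frame to sample from (typically a population from
#'   [generate_population()]).
#' @param n Sample size, `1 <= n <= nrow(table)`.
#' @param seed Integer seed.
#' @param label Sample label, `"reference"` (default) or `"volunteer"`;
#'   volunteer draws get base weight 1 instead of N/n.
#' @return A `psa_sample`: list with `data` (the drawn rows),
#'   `design_weights`, `label` and `rows` (original row indices).
#' @export
srswor <- function(table, n, seed, label = c("reference", "volunteer")) {
  label <- match.arg(label)
  N <- nrow(table)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n > N)
    stop("`n` must lie in [1, ", N, "]", call. = FALSE)
  n <- as.integer(n)
  idx <- with_seed(seed, sample.int(N, n))
  new_psa_sample(table[idx, , drop = FALSE], idx,
                 if (label == "reference") rep(N / n, n) else rep(1, n),
                 label)
}

#' Wrap an external data frame as a PSA sample
#'
#' For the generic mode, where the volunteer and reference datasets
#' come from files rather than from the simulator.
#'
#' @param data Data frame of units.
#' @param label `"reference"` or `"volunteer"`.
#' @param design_weights Positive per-unit design weights; defaults to
#'   1 for every unit (self-weighting).
#' @return A `psa_sample`.
#' @export
as_psa_sample <- function(data, label = c("reference", "volunteer"),
                          design_weights = NULL) {
  label <- match.arg(label)
  if (is.null(design_weights)) design_weights <- rep(1, nrow(data))
  if (length(design_weights) != nrow(data) ||
      any(!is.finite(design_weights) | design_weights <= 0))
    stop("design weights must be positive, one per unit", call. = FALSE)
  new_psa_sample(data, seq_len(nrow(data)), design_weights, label)
}

new_psa_sample <- function(data, rows, design_weights, label) {
  rownames(data) <- NULL
  structure(list(data = data, rows = rows,
                 design_weights = design_weights, label = label),
            class = "psa_sample")
}

#' @export
print.psa_sample <- function(x, ...) {
  cat(x$label, "sample:", nrow(x$data), "units, base weights in [",
      format(min(x$design_weights)), ",", format(max(x$design_weights)), "]\n")
  invisible(x)
}

#' Self-selection probability of a volunteer by age
#'
#' The two parametric self-selection mechanisms used to draw informative
#' convenience samples from the internet subpopulation:
#' \describe{
#'   \item{`logit_linear`}{pi(age) = 1 / (1 + exp(-1 + 0.05 age)),
#'     strictly decreasing in age;}
#'   \item{`logit_sine`}{pi(age) = 1 / (1 + exp(1 - sin(age / 20))),
#'     non-monotone in age.}
#' }
#'
#' @param age Numeric vector of ages in years.
#' @param scheme `"logit_linear"` or `"logit_sine"`.
#' @return Vector of probabilities in (0, 1).
#' @export
selection_probability <- function(age, scheme = c("logit_linear", "logit_sine")) {
  if (!is.numeric(age) || any(!is.finite(age)))
    stop("`age` must be finite numeric", call. = FALSE)
  scheme <- match.arg(scheme)
  switch(scheme,
         logit_linear = 1 / (1 + exp(-1 + 0.05 * age)),
         logit_sine   = 1 / (1 + exp(1 - sin(age / 20))))
}

#' Draw the volunteer convenience sample
#'
#' Draws a fixed-size convenience sample from the internet
#' subpopulation. Under `scheme = "srswor"` the draw is uniform; under
#' the two informative schemes units are drawn sequentially without
#' replacement with probability proportional to their self-selection
#' probability [selection_probability()] among the remaining units, one
#' realisation of fixed-size unequal self-selection. Volunteer base
#' weights are always 1: the design that generated a self-selected
#' sample is unknown in practice, which is the point of PSA.
#'
#' @param internet_table Data frame of internet-access units only.
#' @param scheme `"srswor"`, `"logit_linear"` or `"logit_sine"`.
#' @param n_vs Convenience sample size.
#' @param seed Integer seed.
#' @return A volunteer-labelled `psa_sample` with all design weights 1.
#' @export
draw_convenience <- function(internet_table,
                             scheme = c("srswor", "logit_linear", "logit_sine"),
                             n_vs, seed) {
  scheme <- match.arg(scheme)
  if ("internet" %in% names(internet_table) && !all(internet_table$internet))
    stop("`internet_table` must contain internet = TRUE rows only", call. = FALSE)
  N <- nrow(internet_table)
  if (!is.numeric(n_vs) || length(n_vs) != 1L || n_vs < 1 || n_vs > N)
    stop("`n_vs` must lie in [1, ", N, "]", call. = FALSE)
  n_vs <- as.integer(n_vs)
  if (scheme == "srswor") {
    smp <- srswor(internet_table, n_vs, seed, label = "volunteer")
    return(smp)
  }
  pi <- selection_probability(internet_table$age, scheme)
  idx <- with_seed(seed, sample.int(N, n_vs, replace = FALSE, prob = pi))
  new_psa_sample(internet_table[idx, , drop = FALSE], idx,
                 rep(1, n_vs), "volunteer")
}

# ---- covariate encoding --------------------------------------------------

# Encoder: fixed, sorted one-hot expansion of categorical covariates and
# pass-through of numeric ones, so every estimator consumes one common
# design matrix with a stable column order.
make_encoder <- function(data, covariates) {
  missing_cols <- setdiff(covariates, names(data))
  if (length(missing_cols))
    stop("covariate column(s) not found: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  specs <- lapply(covariates, function(v) {
    col <- data[[v]]
    if (is.numeric(col)) {
      list(name = v, type = "numeric",
           min = min(col), max = max(col))
    } else {
      lev <- if (is.factor(col)) levels(col) else sort(unique(as.character(col)))
      if (is.logical(col)) lev <- c("FALSE", "TRUE")
      list(name = v, type = "categorical", levels = lev)
    }
  })
  structure(list(covariates = covariates, specs = specs),
            class = "psa_encoder")
}

encode_covariates <- function(encoder, data) {
  parts <- lapply(encoder$specs, function(sp) {
    col <- data[[sp$name]]
    if (sp$type == "numeric") {
      m <- matrix(as.numeric(col), ncol = 1,
                  dimnames = list(NULL, sp$name))
      m
    } else {
      chr <- as.character(col)
      m <- vapply(sp$levels, function(l) as.numeric(chr == l),
                  numeric(length(chr)))
      if (length(chr) == 1L) m <- matrix(m, nrow = 1)
      colnames(m) <- paste0(sp$name, "=", sp$levels)
      m
    }
  })
  do.call(cbind, parts)
}

#' Stack the reference and volunteer samples
#'
#' Builds the combined modelling dataset: reference rows get membership
#' indicator z = 0, volunteer rows z = 1; base design weights are
#' carried over; categorical covariates are one-hot encoded (sorted
#' level order) and numeric covariates kept as-is, into one design
#' matrix shared by all propensity estimators.
#'
#' @param reference,volunteer `psa_sample` objects with the
#'   corresponding labels.
#' @param covariates Character vector of covariate column names present
#'   in both samples.
#' @return A `combined_sample`: list with `data` (stacked raw rows of
#'   the covariate columns), `x` (encoded matrix), `z`, `d`, `n`,
#'   `n_vs`, `n_rs` and the `encoder`.
#' @export
combine_samples <- function(reference, volunteer, covariates) {
  stopifnot(inherits(reference, "psa_sample"), inherits(volunteer, "psa_sample"))
  if (reference$label != "reference" || volunteer$label != "volunteer")
    stop("samples must be labelled reference and volunteer", call. = FALSE)
  if (nrow(volunteer$data) == 0L || nrow(reference$data) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  for (smp in list(reference, volunteer)) {
    miss <- setdiff(covariates, names(smp$data))
    if (length(miss))
      stop("missing covariate column(s) in ", smp$label, " sample: ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  data <- rbind(reference$data[, covariates, drop = FALSE],
                volunteer$data[, covariates, drop = FALSE])
  rownames(data) <- NULL
  z <- c(rep(0L, nrow(reference$data)), rep(1L, nrow(volunteer$data)))
  d <- c(reference$design_weights, volunteer$design_weights)
  encoder <- make_encoder(data, covariates)
  structure(list(data = data,
                 x = encode_covariates(encoder, data),
                 z = z, d = d,
                 n = length(z), n_vs = sum(z), n_rs = sum(z == 0L),
                 encoder = encoder),
            class = "combined_sample")
}

#' @export
print.combined_sample <- function(x, ...) {
  cat("Combined sample: n =", x$n, "(", x$n_rs, "reference +", x$n_vs,
      "volunteer ), ", ncol(x$x), "encoded covariate columns\n")
  invisible(x)
}
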