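#' Assign combined-sample units to propensity classes
#'
#' Sorts the combined sample by estimated propensity and cuts it at the
#' quantiles of the combined propensity distribution into `n_classes`
#' strata (five in the standard recommendation). Intervals are
#' right-closed, so boundary ties fall into the lower class; when fewer
#' distinct propensity values than classes exist, classes are merged
#' with a warning.
#'
#' @param sample A [combine_samples()] result.
#' @param p Propensity vector aligned with the sample rows.
#' @param n_classes Number of propensity classes, at least 2.
#' @return Integer vector of class labels in `1:n_classes` (possibly
#'   with gaps after merging), monotone in `p`.
#' @export
stratify_by_propensity <- function(sample, p, n_classes = 5L) {
  stopifnot(inherits(sample, "combined_sample"))
  if (length(p) != sample$n)
    stop("`p` must have one propensity per combined-sample unit", call. = FALSE)
  if (n_classes < 2L) stop("`n_classes` must be >= 2", call. = FALSE)
  if (sample$n < n_classes)
    stop("more classes than units", call. = FALSE)
  br <- unique(quantile(p, probs = seq(0, 1, length.out = n_classes + 1L),
                        names = FALSE))
  if (length(br) < 2L) {
    warning("all propensities identical: a single class is used",
            call. = FALSE)
    return(rep(1L, sample$n))
  }
  if (length(br) < n_classes + 1L)
    warning("fewer distinct propensity values than class boundaries: ",
            length(br) - 1L, " classes used", call. = FALSE)
  as.integer(cut(p, breaks = br, include.lowest = TRUE, right = TRUE))
}

#' Horvitz-Thompson-type propensity-class weights
#'
#' Inside each propensity class c, the adjustment factor is the ratio
#' of the class's share of the total reference design weight to its
#' share of the total volunteer base weight,
#' f_c = (sum of d over reference units in c / total reference d) /
#' (sum of d over volunteer units in c / total volunteer d),
#' and each volunteer unit in class c receives weight w = f_c d. The
#' construction conserves the total volunteer weight mass exactly. A
#' class missing one of the two sample types is merged with its
#' neighbour toward the centre of the class range, with a warning.
#'
#' @param sample A [combine_samples()] result.
#' @param classes Class labels from [stratify_by_propensity()].
#' @return A `psa_weights` object: list with `w` (one weight per
#'   volunteer unit, in sample order), `method = "ht_class"`, `classes`
#'   (possibly after merging), and per-class factors `f`.
#' @export
ht_class_weights <- function(sample, classes) {
  stopifnot(inherits(sample, "combined_sample"))
  if (length(classes) != sample$n)
    stop("`classes` must label every combined-sample unit", call. = FALSE)
  z <- sample$z
  d <- sample$d
  cl <- as.integer(factor(classes)) # compact labels, order preserved
  # merge classes that lack reference or volunteer units
  repeat {
    ok <- vapply(sort(unique(cl)), function(c) {
      any(z == 1L & cl == c) && any(z == 0L & cl == c)
    }, logical(1))
    if (all(ok)) break
    labs <- sort(unique(cl))
    bad <- labs[!ok][1]
    centre <- (min(labs) + max(labs)) / 2
    target <- if (bad <= centre) {
      cand <- labs[labs > bad]
      if (length(cand)) min(cand) else max(labs[labs < bad])
    } else {
      cand <- labs[labs < bad]
      if (length(cand)) max(cand) else min(labs[labs > bad])
    }
    if (length(labs) < 2L)
      stop("cannot form a propensity class containing both sample types",
           call. = FALSE)
    warning("propensity class ", bad, " lacks one sample type; merged ",
            "with class ", target, call. = FALSE)
    cl[cl == bad] <- target
    cl <- as.integer(factor(cl))
  }
  D_r <- sum(d[z == 0L])
  D_v <- sum(d[z == 1L])
  labs <- sort(unique(cl))
  f <- vapply(labs, function(c) {
    (sum(d[z == 0L & cl == c]) / D_r) / (sum(d[z == 1L & cl == c]) / D_v)
  }, numeric(1))
  names(f) <- labs
  w <- f[match(cl[z == 1L], labs)] * d[z == 1L]
  structure(list(w = unname(w), method = "ht_class", classes = cl,
                 f = f), class = "psa_weights")
}

#' Hajek-type inverse-odds weights
#'
#' Each volunteer unit with estimated participation propensity pi
#' receives weight w = (1 - pi) / pi. These weights adjust the
#' volunteer sample toward the population represented by the reference
#' sample. Propensities must lie strictly inside (0, 1); raw estimates
#' touching 0 or 1 (routine for tree-based estimators) must first pass
#' through [clip_propensities()].
#'
#' @param p_volunteer Propensities of the volunteer units only.
#' @return A `psa_weights` object with `w` and `method = "hajek"`.
#' @export
hajek_weights <- function(p_volunteer) {
  if (any(p_volunteer <= 0 | p_volunteer >= 1, na.rm = TRUE) ||
      anyNA(p_volunteer))
    stop("propensities must lie strictly in (0, 1); ",
         "apply clip_propensities() first", call. = FALSE)
  structure(list(w = (1 - p_volunteer) / p_volunteer, method = "hajek"),
            class = "psa_weights")
}

#' @export
print.psa_weights <- function(x, ...) {
  cat("PSA weights (", x$method, "): ", length(x$w), " volunteer units, ",
      "range [", format(min(x$w), digits = 4), ", ",
      format(max(x$w), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Weighted proportion estimator
#'
#' The normalised (ratio) estimator sum(w y) / sum(w), used for both
#' weighting schemes; with equal weights it reduces to the unadjusted
#' sample proportion, and it always stays inside the range of `y`.
#'
#' @param y Binary (0/1 or logical) outcome over the volunteer units.
#' @param weights A `psa_weights` object, or a positive numeric vector.
#' @return The estimated proportion.
#' @export
weighted_proportion <- function(y, weights) {
  w <- if (inherits(weights, "psa_weights")) weights$w else weights
  if (length(y) != length(w))
    stop("`y` and the weights must be aligned", call. = FALSE)
  sw <- sum(w)
  if (!is.finite(sw) || sw <= 0)
    stop("total weight must be positive", call. = FALSE)
  sum(w * as.numeric(y)) / sw
}
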