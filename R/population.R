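#' Generate the fictitious voter population
#'
#' Simulates a finite population of voters with four sociodemographic
#' covariates (age, gender, nationality, education), an internet-access
#' indicator, and voting intention for three fictitious parties. The
#' three parties encode three selection mechanisms with respect to an
#' internet-only volunteer sample: Party 1 depends only on gender, which
#' is independent of internet access (MCAR); Party 2 depends on age,
#' which drives internet access (MAR); Party 3 depends on internet
#' access itself (NMAR).
#'
#' The generator is fully specified:
#' \itemize{
#'   \item age = 82 x + 18 with x ~ Beta(2, 3), so age lies in
#'     \[18, 100\]; three age strata are used below: under 35,
#'     35 to 65, over 65;
#'   \item nationality: non-native with probability 0.15 / 0.10 / 0.025
#'     by age stratum;
#'   \item gender: male or female with equal probability, independent of
#'     everything else;
#'   \item education (primary / secondary / higher): 0.35 / 0.20 / 0.45
#'     under 35, 0.45 / 0.25 / 0.30 at 35 to 65, 0.80 / 0.10 / 0.10
#'     over 65;
#'   \item internet access: natives 0.90 / 0.70 / 0.50 by stratum,
#'     non-natives 0.20 / 0.10 / 0.00;
#'   \item vote_p1: Bernoulli(0.20) for females, never for males;
#'   \item vote_p2: Bernoulli(0 / 0.40 / 0.60) by age stratum;
#'   \item vote_p3: Bernoulli(0.10) without internet access, otherwise
#'     Bernoulli(0.60 / 0.40 / 0.20) by age stratum.
#' }
#' The three vote indicators are drawn independently per person.
#'
#' @param n_pop Population size (the default reproduces the reference
#'   setting of 50,000).
#' @param seed Integer seed; the same `(n_pop, seed)` pair always yields
#'   the identical table.
#' @return A `data.frame` of class `psa_population` with columns `age`
#'   (numeric), `gender`, `nationality`, `education` (factors),
#'   `internet`, `vote_p1`, `vote_p2`, `vote_p3` (logical), and
#'   attributes `n_pop` and `seed`.
#' @examples
#' pop <- generate_population(2000, seed = 1)
#' mean(pop$internet)
#' true_proportion(pop, "p2")
#' @export
generate_population <- function(n_pop = 50000, seed = 1L) {
  if (!is.numeric(n_pop) || length(n_pop) != 1L || is.na(n_pop) || n_pop < 1)
    stop("`n_pop` must be a single integer >= 1", call. = FALSE)
  n_pop <- as.integer(n_pop)

  pop <- with_seed(seed, {
    age <- 82 * rbeta(n_pop, 2, 3) + 18
    stratum <- age_stratum(age)
    s1 <- stratum == "under35"
    s2 <- stratum == "35to65"
    s3 <- stratum == "over65"

    p_nonnative <- ifelse(s1, 0.15, ifelse(s2, 0.10, 0.025))
    nationality <- ifelse(runif(n_pop) < p_nonnative, "non-native", "native")

    gender <- ifelse(runif(n_pop) < 0.5, "female", "male")

    edu_cum <- cbind(
      primary   = ifelse(s1, 0.35, ifelse(s2, 0.45, 0.80)),
      secondary = ifelse(s1, 0.55, ifelse(s2, 0.70, 0.90))
    )
    u <- runif(n_pop)
    education <- ifelse(u < edu_cum[, "primary"], "primary",
                 ifelse(u < edu_cum[, "secondary"], "secondary", "higher"))

    p_int <- ifelse(nationality == "native",
                    ifelse(s1, 0.90, ifelse(s2, 0.70, 0.50)),
                    ifelse(s1, 0.20, ifelse(s2, 0.10, 0.00)))
    internet <- runif(n_pop) < p_int

    vote_p1 <- gender == "female" & runif(n_pop) < 0.20
    p2 <- ifelse(s1, 0, ifelse(s2, 0.40, 0.60))
    vote_p2 <- runif(n_pop) < p2
    p3 <- ifelse(internet, ifelse(s1, 0.60, ifelse(s2, 0.40, 0.20)), 0.10)
    vote_p3 <- runif(n_pop) < p3

    data.frame(
      age = age,
      gender = factor(gender, levels = c("female", "male")),
      nationality = factor(nationality, levels = c("native", "non-native")),
      education = factor(education, levels = c("primary", "secondary", "higher")),
      internet = internet,
      vote_p1 = vote_p1, vote_p2 = vote_p2, vote_p3 = vote_p3
    )
  })

  attr(pop, "n_pop") <- n_pop
  attr(pop, "seed") <- as.integer(seed)
  class(pop) <- c("psa_population", "data.frame")
  pop
}

#' Age stratum of each unit
#'
#' The three age strata used throughout the simulator: under 35,
#' 35 to 65 (inclusive at both ends), over 65.
#'
#' @param age Numeric vector of ages in years.
#' @return Factor with levels `under35`, `35to65`, `over65`.
#' @export
age_stratum <- function(age) {
  factor(ifelse(age < 35, "under35", ifelse(age <= 65, "35to65", "over65")),
         levels = c("under35", "35to65", "over65"))
}

#' Finite-population truth of a party proportion
#'
#' Exact fraction of the generated population (or of its internet /
#' no-internet subdomain) intending to vote for one party. These
#' empirical truths are the targets against which [run_scenario()]
#' measures bias and MSE.
#'
#' @param pop A population table from [generate_population()] (or any
#'   data frame with the same vote/internet columns).
#' @param party One of `"p1"`, `"p2"`, `"p3"`.
#' @param domain `"all"` (default), `"internet"` or `"no_internet"`.
#' @return The exact proportion, a number in \[0, 1\].
#' @export
true_proportion <- function(pop, party = c("p1", "p2", "p3"),
                            domain = c("all", "internet", "no_internet")) {
  party <- match.arg(party)
  domain <- match.arg(domain)
  if (nrow(pop) == 0L) stop("population is empty", call. = FALSE)
  keep <- switch(domain,
                 all = rep(TRUE, nrow(pop)),
                 internet = pop$internet,
                 no_internet = !pop$internet)
  if (!any(keep)) stop("domain `", domain, "` is empty", call. = FALSE)
  mean(pop[[paste0("vote_", party)]][keep])
}

#' @export
print.psa_population <- function(x, ...) {
  cat("Simulated voter population:", nrow(x), "units,",
      sum(x$internet), "with internet access (seed ",
      attr(x, "seed"), ")\n", sep = " ")
  print(head(as.data.frame(x)), ...)
  invisible(x)
}
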