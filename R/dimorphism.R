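#' Descriptive summary of one measurement in one group
#'
#' @param values numeric vector of measurements (mm), at least two finite
#'   values.
#' @return A [group_summary] (n, mean, sample SD with n - 1 divisor, min,
#'   max). A zero spread yields a warning and a summary flagged degenerate:
#'   such a group cannot feed the Gaussian sectioning machinery.
#' @examples
#' summarize_group(c(36.2, 38.1, 41.0))
#' @export
summarize_group <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 values")
  if (any(!is.finite(values))) stop("all values must be finite")
  s <- stats::sd(values)
  out <- group_summary(length(values), mean(values), s,
                       min(values), max(values), check = s > 0)
  if (s <= 0) {
    warning("degenerate group: zero standard deviation")
    attr(out, "degenerate") <- TRUE
  }
  out
}

#' Adjusted Fisher-Pearson standardized skewness (G1)
#'
#' G1 = g1 * sqrt(n (n - 1)) / (n - 2) with g1 = m3 / m2^(3/2), the sample
#' moment ratio. This is the common statistics-package default and the form
#' used to screen each measurement group for asymmetry (|G1| < 1 taken as
#' low skewness).
#'
#' @param values numeric vector, at least 3 values with nonzero variance.
#' @return The skewness coefficient.
#' @examples
#' skewness(c(1, 1, 1, 7))  # 2
#' @export
skewness <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) stop("need at least 3 values")
  if (any(!is.finite(values))) stop("all values must be finite")
  d <- values - mean(values)
  m2 <- mean(d^2)
  if (m2 <= 0) stop("zero variance")
  g1 <- mean(d^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

test_result <- function(statistic, p_value, method) {
  stopifnot(is.finite(p_value), p_value >= 0, p_value <= 1)
  structure(list(statistic = statistic, p_value = p_value, method = method),
            class = "osteosex_test")
}

#' @export
print.osteosex_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g\n",
              x$method, x$statistic, x$p_value))
  invisible(x)
}

#' Normality and homogeneity-of-variance checks for a two-sex comparison
#'
#' Runs a Shapiro-Wilk test within each sex group and a mean-centred
#' Levene's test across the two groups, the screening battery applied to
#' each measurement before the sectioning and discriminant analyses.
#'
#' @param female,male numeric vectors (mm), each with at least 3 values.
#' @return A list with elements `shapiro_female`, `shapiro_male` and
#'   `levene`, each a test-result object with `statistic`, `p_value`,
#'   `method`. A group with zero spread is an error for Shapiro-Wilk; if
#'   both groups are constant Levene is returned flagged with `p_value` NA
#'   replaced by 1 and `degenerate = TRUE`.
#' @export
distribution_tests <- function(female, male) {
  female <- as.numeric(female); male <- as.numeric(male)
  if (length(female) < 3 || length(male) < 3) {
    stop("each group needs at least 3 values")
  }
  if (stats::sd(female) == 0 || stats::sd(male) == 0) {
    stop("constant group: Shapiro-Wilk is undefined")
  }
  swf <- stats::shapiro.test(female)
  swm <- stats::shapiro.test(male)
  values <- c(female, male)
  grp <- factor(rep(c("female", "male"), c(length(female), length(male))))
  lev <- car::leveneTest(values, grp, center = mean)
  lev_res <- test_result(lev[1, "F value"], lev[1, "Pr(>F)"],
                         "Levene (mean-centred)")
  list(shapiro_female = test_result(unname(swf$statistic), swf$p.value,
                                    "Shapiro-Wilk (female)"),
       shapiro_male = test_result(unname(swm$statistic), swm$p.value,
                                  "Shapiro-Wilk (male)"),
       levene = lev_res)
}

#' Mann-Whitney U test with tie-corrected normal approximation
#'
#' Computes the female-side U by midrank sums and the z approximation
#' z = (U - nf nm / 2) / sigma_U with the tie-corrected sigma_U and no
#' continuity correction; the two-sided p-value comes from the normal
#' distribution. z is negative when the female group tends lower, matching
#' the sign convention of the published comparison tables. For small groups
#' (both n <= 10) an exact p-value by complete enumeration over rank
#' assignments is available as a cross-check.
#'
#' @param female,male numeric vectors (mm), each nonempty.
#' @param exact if `TRUE` (and both groups have at most 10 values and no
#'   ties straddle groups), also compute the exact two-sided p-value by
#'   enumeration; returned as `p_exact`.
#' @return A test-result object with `statistic` (z), `p_value`, `method`,
#'   plus fields `u_female`, `u_male`, and optionally `p_exact`.
#' @examples
#' mann_whitney(c(33.1, 30.2, 35.9), c(38.0, 41.2, 37.4))
#' @export
mann_whitney <- function(female, male, exact = FALSE) {
  female <- as.numeric(female); male <- as.numeric(male)
  if (length(female) < 1 || length(male) < 1) stop("both groups must be nonempty")
  if (any(!is.finite(c(female, male)))) stop("all values must be finite")
  nf <- length(female); nm <- length(male); N <- nf + nm
  r <- rank(c(female, male))              # midranks for ties
  rf <- sum(r[seq_len(nf)])
  u_f <- rf - nf * (nf + 1) / 2
  u_m <- nf * nm - u_f
  ties <- table(c(female, male))
  tie_term <- sum(ties^3 - ties)
  sigma2 <- nf * nm / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) stop("all values tied: z statistic undefined")
  z <- (u_f - nf * nm / 2) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  out <- test_result(z, min(p, 1), "Mann-Whitney U (normal approx., tie-corrected)")
  out$u_female <- u_f
  out$u_male <- u_m
  if (exact && nf <= 10 && nm <= 10) {
    out$p_exact <- mann_whitney_exact_p(female, male, u_f)
  }
  out
}

# Exact two-sided p by enumeration of all choose(N, nf) group assignments of
# the observed midranks; valid with ties because the permutation distribution
# conditions on the observed rank multiset.
mann_whitney_exact_p <- function(female, male, u_obs) {
  nf <- length(female); nm <- length(male)
  r <- rank(c(female, male))
  combos <- utils::combn(nf + nm, nf)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - nf * (nf + 1) / 2)
  mu <- nf * nm / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}
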