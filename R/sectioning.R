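#' Gaussian sectioning point between two sex groups
#'
#' Fits one normal distribution per sex from the group summaries and takes
#' as cut-off the point where the two densities intersect between the two
#' means. For equal SDs this is the midpoint of the means; for unequal SDs
#' it is the admissible root of the quadratic obtained by equating
#' log-densities. When the variances are so unequal that no density
#' crossing lies between the means, the cut-off falls back to the point in
#' the closed interval between the means that maximises the D-value (the
#' two objectives coincide whenever an in-interval crossing exists, because
#' dD/dx0 is the difference of the two densities) and the result is
#' flagged. Values below the cut-off classify as female, values at or above
#' as male.
#'
#' @param female,male [group_summary] objects with `sd > 0` and different
#'   means. If the female mean exceeds the male mean the groups are swapped
#'   internally and the result is flagged `reversed`.
#' @param measurement optional label carried into the result.
#' @return An object of class `sectioning_result` with fields
#'   `measurement`, `cutoff`, `d_value`, `female`, `male`, `method`
#'   (`"density_intersection"` or `"dvalue_maximization"`), and `reversed`.
#' @examples
#' f <- group_summary(18, 18.83, 1.82, 16.08, 22.00)
#' m <- group_summary(14, 20.52, 1.39, 17.54, 22.37)
#' fit_cutoff(f, m)  # cut-off 19.41 mm
#' @export
fit_cutoff <- function(female, male, measurement = NA_character_) {
  check_summary_pair(female, male)
  reversed <- FALSE
  if (female$mean > male$mean) {
    tmp <- female; female <- male; male <- tmp
    reversed <- TRUE
  }
  if (female$mean == male$mean) stop("group means are equal: no discriminating cut-off")

  mf <- female$mean; sf <- female$sd
  mm <- male$mean; sm <- male$sd
  method <- "density_intersection"
  if (isTRUE(all.equal(sf, sm))) {
    x0 <- (mf + mm) / 2
  } else {
    # equate log-densities: quadratic a x^2 + b x + c = 0
    a <- 1 / sf^2 - 1 / sm^2
    b <- -2 * (mf / sf^2 - mm / sm^2)
    cc <- mf^2 / sf^2 - mm^2 / sm^2 + 2 * log(sf / sm)
    disc <- b^2 - 4 * a * cc
    roots <- if (disc >= 0) (-b + c(-1, 1) * sqrt(disc)) / (2 * a) else numeric(0)
    inside <- roots[roots > mf & roots < mm]
    if (length(inside) >= 1) {
      x0 <- inside[which.min(abs(inside - (mf + mm) / 2))]
    } else {
      opt <- stats::optimize(function(x) d_value(x, female, male),
                             interval = c(mf, mm), maximum = TRUE,
                             tol = 1e-10)
      x0 <- opt$maximum
      method <- "dvalue_maximization"
    }
  }
  structure(list(measurement = measurement,
                 cutoff = x0,
                 d_value = d_value(x0, female, male),
                 female = female, male = male,
                 method = method, reversed = reversed),
            class = "sectioning_result")
}

#' @export
print.sectioning_result <- function(x, ...) {
  cat(sprintf("sectioning_result%s: cut-off %.2f mm, D-value %.3f (%s%s)\n",
              if (is.na(x$measurement)) "" else paste0(" [", x$measurement, "]"),
              x$cutoff, x$d_value, x$method,
              if (x$reversed) ", polarity reversed" else ""))
  invisible(x)
}

#' D-value: area of non-overlap between two fitted normals
#'
#' D = F(x0; mean_f, sd_f^2) - F(x0; mean_m, sd_m^2), with F the normal
#' cumulative distribution function. At a cut-off between the means (female
#' mean lower) it measures the proportion of each distribution correctly
#' separated by the sectioning point; higher values indicate stronger
#' sexual dimorphism.
#'
#' @param x0 cut-off point (mm).
#' @param female,male [group_summary] objects with `sd > 0`.
#' @return A value in \[-1, 1\]; in \[0, 1\] whenever the female mean is
#'   below the male mean and `x0` lies between them.
#' @examples
#' f <- group_summary(18, 33.33, 4.53, 27.11, 42.93)
#' m <- group_summary(14, 38.22, 4.23, 31.42, 45.49)
#' d_value(35.87, f, m)  # 0.423
#' @export
d_value <- function(x0, female, male) {
  check_summary_pair(female, male)
  if (any(!is.finite(x0))) stop("x0 must be finite")
  stats::pnorm(x0, female$mean, female$sd) - stats::pnorm(x0, male$mean, male$sd)
}

check_summary_pair <- function(female, male) {
  for (g in list(female, male)) {
    if (!inherits(g, "group_summary")) stop("expected group_summary objects")
    if (!is.finite(g$sd) || g$sd <= 0) stop("group sd must be > 0")
  }
  invisible(TRUE)
}

#' Classify a measurement against a sectioning point
#'
#' @param value measurement in mm.
#' @param x0 cut-off point in mm.
#' @return `"female"` if `value < x0`, `"male"` if `value >= x0` (the
#'   boundary goes to male: only values strictly below the cut-off are
#'   female).
#' @export
classify_by_cutoff <- function(value, x0) {
  if (any(!is.finite(value)) || !is.finite(x0)) stop("inputs must be finite")
  ifelse(value < x0, "female", "male")
}

classification_report <- function(correct_f, n_f, correct_m, n_m,
                                  n_excluded = 0L) {
  structure(list(
    percent_correct_female = 100 * correct_f / n_f,
    percent_correct_male = 100 * correct_m / n_m,
    percent_correct_total = 100 * (correct_f + correct_m) / (n_f + n_m),
    n_female = n_f, n_male = n_m, n_excluded = n_excluded),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "classification_report: female %.1f%% (n=%d), male %.1f%% (n=%d), total %.1f%%%s\n",
    x$percent_correct_female, x$n_female,
    x$percent_correct_male, x$n_male, x$percent_correct_total,
    if (x$n_excluded > 0) sprintf(" [%d excluded]", x$n_excluded) else ""))
  invisible(x)
}

#' Evaluate a cut-off point on a dataset
#'
#' Applies [classify_by_cutoff] to every record with the measurement
#' present and tallies per-sex and total percent correct. The total is
#' case-weighted (pooled accuracy), not the mean of the two per-sex rates.
#' Records with the measurement absent are excluded and counted.
#'
#' @param dataset a [study_dataset].
#' @param measurement one of `"maxh"`, `"maxt"`, `"maxw"`.
#' @param x0 cut-off in mm.
#' @return A `classification_report` with per-sex and total percent
#'   correct, group sizes and the exclusion count.
#' @export
evaluate_cutoff <- function(dataset, measurement, x0) {
  stopifnot(inherits(dataset, "study_dataset"))
  measurement <- match.arg(tolower(measurement), MEASUREMENTS)
  vals <- dataset[[measurement]]
  usable <- !is.na(vals)
  n_excluded <- sum(!usable)
  sex <- as.character(dataset$sex)[usable]
  vals <- vals[usable]
  for (s in SEX_LEVELS) {
    if (sum(sex == s) == 0) stop("no usable records for sex: ", s)
  }
  pred <- classify_by_cutoff(vals, x0)
  classification_report(
    correct_f = sum(sex == "female" & pred == "female"),
    n_f = sum(sex == "female"),
    correct_m = sum(sex == "male" & pred == "male"),
    n_m = sum(sex == "male"),
    n_excluded = n_excluded)
}

#' Restrict a dataset to calcined patellae
#'
#' Calcined bone — burnt to complete combustion of organics — is selected
#' as burnt records with burn temperature of at least 800 degrees Celsius
#' and a white surface colour, the criterion used when comparing against
#' cut-offs from earlier cremation studies.
#'
#' @param dataset a [study_dataset].
#' @return The filtered [study_dataset]; empty with a warning when no
#'   record qualifies.
#' @export
filter_calcined <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  keep <- dataset$burn_state == "burnt" &
    !is.na(dataset$burn_temperature) & dataset$burn_temperature >= 800 &
    !is.na(dataset$burn_colour) & dataset$burn_colour == "white"
  out <- dataset[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no calcined records after filtering")
  rownames(out) <- NULL
  attr(out, "provenance") <- paste0(attr(dataset, "provenance"), " [calcined]")
  class(out) <- c("study_dataset", "data.frame")
  out
}
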