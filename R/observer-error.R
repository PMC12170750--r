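check_pairs <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stop("pairs must have exactly 2 replicates per subject")
  if (nrow(pairs) < 2) stop("need at least 2 subjects")
  if (any(!is.finite(pairs))) stop("all measurements must be finite")
  pairs
}

#' Technical error of measurement (TEM)
#'
#' TEM = sqrt(sum(d_i^2) / (2 n)) over n subjects, each measured twice,
#' with d_i the within-subject difference. The absolute (mm) index of
#' intra- or inter-observer measurement error.
#'
#' @param pairs two-column numeric matrix or data frame: one row per
#'   subject, the two replicate measurements in the columns.
#' @return TEM in the measurement's units.
#' @examples
#' tem(rbind(c(10.0, 10.2), c(20.0, 19.8)))  # 0.1414
#' @export
tem <- function(pairs) {
  pairs <- check_pairs(pairs)
  d <- pairs[, 1] - pairs[, 2]
  sqrt(sum(d^2) / (2 * nrow(pairs)))
}

#' Relative technical error of measurement (%TEM)
#'
#' 100 * TEM / grand mean of all replicate measurements; dimensionless, so
#' comparable across measurements of different size.
#'
#' @inheritParams tem
#' @return %TEM (percentage).
#' @export
percent_tem <- function(pairs) {
  pairs <- check_pairs(pairs)
  gm <- mean(pairs)
  if (gm <= 0) stop("grand mean must be positive")
  100 * tem(pairs) / gm
}

#' Coefficient of reliability (R)
#'
#' R = 1 - TEM^2 / s^2, with s^2 the sample variance (n - 1 divisor) of the
#' per-subject mean values. R near 1 indicates measurement error small
#' relative to between-subject variation; R can go negative when noise
#' swamps the between-subject signal.
#'
#' @inheritParams tem
#' @return The reliability coefficient (at most 1).
#' @export
reliability_r <- function(pairs) {
  pairs <- check_pairs(pairs)
  s2 <- stats::var(rowMeans(pairs))
  if (s2 <= 0) stop("zero between-subject variance")
  1 - tem(pairs)^2 / s2
}

#' Observer-error report for one measurement
#'
#' Convenience wrapper computing TEM, %TEM and R together, either from a
#' two-column pair matrix or from a long replicate table
#' (`subject_id, session, observer, measurement, value`) paired by session
#' (intra-observer) or by observer (inter-observer).
#'
#' @param pairs two-column matrix/data frame of duplicate measurements; or
#'   `NULL` when `replicates` is given.
#' @param replicates long-format data frame with columns `subject_id`,
#'   `session`, `observer`, `measurement`, `value`.
#' @param measurement which measurement to extract from `replicates`.
#' @param mode `"intra"` pairs the two sessions of one observer;
#'   `"inter"` pairs the two observers.
#' @return An object of class `reliability_report` with `tem`,
#'   `percent_tem`, `reliability_r`, `n_subjects`.
#' @export
observer_error <- function(pairs = NULL, replicates = NULL,
                           measurement = NULL, mode = c("intra", "inter")) {
  if (is.null(pairs)) {
    mode <- match.arg(mode)
    pairs <- pair_replicates(replicates, measurement, mode)
  }
  pairs <- check_pairs(pairs)
  structure(list(tem = tem(pairs),
                 percent_tem = percent_tem(pairs),
                 reliability_r = reliability_r(pairs),
                 n_subjects = nrow(pairs)),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf(
    "reliability_report: TEM %.3f mm, %%TEM %.2f, R %.4f (n = %d subjects)\n",
    x$tem, x$percent_tem, x$reliability_r, x$n_subjects))
  invisible(x)
}

pair_replicates <- function(replicates, measurement, mode) {
  stopifnot(is.data.frame(replicates))
  needed <- c("subject_id", "session", "observer", "measurement", "value")
  missing_cols <- setdiff(needed, names(replicates))
  if (length(missing_cols) > 0) {
    stop("replicates table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab <- replicates[tolower(replicates$measurement) == tolower(measurement), ]
  key <- if (mode == "intra") tab$session else tab$observer
  levels_key <- sort(unique(key))
  if (length(levels_key) != 2) {
    stop(sprintf("%s pairing needs exactly 2 %s levels, found %d", mode,
                 if (mode == "intra") "session" else "observer",
                 length(levels_key)))
  }
  a <- tab[key == levels_key[1], c("subject_id", "value")]
  b <- tab[key == levels_key[2], c("subject_id", "value")]
  merged <- merge(a, b, by = "subject_id")
  if (nrow(merged) < nrow(a) || nrow(merged) < nrow(b)) {
    warning(sprintf("%d subject(s) lacked both replicates and were dropped",
                    max(nrow(a), nrow(b)) - nrow(merged)))
  }
  as.matrix(merged[, c("value.x", "value.y")])
}
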