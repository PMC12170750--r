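#' Fit a two-group linear discriminant function
#'
#' Computes Fisher's linear discriminant for female vs male on the selected
#' measurements, in the unstandardized-coefficient convention common in
#' osteometric work: the direction is
#' `solve(pooled within-group covariance) %*% (male mean - female mean)`
#' (pooling divisor n - 2), rescaled so the pooled within-group variance of
#' the discriminant scores equals 1, with the constant set so that the
#' case-weighted average of the two group centroids is zero. Males score
#' higher by construction; the classification threshold is the midpoint of
#' the two centroids (equal priors).
#'
#' @param dataset a [study_dataset].
#' @param measurements character vector of measurement names (subset of
#'   `maxh`, `maxt`, `maxw`), the function's ordered variables. Cases
#'   incomplete on these are dropped (listwise) with a message.
#' @param burn_state optionally restrict to `"burnt"` or `"unburnt"`
#'   records before fitting.
#' @return An object of class `discriminant_model` with fields
#'   `measurements`, `coefficients`, `constant`, `centroid_female`,
#'   `centroid_male`, `threshold`, `group_sizes`, `n_dropped`.
#' @examples
#' d <- simulate_study(synthetic_config(seed = 7))
#' fit_lda(d, c("maxh", "maxt", "maxw"), burn_state = "unburnt")
#' @export
fit_lda <- function(dataset, measurements = MEASUREMENTS, burn_state = NULL) {
  stopifnot(inherits(dataset, "study_dataset"))
  measurements <- match.arg(tolower(measurements), MEASUREMENTS,
                            several.ok = TRUE)
  df <- as.data.frame(dataset)
  if (!is.null(burn_state)) df <- df[df$burn_state == burn_state, , drop = FALSE]
  X <- as.matrix(df[, measurements, drop = FALSE])
  complete <- stats::complete.cases(X)
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message(n_dropped, " incomplete case(s) dropped")
  }
  X <- X[complete, , drop = FALSE]
  sex <- as.character(df$sex)[complete]
  fit_lda_matrix(X, sex, measurements, n_dropped)
}

fit_lda_matrix <- function(X, sex, measurements, n_dropped = 0L) {
  nf <- sum(sex == "female"); nm <- sum(sex == "male")
  if (nf < 2 || nm < 2) stop("need at least 2 complete cases per sex")
  Xf <- X[sex == "female", , drop = FALSE]
  Xm <- X[sex == "male", , drop = FALSE]
  muf <- colMeans(Xf); mum <- colMeans(Xm)
  Sp <- (crossprod(sweep(Xf, 2, muf)) + crossprod(sweep(Xm, 2, mum))) /
    (nf + nm - 2)
  w <- tryCatch(solve(Sp, mum - muf), error = function(e) {
    stop("pooled within-group covariance is singular; ",
         "consider removing a measurement")
  })
  scale2 <- drop(t(w) %*% Sp %*% w)
  if (scale2 <= 0) stop("degenerate pooled covariance")
  w <- w / sqrt(scale2)                       # unit pooled score variance
  grand <- (nf * muf + nm * mum) / (nf + nm)  # case-weighted grand mean
  const <- -drop(crossprod(w, grand))
  cf <- drop(crossprod(w, muf)) + const
  cm <- drop(crossprod(w, mum)) + const
  structure(list(measurements = measurements,
                 coefficients = setNames(as.numeric(w), measurements),
                 constant = const,
                 centroid_female = cf, centroid_male = cm,
                 threshold = (cf + cm) / 2,
                 group_sizes = c(female = nf, male = nm),
                 n_dropped = as.integer(n_dropped)),
            class = "discriminant_model")
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat("discriminant_model (two-group LDA, unstandardized coefficients)\n")
  cat(sprintf("  Y = %s %+0.3f\n",
              paste(sprintf("(%s x %0.3f)", x$measurements, x$coefficients),
                    collapse = " + "), x$constant))
  cat(sprintf("  centroids: female %.3f, male %.3f (n = %d/%d); threshold %.3f\n",
              x$centroid_female, x$centroid_male,
              x$group_sizes["female"], x$group_sizes["male"], x$threshold))
  invisible(x)
}

#' Discriminant score of a measurement vector
#'
#' Y = sum(coefficient * value) + constant.
#'
#' @param model a `discriminant_model`.
#' @param values named numeric vector (or single-row data frame) complete
#'   on `model$measurements`.
#' @return The scalar score Y.
#' @export
score_lda <- function(model, values) {
  stopifnot(inherits(model, "discriminant_model"))
  if (is.data.frame(values)) values <- unlist(values[1, , drop = TRUE])
  v <- values[model$measurements]
  if (anyNA(v)) {
    stop("missing component(s): ",
         paste(model$measurements[is.na(v)], collapse = ", "))
  }
  drop(sum(model$coefficients * as.numeric(v)) + model$constant)
}

#' Classify a measurement vector with a discriminant model
#'
#' @inheritParams score_lda
#' @return `"male"` when the score exceeds the model threshold, `"female"`
#'   otherwise (scores exactly at the threshold go to female).
#' @export
classify_lda <- function(model, values) {
  y <- score_lda(model, values)
  # scores within rounding noise of the threshold count as the boundary
  tol <- 1e-9 * max(1, abs(model$threshold))
  if (y - model$threshold > tol) "male" else "female"
}

#' Leave-one-out cross-validated classification accuracy
#'
#' For each complete case the model is refitted on all remaining cases and
#' the held-out case classified; per-sex and total percent correct are
#' reported. Fully deterministic. A fold whose refit has a singular pooled
#' covariance is excluded with a warning.
#'
#' @inheritParams fit_lda
#' @return A `classification_report`.
#' @export
loocv_lda <- function(dataset, measurements = MEASUREMENTS, burn_state = NULL) {
  stopifnot(inherits(dataset, "study_dataset"))
  measurements <- match.arg(tolower(measurements), MEASUREMENTS,
                            several.ok = TRUE)
  df <- as.data.frame(dataset)
  if (!is.null(burn_state)) df <- df[df$burn_state == burn_state, , drop = FALSE]
  X <- as.matrix(df[, measurements, drop = FALSE])
  complete <- stats::complete.cases(X)
  X <- X[complete, , drop = FALSE]
  sex <- as.character(df$sex)[complete]
  n <- nrow(X)
  if (sum(sex == "female") < 3 || sum(sex == "male") < 3) {
    stop("need at least 3 complete cases per sex for LOOCV")
  }
  pred <- character(n)
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    m_i <- tryCatch(
      fit_lda_matrix(X[-i, , drop = FALSE], sex[-i], measurements),
      error = function(e) NULL)
    if (is.null(m_i)) {
      ok[i] <- FALSE
      next
    }
    pred[i] <- classify_lda(m_i, setNames(X[i, ], measurements))
  }
  if (any(!ok)) {
    warning(sum(!ok), " fold(s) excluded: singular refit")
  }
  sex <- sex[ok]; pred <- pred[ok]
  classification_report(
    correct_f = sum(sex == "female" & pred == "female"),
    n_f = sum(sex == "female"),
    correct_m = sum(sex == "male" & pred == "male"),
    n_m = sum(sex == "male"),
    n_excluded = sum(!ok) + sum(!complete))
}

#' Resubstitution (original) classification accuracy
#'
#' Classifies the training cases with the model fitted on all of them.
#'
#' @inheritParams fit_lda
#' @return A `classification_report`.
#' @export
resubstitution_lda <- function(dataset, measurements = MEASUREMENTS,
                               burn_state = NULL) {
  stopifnot(inherits(dataset, "study_dataset"))
  measurements <- match.arg(tolower(measurements), MEASUREMENTS,
                            several.ok = TRUE)
  df <- as.data.frame(dataset)
  if (!is.null(burn_state)) df <- df[df$burn_state == burn_state, , drop = FALSE]
  X <- as.matrix(df[, measurements, drop = FALSE])
  complete <- stats::complete.cases(X)
  X <- X[complete, , drop = FALSE]
  sex <- as.character(df$sex)[complete]
  model <- fit_lda_matrix(X, sex, measurements, sum(!complete))
  pred <- vapply(seq_len(nrow(X)),
                 function(i) classify_lda(model, setNames(X[i, ], measurements)),
                 character(1))
  classification_report(
    correct_f = sum(sex == "female" & pred == "female"),
    n_f = sum(sex == "female"),
    correct_m = sum(sex == "male" & pred == "male"),
    n_m = sum(sex == "male"),
    n_excluded = sum(!complete))
}
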