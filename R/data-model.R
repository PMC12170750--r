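#' @importFrom stats pnorm dnorm qnorm runif rbinom var sd complete.cases
#'   setNames uniroot optimize shapiro.test
#' @importFrom utils read.csv write.csv
NULL

MEASUREMENTS <- c("maxh", "maxt", "maxw")
SEX_LEVELS <- c("female", "male")
SIDE_LEVELS <- c("left", "right")
BURN_LEVELS <- c("unburnt", "burnt")
COLOUR_LEVELS <- c("white", "black", "other", "unknown")

DATASET_COLUMNS <- c("individual_id", "sex", "age_at_death", "side",
                     "burn_state", "burn_temperature", "burn_duration",
                     "burn_colour", MEASUREMENTS)
MANDATORY_COLUMNS <- c("individual_id", "sex", "side", "burn_state")

#' Construct a study dataset of patellar measurement records
#'
#' A `study_dataset` is a validated data frame with one row per measured
#' patella (an individual/side combination). Each row records the
#' individual's sex and age at death, the side, the burn state with its
#' metadata (temperature in Celsius, duration in minutes, surface colour),
#' and up to three measurements in millimetres: maximum height (`maxh`),
#' maximum thickness (`maxt`) and maximum width (`maxw`). Missing
#' measurements are `NA`, never zero.
#'
#' @param records data frame holding at least the mandatory columns
#'   `individual_id`, `sex`, `side`, `burn_state`; remaining columns are
#'   filled with `NA` when absent.
#' @param provenance free-text label describing where the records came from.
#' @return A data frame of class `study_dataset` with the full canonical
#'   column set and a `provenance` attribute.
#' @examples
#' d <- study_dataset(data.frame(
#'   individual_id = c("A", "B"), sex = c("female", "male"),
#'   side = "left", burn_state = "unburnt",
#'   maxh = c(36.2, 41.0), maxt = c(17.9, 20.1), maxw = c(37.5, 43.2)))
#' nrow(d)
#' @export
study_dataset <- function(records, provenance = "unspecified") {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(MANDATORY_COLUMNS, names(records))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in setdiff(DATASET_COLUMNS, names(out))) out[[col]] <- NA
  out <- out[, DATASET_COLUMNS, drop = FALSE]

  out$individual_id <- as.character(out$individual_id)
  out$sex <- normalise_sex(out$sex)
  out$side <- normalise_level(out$side, SIDE_LEVELS, "side")
  out$burn_state <- normalise_level(out$burn_state, BURN_LEVELS, "burn_state")
  colour <- tolower(trimws(as.character(out$burn_colour)))
  colour[is.na(colour) | colour == ""] <- "unknown"
  out$burn_colour <- normalise_level(colour, COLOUR_LEVELS, "burn_colour")
  out$age_at_death <- suppressWarnings(as.integer(out$age_at_death))
  out$burn_temperature <- suppressWarnings(as.numeric(out$burn_temperature))
  out$burn_duration <- suppressWarnings(as.numeric(out$burn_duration))
  for (m in MEASUREMENTS) out[[m]] <- suppressWarnings(as.numeric(out[[m]]))

  key <- paste(out$individual_id, as.character(out$side), sep = "/")
  if (anyDuplicated(key)) {
    stop("duplicate individual_id x side: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  for (m in MEASUREMENTS) {
    bad <- !is.na(out[[m]]) & (out[[m]] <= 0 | out[[m]] >= 100)
    if (any(bad)) {
      stop(sprintf("%s out of plausible range (0, 100) mm in row(s): %s",
                   m, paste(which(bad), collapse = ", ")))
    }
  }
  bad_t <- !is.na(out$burn_temperature) &
    (out$burn_temperature < 0 | out$burn_temperature > 1500)
  if (any(bad_t)) {
    stop("burn_temperature outside [0, 1500] C in row(s): ",
         paste(which(bad_t), collapse = ", "))
  }

  rownames(out) <- NULL
  attr(out, "provenance") <- provenance
  class(out) <- c("study_dataset", "data.frame")
  out
}

normalise_sex <- function(x) {
  raw <- tolower(trimws(as.character(x)))
  mapped <- ifelse(raw %in% c("f", "female"), "female",
                   ifelse(raw %in% c("m", "male"), "male", NA))
  if (anyNA(mapped)) {
    stop("unrecognised sex label(s) in row(s): ",
         paste(which(is.na(mapped)), collapse = ", "),
         " (values: ", paste(unique(raw[is.na(mapped)]), collapse = ", "),
         "); expected female/male")
  }
  factor(mapped, levels = SEX_LEVELS)
}

normalise_level <- function(x, levels, what) {
  raw <- tolower(trimws(as.character(x)))
  bad <- !is.na(raw) & !(raw %in% levels)
  if (any(bad)) {
    stop(sprintf("unrecognised %s value(s): %s (expected %s)", what,
                 paste(unique(raw[bad]), collapse = ", "),
                 paste(levels, collapse = "/")))
  }
  factor(raw, levels = levels)
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("study_dataset: %d records (%d female, %d male), provenance: %s\n",
              nrow(x), sum(x$sex == "female"), sum(x$sex == "male"),
              attr(x, "provenance")))
  cat(sprintf("  burn states: %d unburnt, %d burnt; measurements present: %s\n",
              sum(x$burn_state == "unburnt"), sum(x$burn_state == "burnt"),
              paste(sprintf("%s=%d", MEASUREMENTS,
                            vapply(MEASUREMENTS,
                                   function(m) sum(!is.na(x[[m]])), 0L)),
                    collapse = ", ")))
  invisible(x)
}

#' Read a measurement CSV into a study dataset
#'
#' Expects a comma-separated, UTF-8, header-first file with columns
#' `individual_id,sex,age_at_death,side,burn_state,burn_temperature,
#' burn_duration,burn_colour,maxh,maxt,maxw`. Sex labels are normalised
#' case-insensitively (`F`/`f`/`Female` all work); unparseable measurement
#' cells become `NA` with a warning; missing mandatory columns or duplicate
#' individual/side keys are hard errors.
#'
#' @param path path to the CSV file.
#' @param provenance label stored on the returned dataset; defaults to the
#'   file name.
#' @return A [study_dataset].
#' @export
read_measurements <- function(path, provenance = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = c("NA", ""))
  missing_cols <- setdiff(MANDATORY_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (m in intersect(MEASUREMENTS, names(raw))) {
    parsed <- suppressWarnings(as.numeric(raw[[m]]))
    bad <- !is.na(raw[[m]]) & is.na(parsed)
    if (any(bad)) {
      warning(sprintf("%d unparseable %s cell(s) set to NA (rows %s)",
                      sum(bad), m, paste(which(bad), collapse = ", ")))
    }
    raw[[m]] <- parsed
  }
  study_dataset(raw, provenance = provenance)
}

#' Write a study dataset back to the measurement CSV dialect
#'
#' @param dataset a [study_dataset].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(dataset, path) {
  stopifnot(inherits(dataset, "study_dataset"))
  out <- as.data.frame(dataset)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Per-group descriptive summary of one measurement
#'
#' Bundles the sample size, mean, sample standard deviation (n - 1 divisor),
#' minimum and maximum of one measurement in one sex group — the quantities
#' the sectioning-point and D-value machinery consumes.
#'
#' @param n number of observations.
#' @param mean,sd,min,max summary statistics in millimetres; `sd` uses the
#'   n - 1 divisor.
#' @param check validate `n >= 2`, `sd > 0` and `min <= mean <= max`. Set to
#'   `FALSE` only for verbatim transcriptions of published tables whose
#'   printed cells are internally inconsistent.
#' @return An object of class `group_summary`.
#' @examples
#' group_summary(n = 18, mean = 33.33, sd = 4.53, min = 27.11, max = 42.93)
#' @export
group_summary <- function(n, mean, sd, min = NA_real_, max = NA_real_,
                          check = TRUE) {
  if (check) {
    if (n < 2) stop("group_summary requires n >= 2")
    if (!is.finite(sd) || sd <= 0) stop("group_summary requires sd > 0")
    if (is.finite(min) && is.finite(max) && !(min <= mean && mean <= max)) {
      stop("group_summary requires min <= mean <= max")
    }
  }
  structure(list(n = as.integer(n), mean = mean, sd = sd,
                 min = min, max = max),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("group_summary: n=%d mean=%.2f sd=%.2f min=%.2f max=%.2f (mm)\n",
              x$n, x$mean, x$sd, x$min, x$max))
  invisible(x)
}

#' A named set of published external cut-off points
#'
#' @param source_label where the cut-offs come from (e.g. a prior study).
#' @param cutoffs named numeric vector, measurement -> cut-off in mm.
#' @return An object of class `external_cutoffs`.
#' @export
external_cutoffs <- function(source_label, cutoffs) {
  cutoffs <- unlist(cutoffs)
  if (any(!is.finite(cutoffs)) || any(cutoffs <= 0)) {
    stop("every cut-off must be a positive number")
  }
  names(cutoffs) <- tolower(names(cutoffs))
  structure(list(source_label = source_label, cutoffs = cutoffs),
            class = "external_cutoffs")
}

#' @export
print.external_cutoffs <- function(x, ...) {
  cat(sprintf("external_cutoffs [%s]: %s\n", x$source_label,
              paste(sprintf("%s=%.2f", names(x$cutoffs), x$cutoffs),
                    collapse = ", ")))
  invisible(x)
}
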