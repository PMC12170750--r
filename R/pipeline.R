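ANALYSES <- c("dimorphism", "sectioning", "lda", "loocv",
              "external_cutoffs", "reliability")

#' Configuration for a full analysis run
#'
#' @param input path to a measurement CSV, or `NULL` when `synthetic` is
#'   given.
#' @param synthetic a [synthetic_config], used when `input` is `NULL`.
#' @param measurements measurements to analyse (subset of maxh/maxt/maxw).
#' @param analyses which stages to run, a subset of `"dimorphism"`,
#'   `"sectioning"`, `"lda"`, `"loocv"`, `"external_cutoffs"`,
#'   `"reliability"`; at least one.
#' @param external_cutoff_sources fixture names of published cut-off sets
#'   to evaluate on the calcined subset.
#' @param replicates path to a long-format replicate CSV
#'   (`subject_id,session,observer,measurement,value`) for the reliability
#'   stage, or `NULL` to skip it.
#' @param out_dir directory for the report CSVs and run log.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL,
                            measurements = MEASUREMENTS,
                            analyses = c("dimorphism", "sectioning", "lda",
                                         "loocv", "external_cutoffs"),
                            external_cutoff_sources = c("table6_cavazzuti",
                                                        "table6_hlad"),
                            replicates = NULL,
                            out_dir) {
  measurements <- match.arg(tolower(measurements), MEASUREMENTS,
                            several.ok = TRUE)
  analyses <- match.arg(tolower(analyses), ANALYSES, several.ok = TRUE)
  if (length(analyses) < 1) stop("select at least one analysis")
  if (is.null(input) && is.null(synthetic)) {
    stop("provide either an input CSV path or a synthetic_config")
  }
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_config"))
  structure(list(input = input, synthetic = synthetic,
                 measurements = measurements, analyses = analyses,
                 external_cutoff_sources = external_cutoff_sources,
                 replicates = replicates, out_dir = out_dir),
            class = "pipeline_config")
}

subset_burn <- function(dataset, state) {
  out <- dataset[dataset$burn_state == state, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- paste0(attr(dataset, "provenance"),
                                    " [", state, "]")
  class(out) <- c("study_dataset", "data.frame")
  out
}

#' Per-measurement dimorphism and sectioning table
#'
#' For each measurement with at least two usable values per sex: the
#' per-sex summaries, the Mann-Whitney z and p, and the sectioning point
#' with its D-value — the layout of the published descriptive tables.
#'
#' @param dataset a [study_dataset] (already restricted to one burn state
#'   if desired).
#' @param measurements measurements to tabulate.
#' @return A data frame, one row per measurement.
#' @export
sectioning_table <- function(dataset, measurements = MEASUREMENTS) {
  stopifnot(inherits(dataset, "study_dataset"))
  rows <- lapply(measurements, function(m) {
    f <- dataset[[m]][dataset$sex == "female" & !is.na(dataset[[m]])]
    ml <- dataset[[m]][dataset$sex == "male" & !is.na(dataset[[m]])]
    if (length(f) < 2 || length(ml) < 2) {
      warning("measurement ", m, " skipped: fewer than 2 usable values per sex")
      return(NULL)
    }
    gf <- summarize_group(f)
    gm <- summarize_group(ml)
    mw <- mann_whitney(f, ml)
    sec <- tryCatch(fit_cutoff(gf, gm, measurement = m),
                    error = function(e) NULL)
    data.frame(measurement = m,
               female_n = gf$n, female_mean = gf$mean, female_sd = gf$sd,
               female_min = gf$min, female_max = gf$max,
               male_n = gm$n, male_mean = gm$mean, male_sd = gm$sd,
               male_min = gm$min, male_max = gm$max,
               test_stat = mw$statistic, sig = mw$p_value,
               d_value = if (is.null(sec)) NA_real_ else sec$d_value,
               cutoff_mm = if (is.null(sec)) NA_real_ else sec$cutoff,
               sectioning_method = if (is.null(sec)) NA_character_ else sec$method)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

#' Discriminant-function table (one function per measurement + combined)
#'
#' Fits one single-measurement discriminant function per selected
#' measurement plus, when more than one measurement is selected, the
#' combined function, and reports coefficients, constant, centroids and
#' (when requested) original and cross-validated percent correct.
#'
#' @param dataset a [study_dataset] (typically the burnt subset).
#' @param measurements measurements available to the functions.
#' @param with_cv also run leave-one-out cross-validation.
#' @return A data frame, one row per (function, term), mirroring the
#'   published coefficient table.
#' @export
lda_table <- function(dataset, measurements = MEASUREMENTS, with_cv = TRUE) {
  stopifnot(inherits(dataset, "study_dataset"))
  sets <- lapply(measurements, function(m) m)
  if (length(measurements) > 1) sets <- c(sets, list(measurements))
  rows <- list()
  for (i in seq_along(sets)) {
    ms <- sets[[i]]
    model <- fit_lda(dataset, ms)
    orig <- resubstitution_lda(dataset, ms)
    cv <- if (with_cv) loocv_lda(dataset, ms) else NULL
    rows[[i]] <- data.frame(
      function_id = i,
      term = c(ms, "constant"),
      coefficient = c(unname(model$coefficients), model$constant),
      centroid_female = model$centroid_female,
      centroid_male = model$centroid_male,
      percent_original = orig$percent_correct_total,
      percent_cv = if (is.null(cv)) NA_real_ else cv$percent_correct_total)
  }
  do.call(rbind, rows)
}

#' Evaluate published external cut-offs on a dataset
#'
#' @param dataset a [study_dataset] (typically the calcined subset).
#' @param sources fixture names of [external_cutoffs] sets.
#' @param measurements measurements to evaluate.
#' @return A data frame, one row per (source, measurement): cut-off,
#'   per-sex and total percent correct.
#' @export
external_cutoff_table <- function(dataset,
                                  sources = c("table6_cavazzuti",
                                              "table6_hlad"),
                                  measurements = MEASUREMENTS) {
  rows <- list()
  for (src in sources) {
    set <- if (inherits(src, "external_cutoffs")) src else load_fixture(src)
    for (m in intersect(measurements, names(set$cutoffs))) {
      rep <- evaluate_cutoff(dataset, m, set$cutoffs[[m]])
      rows[[length(rows) + 1]] <- data.frame(
        source = set$source_label, measurement = m,
        cutoff_mm = set$cutoffs[[m]],
        percent_female = rep$percent_correct_female,
        percent_male = rep$percent_correct_male,
        percent_total = rep$percent_correct_total,
        n_female = rep$n_female, n_male = rep$n_male)
    }
  }
  do.call(rbind, rows)
}

# report rounding convention: 2 dp for mm, 3 dp for D-values, 1 dp for %
round_report <- function(df) {
  for (col in names(df)) {
    if (!is.numeric(df[[col]])) next
    if (grepl("d_value", col)) {
      df[[col]] <- round(df[[col]], 3)
    } else if (grepl("percent", col)) {
      df[[col]] <- round(df[[col]], 1)
    } else if (grepl("mean|sd|min|max|cutoff|coefficient|centroid|stat|tem",
                     col)) {
      df[[col]] <- round(df[[col]], 2)
    } else if (grepl("sig", col)) {
      df[[col]] <- round(df[[col]], 4)
    }
  }
  df
}

#' Write report tables to a directory
#'
#' Each element of `results` (a named list of data frames) is written as
#' `<name>.csv`, rounded to the reporting precision (2 decimals for mm,
#' 3 for D-values, 1 for percentages), alongside a single
#' `results_full.yaml` retaining full precision.
#'
#' @param results named list of data frames.
#' @param path output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_report_tables <- function(results, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  if (length(results) == 0) {
    warning("no results to write")
    return(invisible(character(0)))
  }
  stopifnot(!is.null(names(results)), all(nzchar(names(results))))
  written <- character(0)
  for (nm in names(results)) {
    df <- as.data.frame(results[[nm]])
    f <- file.path(path, paste0(nm, ".csv"))
    utils::write.csv(round_report(df), f, row.names = FALSE, na = "")
    written <- c(written, f)
  }
  full <- file.path(path, "results_full.yaml")
  yaml::write_yaml(lapply(results, function(df) {
    lapply(as.data.frame(df), function(col) unname(as.vector(col)))
  }), full)
  invisible(c(written, full))
}

pipeline_config_to_list <- function(config) {
  syn <- config$synthetic
  list(input = config$input,
       measurements = config$measurements,
       analyses = config$analyses,
       external_cutoff_sources = config$external_cutoff_sources,
       replicates = config$replicates,
       synthetic = if (is.null(syn)) NULL else list(
         n_female = syn$n_female, n_male = syn$n_male,
         mean_female = as.numeric(syn$mean_female),
         mean_male = as.numeric(syn$mean_male),
         sd_female = as.numeric(syn$sd_female),
         sd_male = as.numeric(syn$sd_male),
         correlation = as.numeric(syn$correlation),
         shrinkage_mean = as.numeric(syn$shrinkage_mean),
         shrinkage_sd = syn$shrinkage_sd,
         missing_prob_burnt = syn$missing_prob_burnt,
         age_range_female = syn$age_range_female,
         age_range_male = syn$age_range_male,
         seed = syn$seed))
}

pipeline_config_from_list <- function(x, out_dir) {
  syn <- NULL
  if (!is.null(x$synthetic)) {
    s <- x$synthetic
    syn <- synthetic_config(
      n_female = s$n_female, n_male = s$n_male,
      mean_female = unlist(s$mean_female),
      mean_male = unlist(s$mean_male),
      sd_female = unlist(s$sd_female),
      sd_male = unlist(s$sd_male),
      correlation = matrix(unlist(s$correlation), 3, 3),
      shrinkage_mean = unlist(s$shrinkage_mean),
      shrinkage_sd = s$shrinkage_sd,
      missing_prob_burnt = s$missing_prob_burnt,
      age_range_female = unlist(s$age_range_female),
      age_range_male = unlist(s$age_range_male),
      seed = s$seed)
  }
  pipeline_config(
    input = x$input, synthetic = syn,
    measurements = unlist(x$measurements),
    analyses = unlist(x$analyses),
    external_cutoff_sources = unlist(x$external_cutoff_sources),
    replicates = x$replicates,
    out_dir = out_dir)
}

#' Read a pipeline configuration from a YAML file
#'
#' Accepts either a hand-written config file or the `run_log.yaml` a
#' previous [run_pipeline] call wrote (the log embeds the full config, so
#' any run can be replayed exactly).
#'
#' @param path YAML file with the [pipeline_config] fields (optionally
#'   nested under a `config:` key, as in the run log).
#' @param out_dir output directory for the new run.
#' @return A [pipeline_config].
#' @export
read_pipeline_config <- function(path, out_dir) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$config)) x <- x$config
  pipeline_config_from_list(x, out_dir)
}

# tiny polynomial rolling hash of the deparsed config, for the run log
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config, control = "all"), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Executes the selected stages in the study's order on (a) the burnt
#' records, (b) the unburnt antimeres and (c) the calcined subset
#' ([filter_calcined]), writes one CSV per table analogue plus a YAML run
#' log recording the seed, a config hash and exclusion counts, and returns
#' the in-memory results. Deterministic given (input, config, seed): no
#' timestamps enter the outputs.
#'
#' @param config a [pipeline_config].
#' @return Invisibly, a named list with the dataset and every table
#'   produced.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dataset <- if (!is.null(config$input)) {
    read_measurements(config$input)
  } else {
    simulate_study(config$synthetic)
  }
  burnt <- subset_burn(dataset, "burnt")
  unburnt <- subset_burn(dataset, "unburnt")
  calcined <- suppressWarnings(filter_calcined(dataset))

  tables <- list()
  want <- function(a) a %in% config$analyses
  if (want("dimorphism") || want("sectioning")) {
    tables$table_burnt_dimorphism <-
      sectioning_table(burnt, config$measurements)
    tables$table_unburnt_dimorphism <-
      sectioning_table(unburnt, config$measurements)
    if (nrow(calcined) >= 4) {
      tables$table_calcined_dimorphism <- tryCatch(
        sectioning_table(calcined, config$measurements),
        warning = function(w) NULL, error = function(e) NULL)
    }
  }
  if (want("lda") || want("loocv")) {
    tables$table_lda <- lda_table(burnt, config$measurements,
                                  with_cv = want("loocv"))
  }
  if (want("external_cutoffs")) {
    eval_set <- if (nrow(calcined) > 0) calcined else burnt
    tables$table_external_cutoffs <- tryCatch(
      external_cutoff_table(eval_set, config$external_cutoff_sources,
                            config$measurements),
      error = function(e) {
        warning("external cut-off evaluation skipped: ", conditionMessage(e))
        NULL
      })
  }
  if (want("reliability") && !is.null(config$replicates)) {
    reps <- utils::read.csv(config$replicates, stringsAsFactors = FALSE)
    rel <- lapply(intersect(config$measurements,
                            tolower(unique(reps$measurement))),
                  function(m) {
                    r <- observer_error(replicates = reps, measurement = m,
                                        mode = "intra")
                    data.frame(measurement = m, tem = r$tem,
                               percent_tem = r$percent_tem,
                               reliability_r = r$reliability_r,
                               n_subjects = r$n_subjects)
                  })
    tables$table_reliability <- do.call(rbind, rel)
  }
  tables <- Filter(Negate(is.null), tables)

  files <- write_report_tables(tables, config$out_dir)
  log <- list(
    seed = if (!is.null(config$synthetic)) config$synthetic$seed else NA,
    config_hash = config_hash(config),
    provenance = attr(dataset, "provenance"),
    n_records = nrow(dataset),
    n_burnt_unmeasurable = sum(dataset$burn_state == "burnt" &
                                 is.na(dataset$maxh) & is.na(dataset$maxt) &
                                 is.na(dataset$maxw)),
    n_calcined = nrow(calcined),
    analyses = config$analyses,
    measurements = config$measurements,
    tables_written = basename(files),
    config = pipeline_config_to_list(config))
  yaml::write_yaml(log, file.path(config$out_dir, "run_log.yaml"))
  invisible(c(list(dataset = dataset), tables))
}

#' Plot the two fitted normal densities and the sectioning point
#'
#' @param x a `sectioning_result`.
#' @param ... passed to [graphics::curve].
#' @return `x`, invisibly.
#' @export
plot.sectioning_result <- function(x, ...) {
  f <- x$female; m <- x$male
  lo <- min(f$mean - 3.5 * f$sd, m$mean - 3.5 * m$sd)
  hi <- max(f$mean + 3.5 * f$sd, m$mean + 3.5 * m$sd)
  graphics::curve(stats::dnorm(t, f$mean, f$sd), xname = "t",
                  from = lo, to = hi, col = "firebrick", lwd = 2,
                  xlab = "measurement (mm)", ylab = "density",
                  main = if (is.na(x$measurement)) "sectioning point"
                         else x$measurement, ...)
  graphics::curve(stats::dnorm(t, m$mean, m$sd), xname = "t",
                  from = lo, to = hi, col = "navy", lwd = 2, add = TRUE)
  graphics::abline(v = x$cutoff, lty = 2)
  graphics::legend("topright", bty = "n", lwd = 2,
                   col = c("firebrick", "navy"),
                   legend = c("female", "male"))
  invisible(x)
}
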