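FIXTURE_NAMES <- c("table2_burnt", "table3_unburnt",
                   "table2_cutoffs", "table3_cutoffs",
                   "table6_cavazzuti", "table6_hlad",
                   "sample_structure")

#' Load an embedded reference fixture
#'
#' The package ships the published per-sex summary statistics for the burnt
#' and unburnt patellar samples of the source study (18 females, 14 males),
#' the published sectioning points and D-values, the external cut-off points
#' of two earlier cremated-patella studies, and the study's age structure.
#' These are transcriptions of printed tables: a few printed min/max cells
#' are internally inconsistent (e.g. a maximum below the group mean) and are
#' carried verbatim rather than corrected.
#'
#' @param name one of `"table2_burnt"`, `"table3_unburnt"` (per-measurement
#'   lists of female/male [group_summary] pairs), `"table2_cutoffs"`,
#'   `"table3_cutoffs"` (data frames of published D-values and cut-offs),
#'   `"table6_cavazzuti"`, `"table6_hlad"` ([external_cutoffs]), or
#'   `"sample_structure"` (per-sex age structure data frame).
#' @return See `name`.
#' @examples
#' load_fixture("table2_burnt")$maxh$female
#' load_fixture("table6_hlad")
#' @export
load_fixture <- function(name) {
  if (!name %in% FIXTURE_NAMES) {
    stop("unknown fixture '", name, "'; valid fixtures: ",
         paste(FIXTURE_NAMES, collapse = ", "))
  }
  extfile <- function(f) {
    path <- system.file("extdata", f, package = "osteosex")
    if (!nzchar(path)) path <- file.path("inst", "extdata", f)
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (name %in% c("table2_burnt", "table3_unburnt")) {
    f <- if (name == "table2_burnt") "table2_burnt_summaries.csv" else
      "table3_unburnt_summaries.csv"
    tab <- extfile(f)
    out <- lapply(MEASUREMENTS, function(m) {
      rows <- tab[tolower(tab$measurement) == m, ]
      setNames(lapply(SEX_LEVELS, function(s) {
        r <- rows[rows$sex == s, ]
        # check = FALSE: printed min/max cells are reproduced verbatim even
        # where internally inconsistent with the printed mean
        group_summary(r$n, r$mean, r$sd, r$min, r$max, check = FALSE)
      }), SEX_LEVELS)
    })
    return(setNames(out, MEASUREMENTS))
  }
  if (name %in% c("table2_cutoffs", "table3_cutoffs")) {
    f <- if (name == "table2_cutoffs") "table2_sectioning.csv" else
      "table3_sectioning.csv"
    tab <- extfile(f)
    tab$measurement <- tolower(tab$measurement)
    return(tab)
  }
  if (name %in% c("table6_cavazzuti", "table6_hlad")) {
    src <- sub("table6_", "", name)
    tab <- extfile("table6_external_cutoffs.csv")
    tab <- tab[tab$source == src, ]
    return(external_cutoffs(src,
                            setNames(tab$cutoff, tolower(tab$measurement))))
  }
  extfile("sample_structure.csv")
}
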