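# Bundled case-study reference tables ---------------------------------------

#' Reference results for the California case-study farm
#'
#' Net profits reported for a 65.56 ha (162 acre) irrigated corn farm of
#' 324 half-acre land units, under the sixteen management-scale scenarios
#' and the three constrained irrigation patterns. These published figures
#' depend on a soil survey and yield/water tables that were never released,
#' so they cannot be recomputed from scratch; they are bundled as inputs
#' for the derived quantities that *are* reproducible (gain ratios,
#' relative gains for customized irrigation, and the profit-vs-granularity
#' regression).
#'
#' @return list of two data.frames:
#' * `scenarios`: `scenario`, `n_units`, `shape`, `net_profit`,
#'   `gain_ratio` (as printed);
#' * `patterns`: `scenario`, `pattern1`, `pattern2`, `pattern3`, `rgi`
#'   (as printed).
#' @export
case_study_tables <- function() {
  dir <- system.file("extdata", package = "agroplan", mustWork = TRUE)
  list(
    scenarios = read.csv(file.path(dir, "case_study_scenarios.csv"),
      stringsAsFactors = FALSE),
    patterns = read.csv(file.path(dir, "case_study_patterns.csv"),
      stringsAsFactors = FALSE)
  )
}

#' Total area of the case-study farm (ha)
#' @return 65.56
#' @export
case_study_area <- function() 65.56
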