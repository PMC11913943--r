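#' @title Bisley Nature Reserve desk fixtures
#' @description The published area and transition tables for the Bisley
#'   Nature Reserve encroachment study ship with the package as CSV. Values
#'   are printed to 2 decimals, so matrices reconstructed from them carry
#'   rounding noise of a few hundredths of a hectare; the third observed
#'   interval (2019-2023) is additionally internally inconsistent (its
#'   printed grass-row flows sum to 142.37 ha against a printed 2019 grass
#'   area of 124.93 ha), which is why [bisley_transition_matrices] uses a
#'   relaxed completion tolerance there.
#' @name bisley
NULL

bisley_file <- function(name) {
  system.file("extdata", name, package = "encroachr", mustWork = TRUE)
}

#' Published class areas by year (hectares)
#'
#' @param years which years to return (subset of 2009, 2014, 2019, 2023,
#'   2028, 2033; the last two are the study's projections).
#' @return J x length(years) matrix, rows in scheme order
#'   (woody, grasses, bare).
#' @export
bisley_class_areas <- function(years = c(2009, 2014, 2019, 2023)) {
  df <- utils::read.csv(bisley_file("bisley_class_areas.csv"))
  m <- as.matrix(df[, paste0("y", years), drop = FALSE])
  dimnames(m) <- list(df$class, years)
  m
}

#' Published transition flows (hectares)
#'
#' @param interval label such as `"2009-2014"`; `NULL` returns all rows.
#' @return data frame with columns `from`, `to`, `interval`, `area_ha`.
#' @export
bisley_transitions <- function(interval = NULL) {
  df <- utils::read.csv(bisley_file("bisley_transitions.csv"))
  if (!is.null(interval)) df <- df[df$interval == interval, ]
  df
}

#' Partially known transition matrix for one published interval
#'
#' The six printed flows for the interval; the remaining three cells
#' (bare to woody, woody to bare, bare to bare) are `NA`.
#'
#' @param interval label such as `"2009-2014"`.
#' @param scheme a [class_scheme].
#' @return J x J matrix with `NA` unknowns.
#' @export
bisley_known_matrix <- function(interval, scheme = class_scheme()) {
  df <- bisley_transitions(interval)
  if (!nrow(df)) stop(sprintf("no printed flows for '%s'", interval),
                      call. = FALSE)
  m <- matrix(NA_real_, scheme$J, scheme$J,
              dimnames = list(scheme$names, scheme$names))
  m[cbind(match(df$from, scheme$names), match(df$to, scheme$names))] <-
    df$area_ha
  m
}

#' Completed transition matrices for the three observed intervals
#'
#' Solves the three unprinted cells of each interval from the published
#' class-area marginals via [complete_matrix]. The first interval is
#' consistent to within printing precision (max residual 0.47 ha), but the
#' published tables contradict each other on the later intervals: the
#' 2014-2019 grass column is off by 1.24 ha and the 2019-2023 grass row by
#' 17.44 ha, so those completions need the wider per-interval tolerances
#' (see the package vignette).
#'
#' @param scheme a [class_scheme].
#' @param tols completion tolerances (ha) for the three intervals.
#' @return named list of three [transition_matrix] objects with durations
#'   5, 5 and 4 years.
#' @export
bisley_transition_matrices <- function(scheme = class_scheme(),
                                       tols = c(0.5, 2, 20)) {
  areas <- bisley_class_areas()
  intervals <- c("2009-2014", "2014-2019", "2019-2023")
  durations <- c(5, 5, 4)
  out <- lapply(seq_along(intervals), function(k) {
    complete_matrix(bisley_known_matrix(intervals[k], scheme),
                    row_totals = areas[, k], col_totals = areas[, k + 1],
                    duration = durations[k], scheme = scheme, tol = tols[k])
  })
  stats::setNames(out, intervals)
}
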