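#' Class scheme for categorical land-cover maps
#'
#' @param codes ordered integer class codes (unique, length >= 2).
#' @param names class labels, same length as `codes`.
#' @return object of class `class_scheme` with elements `codes`, `names`
#'   and `J` (the number of categories).
#' @export
class_scheme <- function(codes = 1:3,
                         names = c("woody", "grasses", "bare")) {
  codes <- as.integer(codes)
  if (anyDuplicated(codes)) stop("class codes must be unique", call. = FALSE)
  if (length(codes) < 2L) stop("a scheme needs at least two categories",
                               call. = FALSE)
  if (length(names) != length(codes)) {
    stop("`names` must match `codes` in length", call. = FALSE)
  }
  structure(list(codes = codes, names = as.character(names),
                 J = length(codes)),
            class = "class_scheme")
}

#' Transition matrix between two observation dates
#'
#' Entry `(i, j)` is the area (hectares) that was class `i` at the start of
#' the interval and class `j` at its end. Row sums are the class areas at
#' the initial date, column sums the areas at the final date.
#'
#' @param entries J x J non-negative numeric matrix of areas in hectares.
#' @param duration interval length in years (> 0).
#' @param scheme a [class_scheme].
#' @return object of class `transition_matrix` with fields `entries`,
#'   `duration`, `scheme` and `total_area`.
#' @export
transition_matrix <- function(entries, duration, scheme = class_scheme()) {
  entries <- as.matrix(entries)
  J <- scheme$J
  if (!all(dim(entries) == c(J, J))) {
    stop("`entries` must be J x J for the scheme", call. = FALSE)
  }
  if (any(entries < 0, na.rm = TRUE)) {
    stop("transition areas must be non-negative", call. = FALSE)
  }
  if (!is.numeric(duration) || duration <= 0) {
    stop("`duration` must be a positive number of years", call. = FALSE)
  }
  dimnames(entries) <- list(from = scheme$names, to = scheme$names)
  structure(list(entries = entries, duration = as.numeric(duration),
                 scheme = scheme, total_area = sum(entries)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d classes, %g yr, %.2f ha\n",
              x$scheme$J, x$duration, x$total_area))
  print(round(x$entries, 2))
  invisible(x)
}

#' Cross-tabulate two aligned land-cover maps
#'
#' @param map_t,map_t1 aligned categorical [grid]s sharing `scheme`.
#' @param duration interval length in years.
#' @param scheme a [class_scheme].
#' @return a [transition_matrix]; the count of cells excluded because they
#'   are nodata at either date is attached as attribute `"excluded_cells"`.
#' @export
crosstab <- function(map_t, map_t1, duration, scheme = class_scheme()) {
  stopifnot_aligned(map_t, map_t1, "land-cover maps")
  a <- as.vector(map_t$values); b <- as.vector(map_t1$values)
  keep <- !is.na(a) & !is.na(b)
  counts <- table(factor(a[keep], levels = scheme$codes),
                  factor(b[keep], levels = scheme$codes))
  ha <- unclass(counts) * cell_area_ha(map_t)
  tm <- transition_matrix(ha, duration, scheme)
  attr(tm, "excluded_cells") <- sum(!keep)
  tm
}

# Active-set non-negative least squares: min ||Ax - b|| s.t. x >= 0.
# Solves the unconstrained LS via pseudo-inverse, then repeatedly pins the
# most negative coefficient at zero and re-solves the reduced system.
nnls_solve <- function(A, b) {
  pinv_solve <- function(M, y) {
    sv <- svd(M)
    pos <- sv$d > max(dim(M)) * max(sv$d, 0) * .Machine$double.eps
    if (!any(pos)) return(rep(0, ncol(M)))
    sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
  }
  m <- ncol(A)
  free <- rep(TRUE, m)
  x <- rep(0, m)
  for (iter in seq_len(m + 1L)) {
    x[!free] <- 0
    if (any(free)) {
      x[free] <- pinv_solve(A[, free, drop = FALSE], b)
    }
    if (all(x >= -1e-10)) break
    worst <- which.min(x)
    free[worst] <- FALSE
  }
  pmax(x, 0)
}

#' Complete a partially known transition matrix from its marginals
#'
#' Unknown cells (`NA`) are solved from the linear constraints that each row
#' must sum to the class area at the initial date and each column to the
#' area at the final date. When the system is underdetermined or (because
#' printed tables are rounded) slightly inconsistent, the unknowns are the
#' non-negative least-squares solution and the residual of every constraint
#' is reported. A residual above `tol` raises an error.
#'
#' @param known J x J matrix of areas in hectares with `NA` for unknown cells.
#' @param row_totals,col_totals class areas (ha) at the initial and final
#'   dates, in scheme order.
#' @param duration interval length in years.
#' @param scheme a [class_scheme].
#' @param tol maximum tolerated absolute constraint residual in hectares
#'   (default 0.5, sized to absorb 2-decimal rounding of printed tables).
#' @return a [transition_matrix]; the largest absolute constraint residual
#'   (ha) is attached as attribute `"residual"`.
#' @export
complete_matrix <- function(known, row_totals, col_totals, duration = 1,
                            scheme = class_scheme(), tol = 0.5) {
  known <- as.matrix(known)
  J <- scheme$J
  stopifnot(all(dim(known) == c(J, J)),
            length(row_totals) == J, length(col_totals) == J)
  if (abs(sum(row_totals) - sum(col_totals)) >
      max(tol * 2 * J, 1e-6 * sum(row_totals))) {
    stop(sprintf(
      "marginals are inconsistent: rows sum to %.4f ha, columns to %.4f ha",
      sum(row_totals), sum(col_totals)), call. = FALSE)
  }
  unk <- which(is.na(known))
  filled <- known
  if (length(unk)) {
    # constraint matrix: one row per row-sum and per column-sum constraint
    A <- matrix(0, 2L * J, length(unk))
    b <- numeric(2L * J)
    ri <- (unk - 1L) %% J + 1L
    ci <- (unk - 1L) %/% J + 1L
    for (r in seq_len(J)) {
      A[r, ri == r] <- 1
      b[r] <- row_totals[r] - sum(known[r, ], na.rm = TRUE)
    }
    for (cc in seq_len(J)) {
      A[J + cc, ci == cc] <- 1
      b[J + cc] <- col_totals[cc] - sum(known[, cc], na.rm = TRUE)
    }
    x <- nnls_solve(A, b)
    filled[unk] <- x
  }
  resid <- max(abs(c(rowSums(filled) - row_totals,
                     colSums(filled) - col_totals)))
  if (resid > tol) {
    stop(sprintf(
      "constraints infeasible: max residual %.3f ha exceeds tolerance %.3f ha",
      resid, tol), call. = FALSE)
  }
  filled[filled < 0] <- 0
  tm <- transition_matrix(filled, duration, scheme)
  attr(tm, "residual") <- resid
  tm
}

#' Area-change summaries over a land-cover time series
#'
#' @param areas_by_year J x T matrix of class areas (ha); columns named by
#'   year, rows in scheme order.
#' @param scheme a [class_scheme].
#' @param total_area study-region area in hectares used for all percent
#'   figures; defaults to the summed areas of the first year (the region is
#'   assumed constant through time).
#' @return list with:
#'   \describe{
#'     \item{percent_cover}{J x T matrix, `areas / total_area * 100`.}
#'     \item{net_change}{data frame per class: change in ha and in percent
#'       of the region between the first and last year.}
#'     \item{total_area}{the area used as denominator.}
#'   }
#' @export
change_summaries <- function(areas_by_year, scheme = class_scheme(),
                             total_area = NULL) {
  areas_by_year <- as.matrix(areas_by_year)
  stopifnot(nrow(areas_by_year) == scheme$J)
  if (is.null(total_area)) total_area <- sum(areas_by_year[, 1])
  pc <- areas_by_year / total_area * 100
  rownames(pc) <- scheme$names
  last <- ncol(areas_by_year)
  net_ha <- areas_by_year[, last] - areas_by_year[, 1]
  net <- data.frame(class = scheme$names,
                    net_change_ha = as.numeric(net_ha),
                    net_change_pct = as.numeric(net_ha) / total_area * 100,
                    row.names = NULL)
  list(percent_cover = pc, net_change = net, total_area = total_area)
}

#' Relative change of one transition between consecutive intervals
#'
#' `(a - b) / a * 100` for interval areas `a` then `b`: positive values are
#' a relative decline of the flow.
#'
#' @param interval_areas numeric vector of the transition's area (ha) per
#'   interval, in time order.
#' @return numeric vector of length `length(interval_areas) - 1` in percent.
#' @export
transition_relative_change <- function(interval_areas) {
  a <- interval_areas[-length(interval_areas)]
  b <- interval_areas[-1]
  (a - b) / a * 100
}

#' Share of the study region taken by one transition
#'
#' @param transition_area area of the flow in hectares.
#' @param total_area study-region area in hectares.
#' @return percent of the region.
#' @export
transition_share <- function(transition_area, total_area) {
  transition_area / total_area * 100
}

#' Write / read a transition matrix as CSV with a JSON sidecar
#'
#' The CSV holds the J x J hectare entries with class names; the sidecar
#' (`<path>.json`) records the scheme, duration and total area.
#'
#' @param tm a [transition_matrix].
#' @param path CSV path.
#' @return `path` (write) or a [transition_matrix] (read).
#' @export
write_transition_matrix <- function(tm, path) {
  utils::write.csv(as.data.frame(tm$entries), path, row.names = TRUE)
  side <- list(codes = tm$scheme$codes, names = tm$scheme$names,
               duration = tm$duration, total_area = tm$total_area)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_transition_matrix
#' @export
read_transition_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  sch <- class_scheme(side$codes, side$names)
  transition_matrix(as.matrix(df), side$duration, sch)
}
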