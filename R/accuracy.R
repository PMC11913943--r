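#' Build a confusion matrix (reference in rows, map in columns)
#'
#' @param reference either an aligned categorical [grid], or a data frame of
#'   labelled points with columns `x`, `y`, `class` (map coordinates;
#'   points outside the map or on nodata cells are dropped).
#' @param mapped categorical [grid] being assessed.
#' @param scheme a [class_scheme].
#' @return object of class `confusion_matrix`: integer counts with the
#'   scheme attached.
#' @export
build_confusion <- function(reference, mapped, scheme = class_scheme()) {
  if (inherits(reference, "grid")) {
    stopifnot_aligned(reference, mapped, "reference and mapped grids")
    ref <- as.vector(reference$values)
    map <- as.vector(mapped$values)
  } else {
    pts <- as.data.frame(reference)
    stopifnot(all(c("x", "y", "class") %in% names(pts)))
    ci <- floor((pts$x - mapped$origin[1]) / mapped$pixel_size) + 1L
    ri <- floor((mapped$origin[2] - pts$y) / mapped$pixel_size) + 1L
    inside <- ri >= 1 & ri <= nrow(mapped$values) &
      ci >= 1 & ci <= ncol(mapped$values)
    ref <- pts$class[inside]
    map <- mapped$values[cbind(ri[inside], ci[inside])]
  }
  keep <- !is.na(ref) & !is.na(map)
  if (!any(keep)) stop("no overlapping valid cells to compare", call. = FALSE)
  counts <- table(factor(ref[keep], levels = scheme$codes),
                  factor(map[keep], levels = scheme$codes))
  counts <- matrix(as.integer(counts), scheme$J, scheme$J,
                   dimnames = list(reference = scheme$names,
                                   mapped = scheme$names))
  structure(list(counts = counts, scheme = scheme),
            class = "confusion_matrix")
}

#' Confusion matrix from raw counts
#' @param counts J x J non-negative integer matrix, reference in rows.
#' @param scheme a [class_scheme].
#' @return a `confusion_matrix`.
#' @export
confusion_matrix <- function(counts, scheme = class_scheme()) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == scheme$J), all(counts >= 0), sum(counts) > 0)
  dimnames(counts) <- list(reference = scheme$names, mapped = scheme$names)
  structure(list(counts = counts, scheme = scheme),
            class = "confusion_matrix")
}

#' Accuracy metrics from a confusion matrix
#'
#' Overall accuracy, per-class producer's and user's accuracy with their
#' complements (omission and commission error), and Cohen's kappa
#' `(p_o - p_e) / (1 - p_e)` with chance agreement `p_e` from the marginal
#' products. Classes absent from a margin get `NA` for the affected metric.
#'
#' @param cm a `confusion_matrix`.
#' @return list with `overall`, `kappa` and a per-class data frame.
#' @export
accuracy_metrics <- function(cm) {
  n <- sum(cm$counts)
  diagv <- diag(cm$counts)
  rs <- rowSums(cm$counts); cs <- colSums(cm$counts)
  overall <- sum(diagv) / n
  producers <- ifelse(rs > 0, diagv / rs, NA_real_)
  users <- ifelse(cs > 0, diagv / cs, NA_real_)
  pe <- sum((rs / n) * (cs / n))
  kappa <- if (pe < 1) (overall - pe) / (1 - pe) else NA_real_
  list(overall = overall, kappa = kappa, expected_agreement = pe,
       per_class = data.frame(
         class = cm$scheme$names,
         producers = as.numeric(producers), users = as.numeric(users),
         omission_error = 1 - as.numeric(producers),
         commission_error = 1 - as.numeric(users),
         row.names = NULL))
}

#' Quantity and allocation disagreement, and the QADI index
#'
#' On proportions `p = counts / total`: total disagreement
#' `D = 1 - sum(diag(p))`; quantity disagreement
#' `Q = 0.5 * sum(|p_g. - p_.g|)` (mismatched class proportions); allocation
#' disagreement `A = D - Q` (misplaced but quantity-balanced cells). The
#' combined QADI index is the Euclidean norm `sqrt(Q^2 + A^2)`; the `(Q, A)`
#' pair are the plot coordinates of the QADI graph.
#'
#' @param cm a `confusion_matrix`.
#' @return list with `Q`, `A`, `D`, `QADI` (all in `[0, 1]`).
#' @export
disagreement <- function(cm) {
  p <- cm$counts / sum(cm$counts)
  D <- 1 - sum(diag(p))
  Q <- 0.5 * sum(abs(rowSums(p) - colSums(p)))
  A <- D - Q
  list(Q = Q, A = A, D = D, QADI = qadi_index(Q, A))
}

#' Combine quantity and allocation disagreement into one index
#'
#' Kept as a separate function so the combining rule can be swapped; the
#' default is the Euclidean norm of the two components.
#'
#' @param Q,A quantity and allocation disagreement in `[0, 1]`.
#' @return scalar index in `[0, 1]`.
#' @export
qadi_index <- function(Q, A) sqrt(Q^2 + A^2)

#' Plot a QADI graph
#'
#' Quantity disagreement on x, allocation disagreement on y, the assessed
#' map as a single dot; the dashed diagonal marks Q = A.
#'
#' @param Q,A disagreement components.
#' @param path optional PNG path; when given the plot is written there.
#' @param lim axis limit (default covers the point with headroom).
#' @return invisibly, `c(Q, A)`.
#' @export
qadi_plot <- function(Q, A, path = NULL, lim = NULL) {
  if (is.null(lim)) lim <- max(0.2, Q * 1.5, A * 1.5)
  draw <- function() {
    graphics::plot(NA, xlim = c(0, lim), ylim = c(0, lim),
                   xlab = "Quantity disagreement",
                   ylab = "Allocation disagreement", asp = 1)
    graphics::abline(0, 1, lty = 2, col = "grey50")
    graphics::points(Q, A, pch = 16, cex = 1.4)
  }
  if (!is.null(path)) {
    grDevices::png(path, width = 600, height = 600)
    on.exit(grDevices::dev.off())
    draw()
  } else draw()
  invisible(c(Q = Q, A = A))
}

#' Write a confusion matrix as CSV / read it back
#' @param cm a `confusion_matrix`.
#' @param path CSV path; rows are the reference classes.
#' @return `path`, or the `confusion_matrix` on read.
#' @export
write_confusion <- function(cm, path) {
  utils::write.csv(as.data.frame(cm$counts), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_confusion
#' @param scheme a [class_scheme] for the read matrix.
#' @export
read_confusion <- function(path, scheme = class_scheme()) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  confusion_matrix(as.matrix(df), scheme)
}
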