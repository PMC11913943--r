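#' @title Three-level Intensity Analysis
#' @description Compares observed annual change intensities with uniform
#'   intensities at the interval, category and transition levels of a
#'   land-cover transition-matrix time series. An intensity above its
#'   uniform benchmark marks a fast interval, an active category, or a
#'   targeted transition; below it, slow / dormant / avoided. Intensities
#'   with a zero denominator (a class absent at one date) are reported as
#'   `NA` and excluded from flags rather than coerced to zero.
#' @name intensity
NULL

tm_gains <- function(tm) colSums(tm$entries) - diag(tm$entries)
tm_losses <- function(tm) rowSums(tm$entries) - diag(tm$entries)
tm_change <- function(tm) sum(tm$entries) - sum(diag(tm$entries))

#' Interval-level intensity
#'
#' Annual change intensity per interval,
#' `S_t = change_t / (duration_t * area) * 100`, and the uniform annual
#' change over the whole extent,
#' `U = sum(change_t) / (sum(duration_t) * area) * 100`. Each matrix's own
#' total area is its denominator; `U` then equals the duration-weighted
#' mean of the `S_t`.
#'
#' @param matrices list of [transition_matrix] objects in time order.
#' @param labels optional interval labels.
#' @param total_tol maximum tolerated relative spread of total areas across
#'   matrices (default 0.5\%). Reconstructions from rounded printed tables
#'   may need a looser value.
#' @return list with `intervals` (data frame: label, duration,
#'   change area (ha), `S_t` \%/yr, per-interval total change \%, fast flag)
#'   and `U` (\%/yr).
#' @export
interval_level <- function(matrices, labels = NULL, total_tol = 0.005) {
  stopifnot(length(matrices) >= 1L)
  durations <- vapply(matrices, function(m) m$duration, numeric(1))
  if (any(durations <= 0)) stop("durations must be positive", call. = FALSE)
  totals <- vapply(matrices, function(m) m$total_area, numeric(1))
  if (diff(range(totals)) > total_tol * mean(totals)) {
    stop(sprintf(
      "total areas differ by %.2f%% across matrices (tolerance %.2f%%)",
      diff(range(totals)) / mean(totals) * 100, total_tol * 100),
      call. = FALSE)
  }
  changes <- vapply(matrices, tm_change, numeric(1))
  S <- changes / (durations * totals) * 100
  U <- sum(S * durations) / sum(durations)
  if (is.null(labels)) labels <- paste0("interval_", seq_along(matrices))
  list(intervals = data.frame(
         label = labels, duration = durations, change_ha = changes,
         S = S, total_change_pct = S * durations, fast = S > U,
         row.names = NULL),
       U = U)
}

#' Category-level intensity for one interval
#'
#' Gain intensity `G_tj = (gain_j / duration) / area_j(t+1) * 100` and loss
#' intensity `L_ti = (loss_i / duration) / area_i(t) * 100`; a category is
#' an active gainer/loser when its intensity exceeds the uniform annual
#' change `U`.
#'
#' @param tm a [transition_matrix].
#' @param U uniform annual change intensity (\%/yr), normally from
#'   [interval_level] over the full extent.
#' @return data frame per category: gain/loss areas (ha), `G`, `L` (\%/yr,
#'   `NA` where the denominator is zero) and active flags (`NA` when the
#'   intensity is undefined).
#' @export
category_level <- function(tm, U) {
  gains <- tm_gains(tm); losses <- tm_losses(tm)
  area_t1 <- colSums(tm$entries); area_t <- rowSums(tm$entries)
  G <- ifelse(area_t1 > 0, (gains / tm$duration) / area_t1 * 100, NA_real_)
  L <- ifelse(area_t > 0, (losses / tm$duration) / area_t * 100, NA_real_)
  data.frame(class = tm$scheme$names,
             gain_ha = as.numeric(gains), loss_ha = as.numeric(losses),
             G = as.numeric(G), L = as.numeric(L),
             active_gainer = as.numeric(G) > U,
             active_loser = as.numeric(L) > U,
             row.names = NULL)
}

#' Transition-level intensity onto a gaining category
#'
#' For gaining category `n`: `R_tin = (entry(i, n) / duration) / area_i(t)
#' * 100` for each donor `i != n`, against the uniform gain intensity
#' `W_tn = (gain_n / duration) / (total_area - area_n(t)) * 100`. A donor
#' with `R > W` is targeted by `n`'s gains; `R < W` is avoided.
#'
#' @param tm a [transition_matrix].
#' @param gaining class name or code of the gaining category `n`.
#' @return list with `W` and a data frame per donor category: `R`,
#'   `targeted`, `avoided` (`NA` where `R` is undefined).
#' @export
transition_level <- function(tm, gaining) {
  n <- match_class(tm$scheme, gaining)
  area_t <- rowSums(tm$entries)
  gain_n <- sum(tm$entries[, n]) - tm$entries[n, n]
  denomW <- tm$total_area - area_t[n]
  W <- if (denomW > 0) (gain_n / tm$duration) / denomW * 100 else NA_real_
  donors <- setdiff(seq_len(tm$scheme$J), n)
  R <- ifelse(area_t[donors] > 0,
              (tm$entries[donors, n] / tm$duration) / area_t[donors] * 100,
              NA_real_)
  list(gaining = tm$scheme$names[n], W = as.numeric(W),
       transitions = data.frame(
         from = tm$scheme$names[donors], R = as.numeric(R),
         targeted = as.numeric(R) > W, avoided = as.numeric(R) < W,
         row.names = NULL))
}

#' Transition-level intensity out of a losing category
#'
#' Loss-side analogue of [transition_level]: for losing category `m`,
#' `Q_tmj = (entry(m, j) / duration) / area_j(t+1) * 100` for each receiver
#' `j != m`, against `V_tm = (loss_m / duration) /
#' (total_area - area_m(t+1)) * 100`.
#'
#' @param tm a [transition_matrix].
#' @param losing class name or code of the losing category `m`.
#' @return list with `V` and a data frame per receiving category: `Q`,
#'   `targeted`, `avoided`.
#' @export
loss_side_transition_level <- function(tm, losing) {
  m <- match_class(tm$scheme, losing)
  area_t1 <- colSums(tm$entries)
  loss_m <- sum(tm$entries[m, ]) - tm$entries[m, m]
  denomV <- tm$total_area - area_t1[m]
  V <- if (denomV > 0) (loss_m / tm$duration) / denomV * 100 else NA_real_
  rec <- setdiff(seq_len(tm$scheme$J), m)
  Q <- ifelse(area_t1[rec] > 0,
              (tm$entries[m, rec] / tm$duration) / area_t1[rec] * 100,
              NA_real_)
  list(losing = tm$scheme$names[m], V = as.numeric(V),
       transitions = data.frame(
         to = tm$scheme$names[rec], Q = as.numeric(Q),
         targeted = as.numeric(Q) > V, avoided = as.numeric(Q) < V,
         row.names = NULL))
}

match_class <- function(scheme, x) {
  n <- if (is.character(x)) match(x, scheme$names) else match(x, scheme$codes)
  if (is.na(n)) stop(sprintf("class '%s' not in scheme", x), call. = FALSE)
  n
}

#' Stationarity of intensity flags across intervals
#'
#' A flag (active gainer/loser per category, targeted/avoided per
#' transition) is stationary iff it takes the same value in every interval.
#'
#' @param flags_by_interval list (one element per interval) of logical
#'   vectors with matching names.
#' @return data frame with columns `name`, `stationary`, and `value` (the
#'   common flag when stationary, `NA` otherwise). Flags that are `NA` in
#'   any interval are non-stationary unless `NA` in all.
#' @export
stationarity <- function(flags_by_interval) {
  stopifnot(length(flags_by_interval) >= 2L)
  nm <- names(flags_by_interval[[1]])
  mat <- do.call(rbind, lapply(flags_by_interval, function(f) f[nm]))
  same <- apply(mat, 2L, function(col) {
    if (all(is.na(col))) return(TRUE)
    if (any(is.na(col))) return(FALSE)
    all(col == col[1])
  })
  val <- ifelse(same, mat[1, ], NA)
  data.frame(name = nm, stationary = unname(same), value = unname(val),
             row.names = NULL)
}

#' Full intensity report for a matrix series
#'
#' Runs all three levels plus the loss side for every category and collects
#' the flags needed for stationarity checks.
#'
#' @param matrices list of [transition_matrix] objects in time order.
#' @param labels optional interval labels.
#' @param total_tol passed to [interval_level].
#' @return list with `interval` ([interval_level] output), `category`
#'   (per-interval data frames), `gain_side` / `loss_side` (per-interval,
#'   per-category transition tables) and `stationarity` (category-flag
#'   table from [stationarity]).
#' @export
intensity_report <- function(matrices, labels = NULL, total_tol = 0.005) {
  iv <- interval_level(matrices, labels, total_tol)
  U <- iv$U
  cats <- lapply(matrices, category_level, U = U)
  sch <- matrices[[1]]$scheme
  gain_side <- lapply(matrices, function(m) {
    stats::setNames(lapply(sch$names, function(n) transition_level(m, n)),
                    sch$names)
  })
  loss_side <- lapply(matrices, function(m) {
    stats::setNames(
      lapply(sch$names, function(n) loss_side_transition_level(m, n)),
      sch$names)
  })
  flags <- lapply(cats, function(cl) {
    stats::setNames(
      c(cl$active_gainer, cl$active_loser),
      c(paste0(cl$class, ".active_gainer"), paste0(cl$class, ".active_loser")))
  })
  list(interval = iv, category = cats, gain_side = gain_side,
       loss_side = loss_side,
       stationarity = if (length(matrices) >= 2L) stationarity(flags) else NULL)
}
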