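#' @title CA-Markov simulation of future land cover
#' @description Six-phase projection pipeline: screen covariates by pairwise
#'   correlation, estimate how much area changes from a Markov chain fitted
#'   to an observed interval, learn *where* it changes with a
#'   multilayer-perceptron transition-potential model over terrain
#'   covariates and neighbourhood composition, allocate change with a
#'   cellular-automaton rule, iterate, and validate against a held-out map.
#' @name camarkov
NULL

#' Pairwise Pearson correlation between covariates
#'
#' @param stack a `covariate_stack`.
#' @return correlation matrix over jointly valid cells; constant covariates
#'   get `NA` rows/columns (diagonal stays 1).
#' @export
covariate_correlation <- function(stack) {
  nms <- names(stack)
  if (length(nms) < 2L) stop("need at least two covariates", call. = FALSE)
  X <- do.call(cbind, lapply(stack, function(g) as.vector(g$values)))
  colnames(X) <- nms
  X <- X[stats::complete.cases(X), , drop = FALSE]
  sds <- apply(X, 2L, stats::sd)
  r <- suppressWarnings(stats::cor(X))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r) <- 1
  r
}

#' Markov projection of class areas
#'
#' Row-normalizes a transition matrix into transition probabilities `P` and
#' projects `areas_t %*% P^k`. A class with zero initial area keeps an
#' identity row (it persists).
#'
#' @param tm a [transition_matrix] estimated on an observed interval.
#' @param areas_t class areas (ha) at the projection origin; defaults to
#'   the matrix's column sums (the end of the fitted interval).
#' @param steps number of intervals to project.
#' @return list with `P` (the row-stochastic matrix) and `areas`, a
#'   `(steps + 1) x J` matrix of areas (step 0 = `areas_t`); the total is
#'   conserved at every step.
#' @export
markov_project <- function(tm, areas_t = NULL, steps = 1L) {
  if (is.null(areas_t)) areas_t <- colSums(tm$entries)
  rs <- rowSums(tm$entries)
  P <- tm$entries / ifelse(rs > 0, rs, 1)
  zero <- rs == 0
  if (any(zero)) {
    P[zero, ] <- 0
    diag(P)[zero] <- 1
  }
  out <- matrix(NA_real_, steps + 1L, tm$scheme$J,
                dimnames = list(step = 0:steps, class = tm$scheme$names))
  out[1L, ] <- areas_t
  a <- matrix(areas_t, 1L)
  for (k in seq_len(steps)) {
    a <- a %*% P
    out[k + 1L, ] <- a
  }
  list(P = unname(P), areas = out)
}

# feature matrix for the potential model: standardized covariates,
# current-class one-hot, Moore-neighbourhood class fractions
potential_features <- function(map, stack, scheme, covariates,
                               center = NULL, scale = NULL) {
  std <- covariate_features(stack, covariates, center, scale)
  v <- as.vector(map$values)
  onehot <- outer(v, scheme$codes, "==") * 1
  colnames(onehot) <- paste0("is_", scheme$names)
  fr <- moore_fractions(map, scheme)
  colnames(fr) <- paste0("nbr_", scheme$names)
  list(X = cbind(std$X, onehot, fr), center = std$center, scale = std$scale)
}

#' Fit an MLP transition-potential model
#'
#' One multilayer perceptron (single hidden layer, logistic units, softmax
#' output) is trained on a seeded, balanced sample of cells to predict the
#' class at the end of a calibration interval from standardized covariates,
#' the current class (one-hot) and Moore-neighbourhood class fractions.
#' Transitions observed fewer than `min_samples` times fall back to their
#' empirical base rate instead of the network's score.
#'
#' @param map_t,map_t1 aligned categorical grids bounding the calibration
#'   interval.
#' @param stack aligned `covariate_stack`.
#' @param seed RNG seed (sampling and initial weights).
#' @param scheme a [class_scheme].
#' @param hidden hidden-layer size (default 10).
#' @param maxit maximum training epochs (default 1000).
#' @param decay weight decay (default 0).
#' @param n_samples total training cells drawn, split evenly between
#'   changing and persisting cells where possible (default 20000).
#' @param min_samples minimum observations for a transition to be modelled
#'   by the network (default 50).
#' @param restarts number of seeded random weight initializations; the fit
#'   with the lowest final deviance is kept (guards against poor local
#'   optima of the single-hidden-layer network).
#' @return object of class `transition_potential_model`.
#' @export
fit_transition_potential <- function(map_t, map_t1, stack, seed = 1L,
                                     scheme = class_scheme(), hidden = 10L,
                                     maxit = 1000L, decay = 0,
                                     n_samples = 20000L, min_samples = 50L,
                                     restarts = 3L) {
  stopifnot_aligned(map_t, map_t1, "calibration maps")
  stopifnot_aligned(map_t, stack$dem, "land cover and covariates")
  a <- as.vector(map_t$values); b <- as.vector(map_t1$values)
  valid <- which(!is.na(a) & !is.na(b))
  changed <- valid[a[valid] != b[valid]]
  persisted <- valid[a[valid] == b[valid]]
  if (!length(changed)) {
    stop("no cells change class between the calibration maps", call. = FALSE)
  }
  set.seed(seed)
  half <- floor(n_samples / 2)
  take <- function(pool, k) {
    if (length(pool) <= k) pool else sample(pool, k)
  }
  samp <- c(take(changed, half), take(persisted, n_samples - half))
  feats <- potential_features(map_t, stack, scheme,
                              covariates = names(stack))
  J <- scheme$J
  # empirical per-transition counts and base rates (for fallbacks)
  counts <- table(factor(a[valid], levels = scheme$codes),
                  factor(b[valid], levels = scheme$codes))
  counts <- matrix(as.numeric(counts), J, J)
  base_rate <- counts / ifelse(rowSums(counts) > 0, rowSums(counts), 1)
  fallback <- counts < min_samples
  diag(fallback) <- FALSE
  y <- factor(b[samp], levels = scheme$codes)
  fit <- NULL
  for (rs in seq_len(max(restarts, 1L))) {
    set.seed(seed + rs - 1L)
    cand <- nnet::nnet(x = feats$X[samp, , drop = FALSE],
                       y = nnet::class.ind(y),
                       size = hidden, softmax = TRUE, maxit = maxit,
                       decay = decay, trace = FALSE, MaxNWts = 10000L)
    if (is.null(fit) || cand$value < fit$value) fit <- cand
  }
  pred <- scheme$codes[max.col(stats::predict(fit, feats$X[samp, , drop = FALSE]))]
  structure(list(net = fit, scheme = scheme, covariates = names(stack),
                 center = feats$center, scale = feats$scale,
                 base_rate = base_rate, fallback = fallback,
                 meta = list(seed = seed, hidden = hidden, maxit = maxit,
                             n_train = length(samp),
                             training_accuracy = mean(pred == b[samp]))),
            class = "transition_potential_model")
}

#' @export
print.transition_potential_model <- function(x, ...) {
  cat(sprintf(
    "<transition_potential_model> MLP %d hidden units, %d training cells, training accuracy %.3f\n",
    x$meta$hidden, x$meta$n_train, x$meta$training_accuracy))
  invisible(x)
}

#' Per-cell transition potentials
#'
#' Scores every cell of `map` with the model: column `j` holds the
#' potential of ending in class `j`. For transitions flagged as fallbacks
#' at fit time, the network score is replaced by the empirical base rate of
#' the cell's current class.
#'
#' @param model a `transition_potential_model`.
#' @param map categorical [grid] of current land cover.
#' @param stack aligned `covariate_stack`.
#' @return n x J matrix of potentials in `[0, 1]` (cells column-major).
#' @export
predict_potentials <- function(model, map, stack) {
  feats <- potential_features(map, stack, model$scheme, model$covariates,
                              center = model$center, scale = model$scale)
  pot <- stats::predict(model$net, feats$X)
  pot <- pmin(pmax(pot, 0), 1)
  v <- as.vector(map$values)
  sch <- model$scheme
  for (i in seq_len(sch$J)) {
    for (j in seq_len(sch$J)) {
      if (i != j && model$fallback[i, j]) {
        rows <- which(v == sch$codes[i])
        pot[rows, j] <- model$base_rate[i, j]
      }
    }
  }
  colnames(pot) <- sch$names
  pot
}

# largest-remainder rounding of non-negative x to integers summing to
# round(sum(x)); ties broken by index order
largest_remainder <- function(x, total = NULL) {
  if (is.null(total)) total <- round(sum(x))
  base <- floor(x)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(x - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Cellular-automaton allocation of change
#'
#' For each transition `i -> j` the `targets[i, j]` highest-scoring source
#' cells change class, where the score is
#' `potential * neighbour_fraction_j ^ w`; ties are broken by a seeded
#' shuffle. Transitions are processed in row-major scheme order and a cell
#' changes at most once. Realized counts equal the targets exactly.
#'
#' @param current categorical [grid].
#' @param potentials n x J potential matrix from [predict_potentials].
#' @param targets J x J integer matrix of cell counts to convert
#'   (diagonal ignored).
#' @param w neighbourhood weight (>= 0; `w = 0` ignores neighbourhoods).
#' @param seed RNG seed for tie-breaking.
#' @param scheme a [class_scheme].
#' @return categorical [grid] after allocation.
#' @export
ca_allocate <- function(current, potentials, targets, w = 1, seed = 1L,
                        scheme = class_scheme()) {
  stopifnot(w >= 0)
  set.seed(seed)
  v <- as.vector(current$values)
  fr <- moore_fractions(current, scheme)
  taken <- logical(length(v))
  out <- v
  for (i in seq_len(scheme$J)) {
    for (j in seq_len(scheme$J)) {
      if (i == j) next
      tgt <- targets[i, j]
      if (is.na(tgt) || tgt == 0) next
      cand <- which(v == scheme$codes[i] & !taken)
      if (tgt > length(cand)) {
        stop(sprintf(
          "transition %s->%s demands %d cells but only %d are available",
          scheme$names[i], scheme$names[j], tgt, length(cand)),
          call. = FALSE)
      }
      score <- potentials[cand, j] * fr[cand, j]^w
      ord <- order(-score, sample.int(length(cand)))
      pick <- cand[ord[seq_len(tgt)]]
      out[pick] <- scheme$codes[j]
      taken[pick] <- TRUE
    }
  }
  grid(matrix(out, nrow(current$values), ncol(current$values)),
       current$pixel_size, current$origin, current$nodata, "categorical")
}

#' Multi-step CA-Markov simulation
#'
#' Each step converts the Markov-expected transition counts (largest-
#' remainder rounded per source class) into a CA allocation scored by the
#' fitted potential model. Deterministic under a fixed seed.
#'
#' @param start categorical [grid] at the projection origin.
#' @param model a `transition_potential_model`.
#' @param stack aligned `covariate_stack`.
#' @param markov a [transition_matrix] defining per-step transition
#'   probabilities (typically the calibration interval's cross-tabulation).
#' @param steps number of intervals to project.
#' @param w neighbourhood weight passed to [ca_allocate].
#' @param seed RNG seed; step `k` allocates with `seed + k`.
#' @param scheme a [class_scheme].
#' @return list of `steps + 1` grids (first is `start`).
#' @export
simulate_landcover <- function(start, model, stack, markov, steps = 1L,
                               w = 1, seed = 1L, scheme = class_scheme()) {
  stopifnot(steps >= 1L)
  P <- markov_project(markov, steps = 1L)$P
  maps <- vector("list", steps + 1L)
  maps[[1L]] <- start
  cur <- start
  for (k in seq_len(steps)) {
    v <- as.vector(cur$values)
    counts_i <- vapply(scheme$codes, function(cd) sum(v == cd, na.rm = TRUE),
                       numeric(1))
    targets <- matrix(0L, scheme$J, scheme$J)
    for (i in seq_len(scheme$J)) {
      targets[i, ] <- largest_remainder(counts_i[i] * P[i, ],
                                        total = counts_i[i])
    }
    diag(targets) <- 0L
    pot <- predict_potentials(model, cur, stack)
    cur <- ca_allocate(cur, pot, targets, w = w, seed = seed + k,
                       scheme = scheme)
    maps[[k + 1L]] <- cur
  }
  maps
}

#' Validate a simulated map against a reference map
#'
#' @param simulated,reference aligned categorical grids.
#' @param scheme a [class_scheme].
#' @return list with `overall` (proportion correct), `kappa`, `Q`, `A`,
#'   `QADI` and the underlying `confusion_matrix`.
#' @export
validate_simulation <- function(simulated, reference,
                                scheme = class_scheme()) {
  cm <- build_confusion(reference, simulated, scheme)
  met <- accuracy_metrics(cm)
  dis <- disagreement(cm)
  list(overall = met$overall, kappa = met$kappa,
       Q = dis$Q, A = dis$A, QADI = dis$QADI, confusion = cm)
}
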