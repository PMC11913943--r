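#' @title Synthetic landscapes with known transition dynamics
#' @description Seeded generator for terrain covariate stacks and
#'   multi-date three-class land-cover series. Latent surfaces are white
#'   noise smoothed with a uniform kernel (an inexpensive stand-in for a
#'   Gaussian random field); land-cover change follows a per-cell logistic
#'   rule over standardized covariates plus the Moore-neighbourhood fraction
#'   of the destination class, so downstream models can be tested against
#'   known dynamics. Defaults mimic the scale of a ~350 ha reserve mapped at
#'   5 m: 374 x 374 cells, elevation 720-840 m, initial class fractions
#'   (woody 0.3769, grasses 0.6025, bare 0.0206), intervals of 5, 5 and 4
#'   years.
#' @name synthetic_landscape
NULL

# window sums and in-window counts over a (2*half+1)^2 window clipped at
# edges, via integral images
box_sum <- function(m, half) {
  nr <- nrow(m); nc <- ncol(m)
  ii <- function(x) {
    x <- apply(x, 2L, cumsum)
    x <- t(apply(x, 1L, cumsum))
    rbind(0, cbind(0, x))
  }
  I <- ii(m)
  r1 <- pmax(seq_len(nr) - half, 1L); r2 <- pmin(seq_len(nr) + half, nr)
  c1 <- pmax(seq_len(nc) - half, 1L); c2 <- pmin(seq_len(nc) + half, nc)
  sums <- I[r2 + 1L, c2 + 1L] - I[r1, c2 + 1L] - I[r2 + 1L, c1] + I[r1, c1]
  counts <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  list(sums = sums, counts = counts)
}

box_smooth <- function(m, half) {
  if (half < 1) return(m)
  bs <- box_sum(m, half)
  bs$sums / bs$counts
}

smoothed_noise <- function(nr, nc, half) box_smooth(matrix(stats::rnorm(nr * nc), nr, nc), half)

#' Parameters of a synthetic landscape
#'
#' @param shape `(rows, cols)` of the lattice.
#' @param pixel_size metres per cell edge.
#' @param dem_range `(min, max)` elevation in metres.
#' @param smoothness correlation length of the latent fields, in cells
#'   (half-width of the smoothing kernel).
#' @param class_fractions initial proportions of (woody, grasses, bare);
#'   must sum to 1.
#' @param seed integer RNG seed for the whole landscape.
#' @return object of class `landscape_params`.
#' @export
landscape_params <- function(shape = c(374, 374), pixel_size = 5,
                             dem_range = c(720, 840), smoothness = 15,
                             class_fractions = c(woody = 0.3769,
                                                 grasses = 0.6025,
                                                 bare = 0.0206),
                             seed = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 1), pixel_size > 0,
            dem_range[1] < dem_range[2])
  if (abs(sum(class_fractions) - 1) > 1e-9) {
    stop("class_fractions must sum to 1", call. = FALSE)
  }
  structure(list(shape = as.integer(shape), pixel_size = pixel_size,
                 dem_range = dem_range, smoothness = as.integer(smoothness),
                 class_fractions = class_fractions, seed = as.integer(seed)),
            class = "landscape_params")
}

#' Generate an aligned terrain covariate stack
#'
#' DEM = smoothed seeded noise rescaled exactly to `dem_range`; slope,
#' aspect and TWI derived from it; road distance measured from a seeded
#' random west-east polyline.
#'
#' @param params a [landscape_params].
#' @return object of class `covariate_stack`: named list of aligned grids
#'   (`dem`, `slope`, `aspect`, `twi`, `road_dist`) with the params and the
#'   road polyline attached as attributes.
#' @export
generate_covariates <- function(params) {
  set.seed(params$seed)
  nr <- params$shape[1]; nc <- params$shape[2]
  ps <- params$pixel_size
  z <- smoothed_noise(nr, nc, params$smoothness)
  z <- (z - min(z)) / (max(z) - min(z)) *
    diff(params$dem_range) + params$dem_range[1]
  dem <- grid(z, ps, origin = c(0, nr * ps), kind = "continuous")
  slope <- derive_slope(dem)
  aspect <- derive_aspect(dem)
  twi <- derive_twi(dem)
  # wandering west-east road across the extent
  k <- 8L
  xs <- seq(0, nc * ps, length.out = k)
  ys <- nr * ps * (0.5 + 0.4 * cumsum(stats::runif(k, -1, 1)) / sqrt(k))
  ys <- pmin(pmax(ys, 0.05 * nr * ps), 0.95 * nr * ps)
  road <- list(cbind(xs, ys))
  road_dist <- distance_from_lines(dem, road)
  structure(list(dem = dem, slope = slope, aspect = aspect, twi = twi,
                 road_dist = road_dist),
            params = params, road = road, class = "covariate_stack")
}

#' Allocate an initial land-cover map from a latent field
#'
#' Thresholds a smoothed seeded latent field at the quantiles matching
#' `class_fractions`, giving spatially clumped classes whose realized
#' fractions track the request closely (within ~1\% on lattices of 100 x
#' 100 and larger).
#'
#' @param covariates a `covariate_stack` (defines the lattice).
#' @param params the [landscape_params] used to build it.
#' @param scheme a [class_scheme]; classes are assigned to latent quantile
#'   bands in scheme order.
#' @return categorical [grid].
#' @export
generate_initial_landcover <- function(covariates, params,
                                       scheme = class_scheme()) {
  set.seed(params$seed + 1L)
  tmpl <- covariates$dem
  nr <- nrow(tmpl$values); nc <- ncol(tmpl$values)
  latent <- smoothed_noise(nr, nc, params$smoothness)
  fr <- params$class_fractions
  stopifnot(length(fr) == scheme$J)
  cuts <- stats::quantile(latent, cumsum(fr)[-scheme$J], names = FALSE)
  band <- findInterval(latent, cuts, left.open = TRUE) + 1L
  vals <- matrix(scheme$codes[band], nr, nc)
  grid(vals, tmpl$pixel_size, tmpl$origin, tmpl$nodata, "categorical")
}

#' Transition dynamics for the synthetic series
#'
#' Each cell of class `i` moves to class `j` in one interval with
#' probability `plogis(base_logit[i, j] + covariate_coefs[i, j, ] . x +
#' neighbor_coef * f_j)`, where `x` are the standardized covariates and
#' `f_j` the Moore-neighbourhood fraction of the destination class. When
#' `rates` are supplied instead of `base_logit`, intercepts are set to
#' `qlogis(rate) - neighbor_coef * ref_fraction_j` so that realized
#' landscape-level frequencies approximate `rates` (covariates are mean
#' zero; the neighbourhood term's mean is offset by the reference class
#' fraction).
#'
#' @param base_logit J x J matrix of per-transition intercepts (`-Inf`
#'   disables a transition; the diagonal is ignored), or `NULL` to derive
#'   from `rates`.
#' @param rates J x J matrix of target per-interval transition frequencies.
#' @param covariate_coefs J x J x K array of coefficients on the
#'   standardized covariates (default all zero).
#' @param neighbor_coef scalar coefficient on the destination-class Moore
#'   fraction.
#' @param durations years per interval; its length sets the number of steps.
#' @param covariates character vector naming the K covariates used.
#' @param ref_fractions class fractions used for the neighbourhood offset
#'   when deriving intercepts from `rates`.
#' @return object of class `dynamics_params`.
#' @export
dynamics_params <- function(base_logit = NULL, rates = NULL,
                            covariate_coefs = NULL, neighbor_coef = 0,
                            durations = c(5, 5, 4),
                            covariates = c("dem", "slope", "aspect", "twi",
                                           "road_dist"),
                            ref_fractions = NULL) {
  stopifnot(all(durations > 0))
  if (is.null(base_logit)) {
    if (is.null(rates)) stop("supply `base_logit` or `rates`", call. = FALSE)
    J <- nrow(rates)
    off <- if (is.null(ref_fractions)) rep(0, J) else ref_fractions
    base_logit <- stats::qlogis(as.matrix(rates)) -
      matrix(neighbor_coef * off, J, J, byrow = TRUE)
  }
  J <- nrow(base_logit)
  diag(base_logit) <- -Inf
  if (is.null(covariate_coefs)) {
    covariate_coefs <- array(0, dim = c(J, J, length(covariates)))
  }
  stopifnot(all(dim(covariate_coefs) == c(J, J, length(covariates))))
  structure(list(base_logit = base_logit, covariate_coefs = covariate_coefs,
                 neighbor_coef = neighbor_coef, durations = durations,
                 n_steps = length(durations), covariates = covariates),
            class = "dynamics_params")
}

#' Default woody-expansion dynamics at reserve scale
#'
#' Per-interval rates follow the observed first-interval transition
#' frequencies of an encroaching subtropical reserve (grass to woody
#' ~0.275, grass to bare ~0.075, woody to grass ~0.076, bare to grass
#' ~0.716 per 5-year step), with grass-to-woody conversion additionally
#' driven by elevation, wetness and distance to roads and clustered around
#' existing woody cover.
#'
#' @param neighbor_coef clustering strength (default 2.5).
#' @param dem_coef,twi_coef,road_coef covariate effects on the grass-to-
#'   woody transition (standardized scale).
#' @param durations years per interval.
#' @param ref_fractions class fractions used for the intercept offset.
#' @return a [dynamics_params].
#' @export
bisley_like_dynamics <- function(neighbor_coef = 2.5, dem_coef = 1,
                                 twi_coef = 0.5, road_coef = 0.5,
                                 durations = c(5, 5, 4),
                                 ref_fractions = c(0.3769, 0.6025, 0.0206)) {
  rates <- matrix(c(
    NA,     0.0764, 0.0108,   # from woody
    0.2751, NA,     0.0754,   # from grasses
    0.0989, 0.7156, NA        # from bare
  ), 3, 3, byrow = TRUE)
  rates[is.na(rates)] <- 0.5  # diagonal is overwritten with -Inf anyway
  coefs <- array(0, dim = c(3, 3, 5))
  coefs[2, 1, ] <- c(dem_coef, 0, 0, twi_coef, road_coef)
  dynamics_params(rates = rates, covariate_coefs = coefs,
                  neighbor_coef = neighbor_coef, durations = durations,
                  ref_fractions = ref_fractions)
}

# n x K matrix of standardized covariate values (constant fields -> 0)
covariate_features <- function(stack, covariates, center = NULL, scale = NULL) {
  X <- do.call(cbind, lapply(covariates, function(nm) {
    as.vector(stack[[nm]]$values)
  }))
  colnames(X) <- covariates
  if (is.null(center)) center <- colMeans(X, na.rm = TRUE)
  if (is.null(scale)) {
    scale <- apply(X, 2L, stats::sd, na.rm = TRUE)
    scale[scale == 0 | is.na(scale)] <- 1
  }
  list(X = sweep(sweep(X, 2L, center), 2L, scale, "/"),
       center = center, scale = scale)
}

#' Moore-neighbourhood class fractions
#'
#' For every cell, the fraction of its (up to 8) neighbours in each class;
#' edge cells are normalized by their actual neighbour count.
#'
#' @param map categorical [grid].
#' @param scheme a [class_scheme].
#' @return n x J matrix (cells in column-major order).
#' @export
moore_fractions <- function(map, scheme = class_scheme()) {
  v <- map$values
  nr <- nrow(v); nc <- ncol(v)
  nbr_count <- box_sum(matrix(1, nr, nc), 1L)$sums - 1
  out <- matrix(0, nr * nc, scheme$J)
  colnames(out) <- scheme$names
  for (k in seq_len(scheme$J)) {
    ind <- (v == scheme$codes[k]) * 1
    out[, k] <- as.vector((box_sum(ind, 1L)$sums - ind) / nbr_count)
  }
  out
}

#' Simulate a multi-date land-cover series with logistic dynamics
#'
#' @param initial categorical [grid] at the first date.
#' @param covariates aligned `covariate_stack`.
#' @param dyn a [dynamics_params].
#' @param seed integer RNG seed.
#' @param scheme a [class_scheme].
#' @return list of `dyn$n_steps + 1` categorical grids (the first is
#'   `initial`), with attributes `standardization` (the covariate centring/
#'   scaling constants used in the rule), `durations` and `seed`.
#' @export
simulate_series <- function(initial, covariates, dyn, seed = 1L,
                            scheme = class_scheme()) {
  stopifnot_aligned(initial, covariates$dem, "land cover and covariates")
  set.seed(seed)
  std <- covariate_features(covariates, dyn$covariates)
  X <- std$X
  n <- nrow(X)
  J <- scheme$J
  maps <- vector("list", dyn$n_steps + 1L)
  maps[[1L]] <- initial
  cur <- initial
  for (step in seq_len(dyn$n_steps)) {
    fr <- moore_fractions(cur, scheme)
    curv <- as.vector(cur$values)
    P <- matrix(0, n, J)
    for (i in seq_len(J)) {
      rows <- which(curv == scheme$codes[i])
      if (!length(rows)) next
      for (j in seq_len(J)) {
        if (j == i || !is.finite(dyn$base_logit[i, j])) next
        eta <- dyn$base_logit[i, j] +
          as.vector(X[rows, , drop = FALSE] %*% dyn$covariate_coefs[i, j, ]) +
          dyn$neighbor_coef * fr[rows, j]
        P[rows, j] <- stats::plogis(eta)
      }
    }
    s <- rowSums(P)
    over <- s > 1
    if (any(over)) P[over, ] <- P[over, , drop = FALSE] / s[over]
    u <- stats::runif(n)
    dest <- integer(n)
    cum <- numeric(n)
    for (j in seq_len(J)) {
      cum <- cum + P[, j]
      hit <- dest == 0L & P[, j] > 0 & u < cum
      dest[hit] <- j
    }
    newv <- curv
    moved <- dest > 0L
    newv[moved] <- scheme$codes[dest[moved]]
    cur <- grid(matrix(newv, nrow(cur$values), ncol(cur$values)),
                cur$pixel_size, cur$origin, cur$nodata, "categorical")
    maps[[step + 1L]] <- cur
  }
  attr(maps, "standardization") <- std[c("center", "scale")]
  attr(maps, "durations") <- dyn$durations
  attr(maps, "seed") <- seed
  maps
}

#' Write a synthetic series plus manifest to a directory
#'
#' Covariates and each date's map are written as GeoTIFF, alongside a JSON
#' manifest recording every parameter and seed.
#'
#' @param series output of [simulate_series].
#' @param covariates the `covariate_stack` used.
#' @param params the [landscape_params] used.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_series <- function(series, covariates, params, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(covariates)) {
    write_grid(covariates[[nm]], file.path(dir, paste0(nm, ".tif")))
  }
  for (k in seq_along(series)) {
    write_grid(series[[k]], file.path(dir, sprintf("landcover_t%d.tif", k - 1L)))
  }
  manifest <- list(
    params = unclass(params),
    durations = attr(series, "durations"),
    seed = attr(series, "seed"),
    standardization = attr(series, "standardization"),
    files = c(paste0(names(covariates), ".tif"),
              sprintf("landcover_t%d.tif", seq_along(series) - 1L))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
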