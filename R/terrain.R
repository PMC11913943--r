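#' @title Terrain covariates from a DEM
#' @description Slope and aspect use the Horn 3x3 kernel; the topographic
#'   wetness index uses single-direction (D8) flow accumulation. These are
#'   the covariates commonly fed to land-cover transition models alongside
#'   Euclidean distance to roads.
#' @name terrain
NULL

# Pad a matrix by one cell of linear extrapolation (2*edge - inner), so that
# 3x3 kernels at the border behave like one-sided differences. NA propagates.
pad_extrapolate <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  top <- if (nr > 1) 2 * m[1, ] - m[2, ] else m[1, ]
  bot <- if (nr > 1) 2 * m[nr, ] - m[nr - 1, ] else m[nr, ]
  m2 <- rbind(top, m, bot)
  left <- if (nc > 1) 2 * m2[, 1] - m2[, 2] else m2[, 1]
  right <- if (nc > 1) 2 * m2[, nc] - m2[, nc - 1] else m2[, nc]
  unname(cbind(left, m2, right))
}

shift_mat <- function(mp, dr, dc, nr, nc) {
  # mp is the padded matrix; returns the nr x nc window offset by (dr, dc)
  mp[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc), drop = FALSE]
}

horn_gradients <- function(dem) {
  z <- dem$values
  if (all(is.na(z))) stop("DEM contains no valid cells", call. = FALSE)
  nr <- nrow(z); nc <- ncol(z)
  zp <- pad_extrapolate(z)
  a <- shift_mat(zp, -1, -1, nr, nc); b <- shift_mat(zp, -1, 0, nr, nc)
  cc <- shift_mat(zp, -1, 1, nr, nc)
  d <- shift_mat(zp, 0, -1, nr, nc);  f <- shift_mat(zp, 0, 1, nr, nc)
  g <- shift_mat(zp, 1, -1, nr, nc);  h <- shift_mat(zp, 1, 0, nr, nc)
  i <- shift_mat(zp, 1, 1, nr, nc)
  ps <- dem$pixel_size
  dzdx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * ps)  # toward east
  dzdy <- ((a + 2 * b + cc) - (g + 2 * h + i)) / (8 * ps)  # toward north
  list(dzdx = dzdx, dzdy = dzdy)
}

#' Slope in degrees from a DEM
#'
#' Horn 3x3 finite differences; border cells use one-sided differences (via
#' linear extrapolation of the border), and any window touching a nodata
#' cell yields `NA`.
#'
#' @param dem continuous [grid] of elevations in metres.
#' @return [grid] of slope in degrees, in `[0, 90)`.
#' @export
derive_slope <- function(dem) {
  gr <- horn_gradients(dem)
  slope <- atan(sqrt(gr$dzdx^2 + gr$dzdy^2)) * 180 / pi
  grid(slope, dem$pixel_size, dem$origin, dem$nodata, "continuous")
}

#' Aspect in degrees from a DEM
#'
#' Azimuth of the steepest *downslope* direction, clockwise from north,
#' in `[0, 360)`. Flat cells (zero gradient) get the sentinel `-1`.
#'
#' @inheritParams derive_slope
#' @return [grid] of aspect in degrees.
#' @export
derive_aspect <- function(dem) {
  gr <- horn_gradients(dem)
  down_e <- -gr$dzdx; down_n <- -gr$dzdy
  asp <- atan2(down_e, down_n) * 180 / pi
  asp <- ifelse(asp < 0, asp + 360, asp)
  flat <- !is.na(down_e) & abs(gr$dzdx) < 1e-12 & abs(gr$dzdy) < 1e-12
  asp[flat] <- -1
  grid(asp, dem$pixel_size, dem$origin, dem$nodata, "continuous")
}

# D8 receiver index for every cell: the index (in column-major order) of the
# steepest-descent neighbour, or NA for pits/flats. Tie-break follows the
# fixed neighbour order N, NE, E, SE, S, SW, W, NW (first strict maximum
# kept).
d8_receivers <- function(z, ps) {
  nr <- nrow(z); nc <- ncol(z)
  drs <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  dcs <- c(0, 1, 1, 1, 0, -1, -1, -1)
  dist <- ifelse(drs != 0 & dcs != 0, sqrt(2) * ps, ps)
  best_drop <- matrix(-Inf, nr, nc)
  recv <- matrix(NA_integer_, nr, nc)
  idx <- matrix(seq_len(nr * nc), nr, nc)
  for (k in seq_len(8)) {
    rs <- seq_len(nr) + drs[k]; cs <- seq_len(nc) + dcs[k]
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    zn <- matrix(NA_real_, nr, nc)
    zn[ok_r, ok_c] <- z[rs[ok_r], cs[ok_c]]
    nidx <- matrix(NA_integer_, nr, nc)
    nidx[ok_r, ok_c] <- idx[rs[ok_r], cs[ok_c]]
    drop <- (z - zn) / dist[k]
    better <- !is.na(drop) & drop > 0 & drop > best_drop
    best_drop[better] <- drop[better]
    recv[better] <- nidx[better]
  }
  recv
}

#' Topographic wetness index from a DEM
#'
#' `TWI = ln(a / max(tan(beta), eps))` with `a` the specific catchment area
#' (D8 flow accumulation x cell area / cell width, the cell itself included)
#' and `beta` the Horn slope. Flow follows the single steepest-descent
#' neighbour; pits accumulate without breaching. The floor `eps` keeps flat
#' cells finite.
#'
#' @inheritParams derive_slope
#' @param eps floor on `tan(beta)` (default `1e-6`).
#' @return [grid] of TWI (dimensionless), finite wherever the DEM is valid.
#' @export
derive_twi <- function(dem, eps = 1e-6) {
  z <- dem$values
  if (all(is.na(z))) stop("DEM contains no valid cells", call. = FALSE)
  nr <- nrow(z); nc <- ncol(z)
  recv <- d8_receivers(z, dem$pixel_size)
  acc <- rep(1, nr * nc)
  acc[is.na(z)] <- NA_real_
  ord <- order(z, decreasing = TRUE, na.last = NA)
  rv <- as.vector(recv)
  for (i in ord) {
    r <- rv[i]
    if (!is.na(r) && !is.na(acc[r])) acc[r] <- acc[r] + acc[i]
  }
  sca <- acc * dem$pixel_size  # cells * ps^2 / ps
  slope_rad <- derive_slope(dem)$values * pi / 180
  tanb <- pmax(tan(slope_rad), eps)
  twi <- matrix(log(sca / as.vector(tanb)), nr, nc)
  twi[is.na(z)] <- NA_real_
  grid(twi, dem$pixel_size, dem$origin, dem$nodata, "continuous")
}

# squared distance from points (px, py) to segment (x1,y1)-(x2,y2)
seg_dist2 <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) {
    return((px - x1)^2 + (py - y1)^2)
  }
  t <- ((px - x1) * dx + (py - y1) * dy) / len2
  t <- pmin(pmax(t, 0), 1)
  (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
}

#' Euclidean distance from cell centres to the nearest polyline
#'
#' @param template [grid] defining the output lattice.
#' @param lines a list of polylines, each an n x 2 matrix of map coordinates
#'   `(x, y)`, or a path to a GeoJSON file with LineString /
#'   MultiLineString geometries (see [read_lines_geojson]).
#' @return continuous [grid] of distances in map units (metres).
#' @export
distance_from_lines <- function(template, lines) {
  if (is.character(lines)) lines <- read_lines_geojson(lines)
  if (!is.list(lines) || length(lines) == 0) {
    stop("`lines` must be a non-empty list of coordinate matrices",
         call. = FALSE)
  }
  ctr <- cell_centers(template)
  nr <- nrow(template$values); nc <- ncol(template$values)
  px <- rep(ctr$x, each = nr)
  py <- rep(ctr$y, times = nc)
  d2 <- rep(Inf, nr * nc)
  for (ln in lines) {
    ln <- as.matrix(ln)
    if (nrow(ln) == 1L) {
      d2 <- pmin(d2, seg_dist2(px, py, ln[1, 1], ln[1, 2], ln[1, 1], ln[1, 2]))
      next
    }
    for (s in seq_len(nrow(ln) - 1L)) {
      d2 <- pmin(d2, seg_dist2(px, py, ln[s, 1], ln[s, 2],
                               ln[s + 1, 1], ln[s + 1, 2]))
    }
  }
  grid(matrix(sqrt(d2), nr, nc), template$pixel_size, template$origin,
       template$nodata, "continuous")
}

#' Read polylines from a GeoJSON file
#'
#' Accepts LineString and MultiLineString geometries, bare, as Features or
#' inside a FeatureCollection.
#'
#' @param path GeoJSON file path.
#' @return list of n x 2 coordinate matrices.
#' @export
read_lines_geojson <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- list()
  grab <- function(geom) {
    if (is.null(geom$type)) return()
    coords_to_mat <- function(cc) {
      do.call(rbind, lapply(cc, function(p) c(p[[1]], p[[2]])))
    }
    if (geom$type == "LineString") {
      out[[length(out) + 1L]] <<- coords_to_mat(geom$coordinates)
    } else if (geom$type == "MultiLineString") {
      for (part in geom$coordinates) {
        out[[length(out) + 1L]] <<- coords_to_mat(part)
      }
    }
  }
  if (identical(js$type, "FeatureCollection")) {
    for (f in js$features) grab(f$geometry)
  } else if (identical(js$type, "Feature")) {
    grab(js$geometry)
  } else grab(js)
  if (length(out) == 0) stop("no LineString geometries found", call. = FALSE)
  out
}
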