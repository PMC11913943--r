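#' Construct a single-band raster grid
#'
#' A `grid` is the package's raster container: a numeric matrix in row-major
#' map order (row 1 is the northernmost row, column 1 the westernmost
#' column), plus the geometry needed to place it in a projected coordinate
#' system. Missing cells are held as `NA` internally; the `nodata` sentinel
#' is only used on disk.
#'
#' @param values numeric matrix. For `kind = "categorical"` all non-missing
#'   values must be whole numbers (class codes).
#' @param pixel_size cell edge length in metres (> 0).
#' @param origin numeric length-2, map coordinates `(x, y)` of the *top-left
#'   corner* of the top-left cell. The centre of cell `(r, c)` is at
#'   `origin + ((c - 0.5) * pixel_size, -(r - 0.5) * pixel_size)`.
#' @param nodata sentinel value used when writing to disk.
#' @param kind `"continuous"` or `"categorical"`.
#' @return an object of class `grid`.
#' @export
grid <- function(values, pixel_size, origin = c(0, 0), nodata = -9999,
                 kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number", call. = FALSE)
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("grid must have at least one row and one column", call. = FALSE)
  }
  storage.mode(values) <- "double"
  if (kind == "categorical") {
    v <- values[!is.na(values)]
    if (length(v) && any(abs(v - round(v)) > 1e-9)) {
      stop("categorical grid contains non-integer values", call. = FALSE)
    }
    values[] <- round(values)
  }
  structure(
    list(values = values, pixel_size = as.numeric(pixel_size),
         origin = as.numeric(origin), nodata = as.numeric(nodata),
         kind = kind),
    class = "grid"
  )
}

#' @export
print.grid <- function(x, ...) {
  cat(sprintf("<grid> %d x %d cells, %g m pixels, %s\n",
              nrow(x$values), ncol(x$values), x$pixel_size, x$kind))
  cat(sprintf("  origin (%g, %g), nodata %g, %d NA cells\n",
              x$origin[1], x$origin[2], x$nodata, sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.grid <- function(x) dim(x$values)

#' Test whether two grids share the same lattice
#'
#' Grids are aligned iff they have identical shape, pixel size and origin.
#' All multi-grid operations in the package require alignment.
#'
#' @param a,b grids.
#' @param tol numeric tolerance on pixel size and origin.
#' @return logical scalar.
#' @export
is_aligned <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$pixel_size - b$pixel_size) <= tol &&
    all(abs(a$origin - b$origin) <= tol)
}

stopifnot_aligned <- function(a, b, what = "grids") {
  if (!is_aligned(a, b)) {
    stop(sprintf("%s are not aligned (shape, pixel size and origin must match)",
                 what), call. = FALSE)
  }
  invisible(TRUE)
}

#' Map coordinates of cell centres
#'
#' @param g a grid.
#' @return list with `x` (length ncol) and `y` (length nrow) centre
#'   coordinates; row 1 is northernmost so `y` decreases.
#' @export
cell_centers <- function(g) {
  list(x = g$origin[1] + (seq_len(ncol(g$values)) - 0.5) * g$pixel_size,
       y = g$origin[2] - (seq_len(nrow(g$values)) - 0.5) * g$pixel_size)
}

#' Cell area in hectares
#' @param g a grid.
#' @return pixel area in ha (pixel_size^2 / 10000).
#' @export
cell_area_ha <- function(g) g$pixel_size^2 / 1e4

# ---------------------------------------------------------------------------
# ESRI ASCII grid I/O

read_ascii_grid <- function(path) {
  lines <- readLines(path, n = 6L, warn = FALSE)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  req <- c("ncols", "nrows", "cellsize")
  if (!all(req %in% names(hdr))) {
    stop(sprintf("'%s' is not a readable ESRI ASCII grid (missing header)", path),
         call. = FALSE)
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  if (!is.null(hdr$xllcorner)) {
    x0 <- hdr$xllcorner; yll <- hdr$yllcorner
  } else if (!is.null(hdr$xllcenter)) {
    x0 <- hdr$xllcenter - cs / 2; yll <- hdr$yllcenter - cs / 2
  } else stop("ASCII grid header lacks a lower-left reference", call. = FALSE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(path, what = double(), skip = n_hdr, quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop(sprintf("ASCII grid '%s': expected %d values, found %d",
                 path, nr * nc, length(vals)), call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  list(values = m, pixel_size = cs, origin = c(x0, yll + nr * cs),
       nodata = nodata)
}

write_ascii_grid <- function(g, path) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  yll <- g$origin[2] - nr * g$pixel_size
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.17g", g$origin[1]),
    sprintf("yllcorner %.17g", yll),
    sprintf("cellsize %.17g", g$pixel_size),
    sprintf("NODATA_value %.17g", g$nodata)
  )
  v <- g$values
  v[is.na(v)] <- g$nodata
  rows <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Minimal single-band GeoTIFF I/O (uncompressed, little-endian).
#
# Installed R imaging packages only handle display-range TIFFs, so the
# package carries its own reader/writer for the small subset of GeoTIFF it
# needs: one band, no compression, integer or IEEE-float samples, geometry
# in ModelPixelScale + ModelTiepoint, nodata in the GDAL_NODATA ASCII tag.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `12` = 8L)

read_tiff_value <- function(con, type, count, raw4) {
  size <- TIFF_TYPE_SIZE[as.character(type)]
  if (is.na(size)) return(NULL)
  nbytes <- size * count
  if (nbytes <= 4L) {
    data <- raw4[seq_len(nbytes)]
  } else {
    offset <- readBin(raw4, "integer", 1L, size = 4L, endian = "little")
    pos <- seek(con)
    seek(con, offset)
    data <- readBin(con, "raw", nbytes)
    seek(con, pos)
  }
  switch(as.character(type),
    `1` = as.numeric(readBin(data, "integer", count, size = 1L, signed = FALSE)),
    `2` = rawToChar(data[data != as.raw(0)]),
    `3` = as.numeric(readBin(data, "integer", count, size = 2L, signed = FALSE,
                             endian = "little")),
    `4` = as.numeric(readBin(data, "integer", count, size = 4L,
                             endian = "little")),
    `12` = readBin(data, "double", count, size = 8L, endian = "little")
  )
}

read_geotiff <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (!identical(magic[1:2], charToRaw("II"))) {
    stop(sprintf("'%s' is not a little-endian TIFF", path), call. = FALSE)
  }
  ifd_off <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  seek(con, ifd_off)
  n_entries <- readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                       endian = "little")
  tags <- list()
  for (i in seq_len(n_entries)) {
    tag <- readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = "little")
    type <- readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = "little")
    count <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    raw4 <- readBin(con, "raw", 4L)
    tags[[as.character(tag)]] <- read_tiff_value(con, type, count, raw4)
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop(sprintf("TIFF tag %d missing in '%s'", tag, path),
                                 call. = FALSE)
      default
    } else v
  }
  width <- need(256); height <- need(257)
  spp <- need(277, 1)
  if (spp != 1) stop("multi-band TIFF input is not supported", call. = FALSE)
  bits <- need(258)
  if (need(259, 1) != 1) stop("compressed TIFF input is not supported", call. = FALSE)
  sf <- need(339, 1)
  offsets <- need(273); counts <- need(279)
  vals <- numeric(0)
  for (k in seq_along(offsets)) {
    seek(con, offsets[k])
    n <- counts[k] / (bits / 8)
    v <- switch(as.character(sf),
      `1` = if (bits == 8) as.numeric(readBin(con, "integer", n, size = 1L, signed = FALSE))
            else if (bits == 16) as.numeric(readBin(con, "integer", n, size = 2L, signed = FALSE, endian = "little"))
            else as.numeric(readBin(con, "integer", n, size = 4L, endian = "little")),
      `2` = as.numeric(readBin(con, "integer", n, size = bits / 8, signed = TRUE, endian = "little")),
      `3` = readBin(con, "double", n, size = bits / 8, endian = "little"),
      stop("unsupported TIFF sample format", call. = FALSE))
    vals <- c(vals, v)
  }
  if (length(vals) != width * height) {
    stop(sprintf("TIFF '%s' has truncated image data", path), call. = FALSE)
  }
  m <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)
  scale <- need(33550, c(1, 1, 0))
  tie <- need(33922, c(0, 0, 0, 0, 0, 0))
  nodata <- suppressWarnings(as.numeric(need(42113, "-9999")))
  if (is.na(nodata)) nodata <- -9999
  origin <- c(tie[4] - tie[1] * scale[1], tie[5] + tie[2] * scale[2])
  m[m == nodata] <- NA_real_
  list(values = m, pixel_size = scale[1], origin = origin, nodata = nodata)
}

tiff_entry <- function(tag, type, count, value_raw4) {
  c(writeBin(as.integer(tag), raw(), size = 2L, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2L, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4L, endian = "little"),
    value_raw4)
}

raw4_short <- function(x) {
  c(writeBin(as.integer(x), raw(), size = 2L, endian = "little"), raw(2))
}
raw4_long <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

write_geotiff <- function(g, path) {
  v <- t(g$values)  # column-major of transpose = row-major scan order
  v[is.na(v)] <- g$nodata
  nr <- nrow(g$values); nc <- ncol(g$values)
  data_off <- 8L
  data_len <- nr * nc * 8L
  scale_off <- data_off + data_len
  tie_off <- scale_off + 24L
  nod_str <- sprintf("%.17g", g$nodata)
  nod_raw <- c(charToRaw(nod_str), as.raw(0))
  nod_off <- tie_off + 48L
  ifd_off <- nod_off + length(nod_raw)
  if (ifd_off %% 2L == 1L) ifd_off <- ifd_off + 1L

  entries <- list(
    tiff_entry(256, 3, 1, raw4_short(nc)),            # ImageWidth
    tiff_entry(257, 3, 1, raw4_short(nr)),            # ImageLength
    tiff_entry(258, 3, 1, raw4_short(64)),            # BitsPerSample
    tiff_entry(259, 3, 1, raw4_short(1)),             # Compression = none
    tiff_entry(262, 3, 1, raw4_short(1)),             # BlackIsZero
    tiff_entry(273, 4, 1, raw4_long(data_off)),       # StripOffsets
    tiff_entry(277, 3, 1, raw4_short(1)),             # SamplesPerPixel
    tiff_entry(278, 3, 1, raw4_short(nr)),            # RowsPerStrip
    tiff_entry(279, 4, 1, raw4_long(data_len)),       # StripByteCounts
    tiff_entry(339, 3, 1, raw4_short(3)),             # SampleFormat = IEEE float
    tiff_entry(33550, 12, 3, raw4_long(scale_off)),   # ModelPixelScale
    tiff_entry(33922, 12, 6, raw4_long(tie_off)),     # ModelTiepoint
    tiff_entry(42113, 2, length(nod_raw), raw4_long(nod_off))  # GDAL_NODATA
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(as.integer(ifd_off), con, size = 4L, endian = "little")
  writeBin(as.vector(v), con, size = 8L, endian = "little")
  writeBin(c(g$pixel_size, g$pixel_size, 0), con, size = 8L, endian = "little")
  writeBin(c(0, 0, 0, g$origin[1], g$origin[2], 0), con, size = 8L,
           endian = "little")
  writeBin(nod_raw, con)
  if (seek(con) %% 2L == 1L) writeBin(as.raw(0), con)
  writeBin(length(entries), con, size = 2L, endian = "little")
  for (e in entries) writeBin(e, con)
  writeBin(0L, con, size = 4L, endian = "little")  # no next IFD
  invisible(path)
}

# ---------------------------------------------------------------------------

#' Read a single-band raster
#'
#' Supports uncompressed single-band GeoTIFF (`.tif`/`.tiff`) and ESRI ASCII
#' grids (any other extension). On-disk nodata cells become `NA`.
#'
#' @param path file path.
#' @param kind `"continuous"` or `"categorical"`; categorical files must
#'   contain whole-number codes only.
#' @return a [grid].
#' @export
read_grid <- function(path, kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path),
                               call. = FALSE)
  raw <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    read_geotiff(path)
  } else {
    read_ascii_grid(path)
  }
  grid(raw$values, pixel_size = raw$pixel_size, origin = raw$origin,
       nodata = raw$nodata, kind = kind)
}

#' Write a grid to disk
#'
#' Format chosen by extension: `.tif`/`.tiff` writes an uncompressed
#' float64 GeoTIFF, anything else an ESRI ASCII grid. Both round-trip
#' values, geometry and nodata exactly.
#'
#' @param g a [grid].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(g, path) {
  stopifnot(inherits(g, "grid"))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) write_geotiff(g, path)
  else write_ascii_grid(g, path)
  invisible(path)
}

#' Resample a grid onto another grid's lattice
#'
#' @param g source [grid].
#' @param template [grid] whose lattice the output adopts.
#' @param method `"nearest"` (required for categorical grids) or
#'   `"bilinear"`. Bilinear interpolates between the four surrounding source
#'   cell centres, so output values stay within the local neighbourhood's
#'   range; outside the source centre hull it clamps to the edge value.
#' @return a [grid] aligned with `template`.
#' @export
resample_to <- function(g, template, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  if (g$kind == "categorical" && method != "nearest") {
    stop("bilinear resampling is invalid for categorical grids", call. = FALSE)
  }
  if (is_aligned(g, template)) {
    out <- g
    return(out)
  }
  src <- g$values
  tc <- cell_centers(template)
  # fractional (row, col) position of template centres in source index space
  u <- (tc$x - g$origin[1]) / g$pixel_size + 0.5   # columns
  v <- (g$origin[2] - tc$y) / g$pixel_size + 0.5   # rows
  nrow_s <- nrow(src); ncol_s <- ncol(src)
  if (method == "nearest") {
    ci <- pmin(pmax(round(u), 1), ncol_s)
    ri <- pmin(pmax(round(v), 1), nrow_s)
    vals <- outer(ri, ci, function(r, c) src[cbind(r, c)])
  } else {
    u <- pmin(pmax(u, 1), ncol_s); v <- pmin(pmax(v, 1), nrow_s)
    c0 <- pmin(floor(u), max(ncol_s - 1L, 1L)); fx <- u - c0
    r0 <- pmin(floor(v), max(nrow_s - 1L, 1L)); fy <- v - r0
    c1 <- pmin(c0 + 1L, ncol_s); r1 <- pmin(r0 + 1L, nrow_s)
    vals <- matrix(NA_real_, length(v), length(u))
    for (i in seq_along(v)) {
      z00 <- src[r0[i], c0]; z01 <- src[r0[i], c1]
      z10 <- src[r1[i], c0]; z11 <- src[r1[i], c1]
      top <- z00 * (1 - fx) + z01 * fx
      bot <- z10 * (1 - fx) + z11 * fx
      vals[i, ] <- top * (1 - fy[i]) + bot * fy[i]
    }
  }
  grid(vals, pixel_size = template$pixel_size, origin = template$origin,
       nodata = template$nodata, kind = g$kind)
}
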