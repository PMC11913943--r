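#' @title Run-level reporting
#' @description Assembles the tables a change-analysis run produces
#'   (areas/percent per year, transitions per interval, intensity levels,
#'   projections, validation metrics) into a report directory with a single
#'   machine-readable JSON summary. The report layer never recomputes
#'   science: every headline number is copied from an upstream CSV/JSON
#'   cell, except percent covers, which are deliberately recomputed from
#'   hectares and the run's constant region area so that inconsistent
#'   percent columns in input tables cannot propagate.
#' @name reporting
NULL

# canonical JSON: names sorted recursively so hashes ignore field order
canonical_json <- function(x) {
  sort_rec <- function(v) {
    if (is.list(v) && !is.null(names(v)) && length(v)) {
      v <- v[order(names(v))]
      lapply(v, sort_rec)
    } else if (is.list(v)) lapply(v, sort_rec) else v
  }
  jsonlite::toJSON(sort_rec(x), auto_unbox = TRUE, digits = NA)
}

#' Stable hash of a configuration object
#'
#' MD5 of the canonical (recursively name-sorted) JSON encoding, so the
#' hash is invariant to field reordering.
#'
#' @param config a (nested) list.
#' @return hex string.
#' @export
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(canonical_json(config)), tf)
  unname(tools::md5sum(tf))
}

#' Manifest of a pipeline run
#'
#' @param inputs character vector of input paths.
#' @param config configuration list (hashed with [config_hash]).
#' @param outputs character vector of produced files.
#' @param seed integer seed(s) used.
#' @return named list (class `run_manifest`).
#' @export
run_manifest <- function(inputs, config, outputs, seed) {
  structure(list(inputs = inputs, config_hash = config_hash(config),
                 seed = seed, outputs = sort(outputs)),
            class = "run_manifest")
}

read_if <- function(path, reader) if (file.exists(path)) reader(path) else NULL

#' Build a report bundle from a run directory
#'
#' Looks for the standard stage outputs (`areas_by_year.csv` with a `class`
#' column and `y<year>` area columns; `transitions.csv` with `from`, `to`,
#' `interval`, `area_ha`; `intensity_interval.csv`; `projection.csv`;
#' `validation.json`), writes derived CSV tables plus `summary.json` under
#' `<run_dir>/report/`, and lists missing stages under `gaps` instead of
#' failing. Re-running on the same directory reproduces the summary
#' byte-for-byte.
#'
#' @param run_dir directory containing stage outputs.
#' @return the summary list, invisibly; side effect: files under
#'   `<run_dir>/report/`.
#' @export
build_report <- function(run_dir) {
  out_dir <- file.path(run_dir, "report")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gaps <- character(0)
  summary <- list()

  areas <- read_if(file.path(run_dir, "areas_by_year.csv"), utils::read.csv)
  if (is.null(areas)) {
    gaps <- c(gaps, "areas_by_year.csv")
  } else {
    ycols <- grep("^y[0-9]+$", names(areas), value = TRUE)
    m <- as.matrix(areas[, ycols, drop = FALSE])
    rownames(m) <- areas$class
    total <- sum(m[, 1])
    pc <- round(m / total * 100, 2)
    pc_df <- data.frame(class = rownames(pc), pc, check.names = FALSE,
                        row.names = NULL)
    utils::write.csv(pc_df, file.path(out_dir, "percent_cover.csv"),
                     row.names = FALSE)
    net <- data.frame(class = rownames(m),
                      net_change_ha = m[, ncol(m)] - m[, 1],
                      net_change_pct = round((m[, ncol(m)] - m[, 1]) /
                                               total * 100, 2),
                      row.names = NULL)
    utils::write.csv(net, file.path(out_dir, "net_change.csv"),
                     row.names = FALSE)
    summary$total_area_ha <- total
    summary$percent_cover <- stats::setNames(
      lapply(seq_len(nrow(pc)), function(r) as.list(pc[r, ])), rownames(pc))
    summary$net_change_ha <- stats::setNames(as.list(net$net_change_ha),
                                             net$class)
    summary$net_change_pct <- stats::setNames(as.list(net$net_change_pct),
                                              net$class)
  }

  trans <- read_if(file.path(run_dir, "transitions.csv"), utils::read.csv)
  if (is.null(trans)) gaps <- c(gaps, "transitions.csv")
  else {
    summary$transitions <- lapply(split(trans, trans$interval), function(d) {
      stats::setNames(as.list(d$area_ha), paste(d$from, d$to, sep = "->"))
    })
  }

  ii <- read_if(file.path(run_dir, "intensity_interval.csv"), utils::read.csv)
  if (is.null(ii)) gaps <- c(gaps, "intensity_interval.csv")
  else {
    summary$interval_intensity <- stats::setNames(as.list(ii$S), ii$label)
    if ("U" %in% names(ii)) summary$uniform_intensity <- ii$U[1]
  }

  proj <- read_if(file.path(run_dir, "projection.csv"), utils::read.csv)
  if (is.null(proj)) gaps <- c(gaps, "projection.csv")
  else summary$projection <- proj

  val <- read_if(file.path(run_dir, "validation.json"), jsonlite::fromJSON)
  if (is.null(val)) gaps <- c(gaps, "validation.json")
  else summary$validation <- val

  summary$gaps <- as.list(sort(gaps))
  json <- canonical_json(summary)
  writeLines(as.character(json), file.path(out_dir, "summary.json"))
  invisible(summary)
}
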