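#' Write a spike raster to disk
#'
#' Text dialect: one event per line, `time_ms<TAB>neuron_id`, with a header
#' line. A columnar binary dialect (Feather, via the arrow package) is
#' available for long runs.
#'
#' @param raster A tibble with `time_ms`, `neuron`.
#' @param path Output file.
#' @param format `"tsv"` or `"feather"`.
#' @export
write_raster <- function(raster, path, format = c("tsv", "feather")) {
  format <- match.arg(format)
  if (format == "feather") {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      abort("the feather dialect needs the 'arrow' package")
    }
    arrow::write_feather(raster, path)
  } else {
    utils::write.table(raster, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' Read a spike raster written by [write_raster()]
#' @param path File path.
#' @param format `"tsv"` or `"feather"`.
#' @return A tibble with `time_ms`, `neuron`.
#' @export
read_raster <- function(path, format = c("tsv", "feather")) {
  format <- match.arg(format)
  if (format == "feather") {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      abort("the feather dialect needs the 'arrow' package")
    }
    return(as_tibble(arrow::read_feather(path)))
  }
  df <- utils::read.delim(path, sep = "\t")
  tibble(time_ms = as.integer(df$time_ms), neuron = as.integer(df$neuron))
}

#' Write a dense weight-matrix snapshot
#'
#' CSV payload preceded by a comment header carrying the snapshot time and
#' matrix size (`# time_ms=<t> n_neurons=<n>`).
#'
#' @param weights Weight matrix `[pre, post]`.
#' @param path Output file.
#' @param time_ms Snapshot time.
#' @export
write_weights <- function(weights, path, time_ms = 0) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# time_ms=%s n_neurons=%d", format(time_ms),
                     nrow(weights)), con)
  utils::write.table(weights, con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a weight-matrix snapshot written by [write_weights()]
#' @param path File path.
#' @return A matrix with attributes `time_ms` and `n_neurons`.
#' @export
read_weights <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- as.matrix(utils::read.csv(path, header = FALSE, skip = 1))
  dimnames(m) <- NULL
  attr(m, "time_ms") <- as.numeric(sub(".*time_ms=([^ ]+).*", "\\1", hdr))
  attr(m, "n_neurons") <- nrow(m)
  m
}

#' Write all artifacts of a run to a directory
#'
#' Writes `trials.csv`, `metrics.json` (the [glance()] row), `config.json`
#' (the full configuration echo, sufficient to re-run the experiment),
#' `raster.tsv` (if recorded) and `weights_final.csv`.
#'
#' @param run An `lsa_run`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_results <- function(run, dir) {
  stopifnot(inherits(run, "lsa_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  jsonlite::write_json(as.list(glance(run)), file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- unclass(run$config)
  cfg$zone_sizes <- as.list(cfg$zone_sizes)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(run$raster)) {
    write_raster(run$raster, file.path(dir, "raster.tsv"))
  }
  write_weights(run$w_final, file.path(dir, "weights_final.csv"),
                time_ms = run$duration_ms)
  invisible(dir)
}

#' Read back the artifacts written by [write_results()]
#'
#' @param dir Directory written by [write_results()].
#' @return A list with `trials` (tibble), `metrics` (list), `config`
#'   (`lsa_config`), `raster` (tibble or `NULL`), `weights` (matrix).
#' @export
read_results <- function(dir) {
  trials <- as_tibble(utils::read.csv(file.path(dir, "trials.csv")))
  trials$timed_out <- as.logical(trials$timed_out)
  trials$reaction_time_ms <- as.numeric(trials$reaction_time_ms)
  metrics <- jsonlite::read_json(file.path(dir, "metrics.json"),
                                 simplifyVector = TRUE)
  cfg_raw <- jsonlite::read_json(file.path(dir, "config.json"),
                                 simplifyVector = TRUE)
  preset <- cfg_raw$preset
  cfg_raw$preset <- NULL
  cfg_raw$zone_sizes <- unlist(cfg_raw$zone_sizes)
  config <- do.call(lsa_config, c(list(preset = preset), cfg_raw))
  raster_path <- file.path(dir, "raster.tsv")
  raster <- if (file.exists(raster_path)) read_raster(raster_path) else NULL
  weights <- read_weights(file.path(dir, "weights_final.csv"))
  list(trials = trials, metrics = metrics, config = config,
       raster = raster, weights = weights)
}
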