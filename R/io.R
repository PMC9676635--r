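#' Write an epoch set to a plain-text container
#'
#' The container is a directory holding `meta.json` (schema version, times,
#' sampling rate, layout), `trials.tsv` (per-trial metadata) and `data.tsv`
#' (the voltage array flattened to `n_trials * n_channels` rows by
#' `n_times` columns, trial-major). Floats are written with
#' shortest-round-trip formatting, so write/read is lossless.
#'
#' @param epochs An `epoch_set`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epochs$data)
  meta <- list(schema = "intrudetect-epochs", schema_version = 1L,
               n_trials = d[1], n_channels = d[2], n_times = d[3],
               sfreq = epochs$sfreq, times = epochs$times,
               layout = list(channel_ids = epochs$layout$channel_ids,
                             positions = unname(epochs$layout$positions),
                             region_tags = epochs$layout$region_tags))
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  if (ncol(epochs$trials) == 0) {
    file.create(file.path(path, "trials.tsv"))
  } else {
    data.table::fwrite(epochs$trials, file.path(path, "trials.tsv"),
                       sep = "\t", na = "NA", quote = FALSE)
  }
  if (d[1] > 0) {
    flat <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = d[3])  # times rows
    flat <- t(flat)                                # rows: trial-major channel
    # %.17g guarantees bit-exact round-trip of doubles through text
    chars <- matrix(sprintf("%.17g", flat), nrow = nrow(flat))
    writeLines(apply(chars, 1, paste, collapse = "\t"),
               file.path(path, "data.tsv"))
  }
  invisible(path)
}

#' Read an epoch set written by [write_epochs()]
#'
#' @param path Container directory.
#' @return An `epoch_set`.
#' @export
read_epochs <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop_schema("not an epochs container: missing meta.json")
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(meta$schema, "intrudetect-epochs")) {
    stop_schema("unrecognised container schema")
  }
  if (!identical(as.integer(meta$schema_version), 1L)) {
    stop_schema("unsupported schema_version: ", meta$schema_version)
  }
  for (field in c("times", "sfreq", "n_trials", "n_channels", "n_times")) {
    if (is.null(meta[[field]])) stop_schema("container missing field: ", field)
  }
  trials_file <- file.path(path, "trials.tsv")
  trials <- if (file.size(trials_file) == 0) {
    data.frame()
  } else {
    as.data.frame(data.table::fread(trials_file, sep = "\t",
                                    na.strings = "NA"))
  }
  d <- c(meta$n_trials, meta$n_channels, meta$n_times)
  dat <- array(0, dim = d)
  if (d[1] > 0) {
    flat <- as.matrix(data.table::fread(file.path(path, "data.tsv"),
                                        sep = "\t", header = FALSE))
    dat <- aperm(array(t(flat), dim = c(d[3], d[2], d[1])), c(3, 2, 1))
  }
  pos <- matrix(unlist(meta$layout$positions), ncol = 2,
                dimnames = list(NULL, c("x", "y")))
  layout <- structure(list(channel_ids = meta$layout$channel_ids,
                           positions = pos,
                           region_tags = meta$layout$region_tags),
                      class = "sensor_layout")
  if (d[1] == 0 && ncol(trials) == 0) {
    trials <- data.frame(participant = integer(), task = character(),
                         condition = character(), block = integer(),
                         item = integer(), report = integer(),
                         rt_ms = numeric())
  }
  epoch_set(dat, meta$times, meta$sfreq, trials, layout)
}

#' Write/read a behavioral table as TSV
#'
#' @param table data.frame.
#' @param path File path.
#' @return `path` invisibly / the data.frame.
#' @export
write_behavioral <- function(table, path) {
  data.table::fwrite(table, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_behavioral
#' @export
read_behavioral <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
}

#' Write a reproducibility manifest
#'
#' Records the configuration snapshot, package version, consumed child
#' seeds, content hashes (md5) of the listed output files and per-stage
#' wall-clock times. Re-running a deterministic stage with the same
#' configuration reproduces identical hashes.
#'
#' @param path Output JSON path.
#' @param config Configuration list.
#' @param seeds Named list/vector of child seeds consumed.
#' @param outputs Character vector of output file paths to hash.
#' @param timings Named numeric vector of stage wall-clock seconds.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config, seeds = NULL, outputs = character(),
                           timings = NULL) {
  files <- outputs[file.exists(outputs)]
  man <- list(package = "intrudetect",
              version = as.character(utils::packageVersion("intrudetect")),
              config = config, seeds = seeds,
              hashes = as.list(tools::md5sum(files)),
              timings_s = as.list(timings))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(man)
}
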