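#' Labeled multichannel epoch container
#'
#' The common in-memory container for single trials and m-ERPs: a trials x
#' channels x time numeric array with its sampling rate, per-trial class
#' labels and subject IDs, and channel names. Amplitudes are in microvolts
#' (the pipeline is scale-invariant under the models' default input
#' normalization, so unit mistakes degrade gracefully).
#'
#' @param data Numeric array, trials x channels x time.
#' @param fs Sampling rate in Hz.
#' @param labels Integer class labels in `1..n_classes`, one per trial.
#' @param subjects Subject identifier per trial (character or integer).
#' @param channel_names Unique channel names, one per channel.
#' @param provenance Optional trial-origin log (e.g. the grouping log of
#'   [generate_m_erps()]).
#' @return An `epoch_set` object.
#' @export
epoch_set <- function(data, fs, labels, subjects, channel_names,
                      provenance = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3, fs > 0)
  q <- dim(data)[1]
  if (length(labels) != q) {
    stop("labels length (", length(labels), ") != trial count (", q, ")")
  }
  if (length(subjects) != q) {
    stop("subjects length (", length(subjects), ") != trial count (", q, ")")
  }
  if (length(channel_names) != dim(data)[2]) {
    stop("channel_names length (", length(channel_names),
         ") != channel count (", dim(data)[2], ")")
  }
  if (anyDuplicated(channel_names)) stop("channel_names must be unique")
  structure(list(data = data, fs = fs, labels = as.integer(labels),
                 subjects = subjects,
                 channel_names = as.character(channel_names),
                 provenance = provenance),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
    d[1], d[2], d[3], x$fs))
  cat(sprintf("  classes: %s | subjects: %s\n",
              paste(names(table(x$labels)), table(x$labels),
                    sep = ":", collapse = ", "),
              paste(unique(x$subjects), collapse = ", ")))
  invisible(x)
}

#' Subset an epoch set by trials and/or channels
#'
#' @param x An [epoch_set()].
#' @param trials Trial index vector (default all).
#' @param channels Channel indices or names (default all).
#' @return A new `epoch_set`.
#' @export
subset_epochs <- function(x, trials = NULL, channels = NULL) {
  stopifnot(inherits(x, "epoch_set"))
  if (is.null(trials)) trials <- seq_len(dim(x$data)[1])
  if (is.null(channels)) {
    channels <- seq_len(dim(x$data)[2])
  } else if (is.character(channels)) {
    channels <- match(channels, x$channel_names)
    if (anyNA(channels)) stop("unknown channel name")
  }
  epoch_set(x$data[trials, channels, , drop = FALSE], x$fs,
            x$labels[trials], x$subjects[trials],
            x$channel_names[channels])
}

#' Read / write epoch containers
#'
#' Two on-disk layouts round-trip the [epoch_set()] container bit-exactly:
#' \describe{
#'   \item{`rds`}{a single RDS file holding the whole object (default).}
#'   \item{`tsv`}{a plain-text directory: `meta.json` (fs, dims, labels,
#'     subjects, channel names) plus `epochs.tsv`, trials x channels rows
#'     (trial-major) by T columns. Used for small text fixtures and
#'     interchange.}
#' }
#'
#' @param x An [epoch_set()].
#' @param path File (`rds`) or directory (`tsv`) path.
#' @param format `"rds"` or `"tsv"`.
#' @return `write_epochs()` returns `path` invisibly; `read_epochs()`
#'   returns an `epoch_set`.
#' @export
write_epochs <- function(x, path, format = c("rds", "tsv")) {
  stopifnot(inherits(x, "epoch_set"))
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(x, path)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(x$data)
  meta <- list(fs = x$fs, n_trials = d[1], n_channels = d[2],
               n_samples = d[3], labels = x$labels,
               subjects = as.character(x$subjects),
               channel_names = x$channel_names)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  flat <- matrix(aperm(x$data, c(3, 2, 1)), nrow = d[1] * d[2],
                 byrow = TRUE)
  # 17 significant digits so doubles survive the decimal round trip exactly
  utils::write.table(matrix(sprintf("%.17g", flat), nrow = nrow(flat)),
                     file.path(path, "epochs.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path, format = c("rds", "tsv")) {
  format <- match.arg(format)
  if (format == "rds") {
    x <- readRDS(path)
    if (!inherits(x, "epoch_set")) stop("not an epoch_set container: ", path)
    return(x)
  }
  mf <- file.path(path, "meta.json")
  ef <- file.path(path, "epochs.tsv")
  if (!file.exists(mf)) stop("missing dataset: ", mf)
  if (!file.exists(ef)) stop("missing dataset: ", ef)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(ef, sep = "\t"))
  if (nrow(flat) != meta$n_trials * meta$n_channels ||
      ncol(flat) != meta$n_samples) {
    stop("epochs.tsv shape (", nrow(flat), "x", ncol(flat),
         ") inconsistent with meta.json (",
         meta$n_trials * meta$n_channels, "x", meta$n_samples, ")")
  }
  dat <- aperm(array(t(flat), dim = c(meta$n_samples, meta$n_channels,
                                      meta$n_trials)), c(3, 2, 1))
  epoch_set(dat, meta$fs, meta$labels, meta$subjects, meta$channel_names)
}
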