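#' m-subsample averaging: generate an ensemble of m-ERPs
#'
#' Improves the signal-to-noise ratio of single trials by repeated
#' averaging of small, disjoint random draws. Within each internal round
#' the trials are randomly permuted and partitioned into disjoint groups of
#' `m` (no trial reused within a round; the `Q mod m` leftovers are
#' discarded), each group is averaged sample-wise, and rounds repeat until
#' `target_count` m-ERPs have been emitted. An average of m single trials
#' is an m-ERP; with `m = 1` the output is a permutation of the input
#' trials (1-ERPs).
#'
#' @param trials An [epoch_set()] restricted to one class (and typically
#'   one subject); all trials are pooled for averaging.
#' @param m Trials per average (>= 1).
#' @param target_count Number of m-ERPs to emit (default: the number of
#'   input trials, mirroring the convention of generating an equal number
#'   of m-ERPs).
#' @param seed RNG seed; the draw is deterministic given the seed.
#' @return An `epoch_set` of m-ERPs whose `provenance` field holds the
#'   grouping log: a data.frame with one row per emitted m-ERP (`output`,
#'   `round`, and `trials`, a list-column of the averaged trial indices).
#' @export
generate_m_erps <- function(trials, m, target_count = NULL, seed = 1L) {
  stopifnot(inherits(trials, "epoch_set"))
  q <- dim(trials$data)[1]
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1")
  if (m > q) stop("m (", m, ") exceeds the number of trials (", q, ")")
  if (is.null(target_count)) target_count <- q
  stopifnot(target_count >= 1)
  rng <- new_rng(seed)
  per_round <- q %/% m
  out <- array(0, dim = c(target_count, dim(trials$data)[2],
                          dim(trials$data)[3]))
  log_round <- integer(target_count)
  log_groups <- vector("list", target_count)
  emitted <- 0L
  round_i <- 0L
  while (emitted < target_count) {
    round_i <- round_i + 1L
    perm <- rng$sample(q)
    for (g in seq_len(per_round)) {
      if (emitted >= target_count) break
      emitted <- emitted + 1L
      idx <- perm[((g - 1L) * m + 1L):(g * m)]
      sl <- trials$data[idx, , , drop = FALSE]
      out[emitted, , ] <- if (m == 1L) sl[1L, , ] else colMeans(sl, dims = 1)
      log_round[emitted] <- round_i
      log_groups[[emitted]] <- sort(idx)
    }
  }
  log <- data.frame(output = seq_len(target_count), round = log_round)
  log$trials <- log_groups
  lab <- unique(trials$labels)
  subj <- unique(trials$subjects)
  epoch_set(out, trials$fs,
            labels = rep(if (length(lab) == 1L) lab else NA_integer_,
                         target_count),
            subjects = rep(if (length(subj) == 1L) subj else NA,
                           target_count),
            channel_names = trials$channel_names,
            provenance = log)
}

#' Serialize a grouping log as JSON lines
#'
#' One JSON object per emitted m-ERP (`output`, `round`, `trials`), so the
#' provenance of every average is auditable outside R.
#'
#' @param log The `provenance` data.frame of [generate_m_erps()] output.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_grouping_log <- function(log, path) {
  stopifnot(is.data.frame(log))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(log))) {
    writeLines(jsonlite::toJSON(
      list(output = log$output[i], round = log$round[i],
           trials = log$trials[[i]]),
      auto_unbox = TRUE), con)
  }
  invisible(path)
}
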