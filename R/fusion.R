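#' Fuse per-channel Z-scalograms into a frequency-time-spatial cuboid
#'
#' Stacks the Z-scalograms of D channels along a third (spatial) axis, in
#' the order given, producing the F x T x D input of the cuboid fusion
#' classifier. Fusion is lossless: slice `d` of the result is channel `d`'s
#' scalogram, bit for bit.
#'
#' @param scalograms List of `kind = "Z"` scalograms sharing one grid; list
#'   order is the channel rank order (rank 1 first).
#' @param channel_names Optional character vector naming the channels.
#' @param class_label Optional class label carried along for bookkeeping.
#' @return A `fusion_cuboid`: `values` (F x T x D array), `channel_names`,
#'   `class_label`.
#' @export
fuse_cuboid <- function(scalograms, channel_names = NULL, class_label = NULL) {
  stopifnot(is.list(scalograms), length(scalograms) >= 1)
  ref <- scalograms[[1]]
  stopifnot(inherits(ref, "scalogram"))
  for (d in seq_along(scalograms)) {
    s <- scalograms[[d]]
    if (!inherits(s, "scalogram") || !identical(s$kind, "Z")) {
      stop("element ", d, " is not a Z-scalogram")
    }
    if (!all(dim(s$values) == dim(ref$values))) {
      stop("element ", d, " has shape ",
           paste(dim(s$values), collapse = "x"), ", expected ",
           paste(dim(ref$values), collapse = "x"))
    }
  }
  D <- length(scalograms)
  vals <- array(0, dim = c(dim(ref$values), D))
  for (d in seq_len(D)) vals[, , d] <- scalograms[[d]]$values
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(D))
  stopifnot(length(channel_names) == D)
  structure(list(values = vals, channel_names = channel_names,
                 class_label = class_label),
            class = "fusion_cuboid")
}

#' Fuse per-channel V-vectors into a frequency-time-spatial matrix
#'
#' Places the V-feature vectors of D channels as the columns of an NV x D
#' matrix, in the order given (channel rank order), producing the input of
#' the matrix fusion classifier.
#'
#' @param vectors List of [make_v_vector()] objects of equal length.
#' @inheritParams fuse_cuboid
#' @return A `fusion_matrix`: `values` (NV x D matrix), `channel_names`,
#'   `class_label`.
#' @export
fuse_matrix <- function(vectors, channel_names = NULL, class_label = NULL) {
  stopifnot(is.list(vectors), length(vectors) >= 1)
  lens <- vapply(vectors, function(v) {
    stopifnot(inherits(v, "v_vector"))
    length(v$values)
  }, integer(1))
  if (length(unique(lens)) != 1) {
    d <- which(lens != lens[1])[1]
    stop("element ", d, " has length ", lens[d], ", expected ", lens[1])
  }
  vals <- vapply(vectors, function(v) v$values, numeric(lens[1]))
  vals <- matrix(vals, nrow = lens[1])
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(ncol(vals)))
  stopifnot(length(channel_names) == ncol(vals))
  structure(list(values = vals, channel_names = channel_names,
                 class_label = class_label),
            class = "fusion_matrix")
}

#' @export
print.fusion_cuboid <- function(x, ...) {
  cat(sprintf("<fusion_cuboid> %s (channels: %s)\n",
              paste(dim(x$values), collapse = "x"),
              paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' @export
print.fusion_matrix <- function(x, ...) {
  cat(sprintf("<fusion_matrix> %s (channels: %s)\n",
              paste(dim(x$values), collapse = "x"),
              paste(x$channel_names, collapse = ", ")))
  invisible(x)
}
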