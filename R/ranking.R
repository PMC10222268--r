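# Per-channel V-vector feature matrices (one Q x NV matrix per channel).
.channel_v_features <- function(data, grid, mask) {
  q <- dim(data$data)[1]
  C <- dim(data$data)[2]
  lapply(seq_len(C), function(ch) {
    t(vapply(seq_len(q), function(i) {
      make_v_vector(morlet_cwt(data$data[i, ch, ], grid), mask)$values
    }, numeric(mask$nv)))
  })
}

.fisher_score <- function(feats, labels) {
  classes <- sort(unique(labels))
  mus <- lapply(classes, function(cl) colMeans(feats[labels == cl, , drop = FALSE]))
  vars <- lapply(classes, function(cl) {
    apply(feats[labels == cl, , drop = FALSE], 2, stats::var)
  })
  grand <- Reduce(`+`, mus) / length(mus)
  between <- Reduce(`+`, lapply(mus, function(m) (m - grand)^2)) / length(mus)
  within <- Reduce(`+`, vars) / length(vars)
  mean(between / (within + 1e-12))
}

# Stratified k-fold CV accuracy of a nearest-class-centroid classifier.
.centroid_cv_score <- function(feats, labels, folds, seed) {
  rng <- new_rng(seed)
  classes <- sort(unique(labels))
  fold_of <- integer(length(labels))
  for (cl in classes) {
    idx <- which(labels == cl)
    fold_of[idx[rng$sample(length(idx))]] <-
      rep_len(seq_len(folds), length(idx))
  }
  correct <- 0L
  for (k in seq_len(folds)) {
    tr <- fold_of != k
    mus <- vapply(classes, function(cl) {
      colMeans(feats[tr & labels == cl, , drop = FALSE])
    }, numeric(ncol(feats)))
    te <- which(!tr)
    d2 <- vapply(seq_along(classes), function(j) {
      rowSums((feats[te, , drop = FALSE] -
                 rep(mus[, j], each = length(te)))^2)
    }, numeric(length(te)))
    pred <- classes[max.col(-matrix(d2, nrow = length(te)), "first")]
    correct <- correct + sum(pred == labels[te])
  }
  correct / length(labels)
}

#' Score channels of one subject by class discriminability
#'
#' Scores every channel by how well its in-COI wavelet features (V-vectors)
#' separate the classes. The default `"cv"` method is the cross-validated
#' accuracy of a lightweight unichannel nearest-class-centroid classifier;
#' `"fisher"` is the (faster) mean per-feature Fisher discriminant ratio of
#' the class-conditional V-vector distributions. Higher is better.
#'
#' @param data An [epoch_set()] for one subject with >= 2 classes and >= 2
#'   trials per class.
#' @param method `"cv"` or `"fisher"`.
#' @param grid Optional [build_scale_grid()]; defaults to the grid for this
#'   data's sampling rate and epoch length.
#' @param e_fold COI guard constant, see [compute_coi()].
#' @param folds,seed Cross-validation folds and RNG seed (`"cv"` method).
#' @return Numeric vector of non-negative per-channel scores, named by
#'   channel.
#' @export
score_channels <- function(data, method = c("cv", "fisher"), grid = NULL,
                           e_fold = 2.0147, folds = 5L, seed = 1L) {
  stopifnot(inherits(data, "epoch_set"))
  method <- match.arg(method)
  labels <- data$labels
  tab <- table(labels)
  if (length(tab) < 2) stop("channel scoring needs >= 2 classes")
  if (any(tab < 2)) stop("channel scoring needs >= 2 trials per class")
  T_ <- dim(data$data)[3]
  if (is.null(grid)) {
    grid <- suppressWarnings(build_scale_grid(data$fs, T_))
  }
  mask <- compute_coi(grid, T_, e_fold = e_fold)
  feats <- .channel_v_features(data, grid, mask)
  folds <- min(folds, min(tab))
  scores <- vapply(seq_along(feats), function(ch) {
    if (method == "fisher") {
      .fisher_score(feats[[ch]], labels)
    } else {
      # one shared fold assignment across channels, so the score is a
      # function of the channel data alone
      .centroid_cv_score(feats[[ch]], labels, folds, seed)
    }
  }, numeric(1))
  stats::setNames(scores, data$channel_names)
}

#' Rank channels from scores
#'
#' Rank 1 is the best (highest-scoring) channel; exact ties are broken in
#' favor of the lower channel index, so rankings are deterministic.
#'
#' @param scores Finite numeric scores, one per channel.
#' @return Integer ranks (a permutation of `1..C`), named like `scores`.
#' @export
rank_channels <- function(scores) {
  stopifnot(is.numeric(scores), all(is.finite(scores)))
  ord <- order(-scores, seq_along(scores))
  ranks <- integer(length(scores))
  ranks[ord] <- seq_along(scores)
  stats::setNames(ranks, names(scores))
}

#' Aggregate per-subject rankings by rank-of-rank-sum
#'
#' Sums the single-subject ranks channel-wise and ranks the rank-sums
#' (smallest sum = rank 1, ties broken by lower channel index). This is the
#' group channel selection used when subjects are pooled.
#'
#' @param per_subject_ranks List of per-subject rank vectors (or a matrix
#'   with one row per subject), all covering the same channel set.
#' @return List with `rank_sums` and `group_ranks` (a permutation of
#'   `1..C`).
#' @export
group_rank <- function(per_subject_ranks) {
  if (is.matrix(per_subject_ranks)) {
    per_subject_ranks <- asplit(per_subject_ranks, 1)
  }
  stopifnot(length(per_subject_ranks) >= 1)
  ref <- per_subject_ranks[[1]]
  for (i in seq_along(per_subject_ranks)) {
    ri <- per_subject_ranks[[i]]
    if (length(ri) != length(ref) ||
        (!is.null(names(ref)) && !identical(names(ri), names(ref)))) {
      stop("subject ", i, " ranking does not cover the same channel set")
    }
  }
  sums <- Reduce(`+`, lapply(per_subject_ranks, as.numeric))
  ord <- order(sums, seq_along(sums))
  granks <- integer(length(sums))
  granks[ord] <- seq_along(sums)
  list(rank_sums = stats::setNames(sums, names(ref)),
       group_ranks = stats::setNames(granks, names(ref)))
}

#' Rank channels per subject and for the pooled group
#'
#' Convenience driver: scores and ranks each subject's channels with
#' [score_channels()]/[rank_channels()], then aggregates the subject
#' rankings with [group_rank()].
#'
#' @param data Multi-subject [epoch_set()].
#' @inheritParams score_channels
#' @return List with `table` (tidy data.frame: subject, channel, score,
#'   rank; the group rows have subject `"group"` and score `NA`),
#'   `per_subject_ranks`, and `group_ranks`.
#' @export
channel_ranking <- function(data, method = c("cv", "fisher"), grid = NULL,
                            e_fold = 2.0147, folds = 5L, seed = 1L) {
  stopifnot(inherits(data, "epoch_set"))
  method <- match.arg(method)
  subjects <- unique(data$subjects)
  rows <- list()
  ranks <- list()
  for (s in subjects) {
    sub <- subset_epochs(data, trials = data$subjects == s)
    sc <- score_channels(sub, method = method, grid = grid, e_fold = e_fold,
                         folds = folds, seed = seed)
    rk <- rank_channels(sc)
    ranks[[as.character(s)]] <- rk
    rows[[length(rows) + 1L]] <- data.frame(
      subject = as.character(s), channel = data$channel_names,
      score = as.numeric(sc), rank = as.integer(rk))
  }
  gr <- group_rank(ranks)
  rows[[length(rows) + 1L]] <- data.frame(
    subject = "group", channel = data$channel_names, score = NA_real_,
    rank = as.integer(gr$group_ranks))
  list(table = do.call(rbind, rows), per_subject_ranks = ranks,
       group_ranks = gr$group_ranks)
}
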