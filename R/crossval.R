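#' Cross-validation protocol
#'
#' Describes one classification experiment: the protocol mode
#' (`"customized"` = within-subject stratified k-fold, the BCI-style
#' design; `"group"` = k-subject-fold, reducing to leave-one-subject-out
#' at `k = B`, the clinical-style design), the subsample parameter m, the
#' channel count D, the model kind, and the number of repetitions.
#'
#' @param mode `"customized"` or `"group"`.
#' @param k Number of folds (customized: trial folds per subject; group:
#'   subject folds).
#' @param runs Repetitions; each run reseeds the fold split, the subsample
#'   grouping and the model weights (default 50).
#' @param m Subsample averaging parameter (1 = single trials).
#' @param D Number of (top-ranked) channels fed to the classifier.
#' @param model_kind Classifier model, see [model_spec()].
#' @param seed Protocol seed; run r uses child seeds derived from it.
#' @param leakage `"partition"` (default) generates m-ERPs separately from
#'   the trials inside each CV partition, so no single trial contributes
#'   to both train and test averages; `"pool"` reproduces the
#'   average-then-split alternative.
#' @return A `cv_protocol` object.
#' @export
cv_protocol <- function(mode = c("customized", "group"), k = 5L,
                        runs = 50L, m = 1L, D = 1L,
                        model_kind = "z_matrix", seed = 1L,
                        leakage = c("partition", "pool")) {
  structure(list(mode = match.arg(mode), k = as.integer(k),
                 runs = as.integer(runs), m = as.integer(m),
                 D = as.integer(D), model_kind = model_kind,
                 seed = as.integer(seed), leakage = match.arg(leakage)),
            class = "cv_protocol")
}

#' CNN classifier adapter for the CV drivers
#'
#' Wraps the four scalogram models behind the fit/predict interface the
#' cross-validation drivers consume. The spec is derived from the first
#' training input's shape at fit time.
#'
#' @param epochs,batch_size,learning_rate,dropout,normalize Training
#'   options forwarded to [model_spec()] (defaults are the models'
#'   standard options; smaller `epochs` gives faster, rougher fits).
#' @param n_classes Number of classes.
#' @return A classifier adapter (list with `fit`, `predict`,
#'   `needs_features = TRUE`).
#' @export
cnn_classifier <- function(epochs = 50L, batch_size = 32L,
                           learning_rate = 0.001, dropout = 0.15,
                           normalize = TRUE, n_classes = 2L) {
  list(
    needs_features = TRUE,
    fit = function(model_kind, inputs, labels, seed) {
      dims <- dim(inputs[[1]])
      if (is.null(dims)) dims <- length(inputs[[1]])
      if (model_kind == "z_matrix" || model_kind == "v_matrix") {
        dims <- dims[1:2]
      }
      sp <- model_spec(model_kind, dims, n_classes = n_classes,
                       epochs = epochs, batch_size = batch_size,
                       learning_rate = learning_rate, dropout = dropout,
                       normalize = normalize)
      train_model(build_model(sp, seed = seed), inputs, labels)
    },
    predict = function(fit, inputs) decide(predict(fit, inputs))
  )
}

#' Constant-answer classifier stub
#'
#' Always predicts one class; it needs no features, so the CV drivers skip
#' the scalogram pipeline entirely. Used to audit the drivers' accounting
#' (tested counts, fold sizes, chance-level accuracy) at negligible cost.
#'
#' @param class The class it always answers.
#' @return A classifier adapter.
#' @export
constant_classifier <- function(class = 1L) {
  list(needs_features = FALSE,
       fit = function(model_kind, inputs, labels, seed) class,
       predict = function(fit, inputs) rep(fit, length(inputs)))
}

# Featurize an epoch_set of m-ERPs for one model kind over ranked channels.
.featurize <- function(eps, model_kind, channels, grid, mask) {
  q <- dim(eps$data)[1]
  lapply(seq_len(q), function(i) {
    if (model_kind == "z_cuboid") {
      zs <- lapply(channels, function(ch) {
        make_z_scalogram(morlet_cwt(eps$data[i, ch, ], grid), mask)
      })
      fuse_cuboid(zs)$values
    } else if (model_kind == "z_matrix") {
      make_z_scalogram(morlet_cwt(eps$data[i, channels[1], ], grid),
                       mask)$values
    } else if (model_kind == "v_matrix") {
      vs <- lapply(channels, function(ch) {
        make_v_vector(morlet_cwt(eps$data[i, ch, ], grid), mask)
      })
      fuse_matrix(vs)$values
    } else {
      make_v_vector(morlet_cwt(eps$data[i, channels[1], ], grid),
                    mask)$values
    }
  })
}

# Per-class m-ERP ensembles from one subject's trials; target count = the
# per-class trial count, mirroring the generate-an-equal-number convention.
.m_ensemble <- function(eps, m, seed) {
  classes <- sort(unique(eps$labels))
  sets <- lapply(seq_along(classes), function(ci) {
    cl <- classes[ci]
    sub <- subset_epochs(eps, trials = eps$labels == cl)
    generate_m_erps(sub, m = m, seed = derive_seed(seed, ci))
  })
  n_per <- vapply(sets, function(s) dim(s$data)[1], integer(1))
  dims <- dim(sets[[1]]$data)
  arr <- array(0, dim = c(sum(n_per), dims[2], dims[3]))
  off <- 0L
  for (s in sets) {
    n <- dim(s$data)[1]
    arr[(off + 1L):(off + n), , ] <- s$data
    off <- off + n
  }
  trials_used <- unlist(lapply(sets, function(s) {
    unlist(s$provenance$trials)
  }), use.names = FALSE)
  list(epochs = epoch_set(arr, eps$fs,
                          labels = rep(classes, n_per),
                          subjects = rep(eps$subjects[1], sum(n_per)),
                          channel_names = eps$channel_names),
       trials_by_set = lapply(sets, function(s) s$provenance))
}

.stratified_folds <- function(labels, k, rng) {
  fold_of <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      stop("class ", cl, " has fewer trials (", length(idx),
           ") than folds (", k, ")")
    }
    fold_of[idx[rng$sample(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold_of
}

.new_cv_result <- function(records, proto) {
  records$accuracy <- 100 * records$n_correct / records$n_tested
  structure(list(records = records, proto = proto), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result %s> k=%d runs=%d m=%d D=%d model=%s\n",
              x$proto$mode, x$proto$k, x$proto$runs, x$proto$m, x$proto$D,
              x$proto$model_kind))
  print(summarize_cv(x))
  invisible(x)
}

#' Within-subject (customized) cross-validation
#'
#' Repeated stratified k-fold cross-validation on one subject's trials.
#' Each run reseeds the fold split, the m-ERP groupings and the model
#' weights. Under the default leakage mode the training and test m-ERPs
#' are averaged from disjoint trial partitions, so no single trial
#' contributes to both sides of a fold; every m-ERP is tested exactly once
#' per run.
#'
#' @param data [epoch_set()] of one subject's single trials.
#' @param proto A `mode = "customized"` [cv_protocol()].
#' @param classifier A classifier adapter ([cnn_classifier()] by default
#'   with `epochs` as configured there; [constant_classifier()] for
#'   accounting checks).
#' @param channels Rank-ordered channel indices; the first `proto$D` are
#'   used (default `1:D`).
#' @param grid Optional [build_scale_grid()] (defaults to the standard
#'   grid for this data's geometry).
#' @param e_fold COI guard constant.
#' @return A `cv_result`: `records` has one row per (run, fold) with
#'   tested/correct counts and accuracy.
#' @export
run_customized_cv <- function(data, proto, classifier = cnn_classifier(),
                              channels = NULL, grid = NULL,
                              e_fold = 2.0147) {
  stopifnot(inherits(data, "epoch_set"), inherits(proto, "cv_protocol"),
            proto$mode == "customized")
  if (length(unique(data$subjects)) != 1) {
    stop("customized CV expects a single subject's epochs")
  }
  if (is.null(channels)) channels <- seq_len(proto$D)
  channels <- channels[seq_len(proto$D)]
  T_ <- dim(data$data)[3]
  need_feat <- isTRUE(classifier$needs_features)
  if (need_feat) {
    if (is.null(grid)) grid <- suppressWarnings(build_scale_grid(data$fs, T_))
    mask <- compute_coi(grid, T_, e_fold = e_fold)
  }
  rec <- list()
  for (r in seq_len(proto$runs)) {
    rseed <- derive_seed(proto$seed, r)
    rng <- new_rng(rseed)
    if (proto$leakage == "pool") {
      ens <- .m_ensemble(data, proto$m, derive_seed(rseed, 99))
      pool_eps <- ens$epochs
      fold_of <- .stratified_folds(pool_eps$labels, proto$k, rng)
      feats <- if (need_feat) {
        .featurize(pool_eps, proto$model_kind, channels, grid, mask)
      }
      for (f in seq_len(proto$k)) {
        te <- which(fold_of == f)
        tr <- which(fold_of != f)
        fit <- classifier$fit(proto$model_kind,
                              if (need_feat) feats[tr],
                              pool_eps$labels[tr], derive_seed(rseed, f))
        pred <- classifier$predict(fit, if (need_feat) feats[te] else te)
        rec[[length(rec) + 1L]] <- data.frame(
          run = r, fold = f, subject = data$subjects[1],
          n_tested = length(te),
          n_correct = sum(pred == pool_eps$labels[te]))
      }
    } else {
      fold_of <- .stratified_folds(data$labels, proto$k, rng)
      for (f in seq_len(proto$k)) {
        tr_set <- subset_epochs(data, trials = fold_of != f)
        te_set <- subset_epochs(data, trials = fold_of == f)
        tr_ens <- .m_ensemble(tr_set, proto$m, derive_seed(rseed, f, 1))
        te_ens <- .m_ensemble(te_set, proto$m, derive_seed(rseed, f, 2))
        tr_feats <- if (need_feat) {
          .featurize(tr_ens$epochs, proto$model_kind, channels, grid, mask)
        }
        te_feats <- if (need_feat) {
          .featurize(te_ens$epochs, proto$model_kind, channels, grid, mask)
        }
        fit <- classifier$fit(proto$model_kind, tr_feats,
                              tr_ens$epochs$labels, derive_seed(rseed, f))
        pred <- classifier$predict(
          fit,
          if (need_feat) te_feats else seq_along(te_ens$epochs$labels))
        rec[[length(rec) + 1L]] <- data.frame(
          run = r, fold = f, subject = data$subjects[1],
          n_tested = length(te_ens$epochs$labels),
          n_correct = sum(pred == te_ens$epochs$labels))
      }
    }
  }
  .new_cv_result(do.call(rbind, rec), proto)
}

#' Group-based (k-subject-fold) cross-validation
#'
#' Folds partition subjects, never trials: the classifier is trained on
#' the m-ERPs of the subjects outside a fold and tested on each left-out
#' subject separately, so the training set never contains any test
#' subject's data. With `k = B` (one subject per fold) this is
#' leave-one-subject-out cross-validation. Subject-to-fold assignment is
#' reshuffled between runs when `k < B`.
#'
#' @param data Multi-subject [epoch_set()] of single trials.
#' @param proto A `mode = "group"` [cv_protocol()]; `k` must divide the
#'   subject count.
#' @inheritParams run_customized_cv
#' @return A `cv_result` with one record per (run, fold, test subject).
#' @export
run_group_cv <- function(data, proto, classifier = cnn_classifier(),
                         channels = NULL, grid = NULL, e_fold = 2.0147) {
  stopifnot(inherits(data, "epoch_set"), inherits(proto, "cv_protocol"),
            proto$mode == "group")
  subjects <- unique(data$subjects)
  B <- length(subjects)
  if (B < 2) stop("group CV needs >= 2 subjects")
  if (proto$k > B) stop("k (", proto$k, ") exceeds the subject count (",
                        B, ")")
  if (B %% proto$k != 0) {
    stop("k (", proto$k, ") must divide the subject count (", B, ")")
  }
  if (is.null(channels)) channels <- seq_len(proto$D)
  channels <- channels[seq_len(proto$D)]
  T_ <- dim(data$data)[3]
  need_feat <- isTRUE(classifier$needs_features)
  if (need_feat) {
    if (is.null(grid)) grid <- suppressWarnings(build_scale_grid(data$fs, T_))
    mask <- compute_coi(grid, T_, e_fold = e_fold)
  }
  per_subj <- lapply(subjects, function(s) {
    subset_epochs(data, trials = data$subjects == s)
  })
  names(per_subj) <- subjects
  rec <- list()
  for (r in seq_len(proto$runs)) {
    rseed <- derive_seed(proto$seed, r)
    rng <- new_rng(rseed)
    ord <- if (proto$k < B) subjects[rng$sample(B)] else subjects
    fold_subjects <- split(ord, rep(seq_len(proto$k), each = B / proto$k))
    # per-run m-ERP ensembles (and features) per subject
    ens <- lapply(seq_along(subjects), function(si) {
      .m_ensemble(per_subj[[si]], proto$m, derive_seed(rseed, si))
    })
    names(ens) <- subjects
    feats <- if (need_feat) {
      lapply(ens, function(e) {
        .featurize(e$epochs, proto$model_kind, channels, grid, mask)
      })
    }
    for (f in seq_len(proto$k)) {
      test_s <- fold_subjects[[f]]
      train_s <- setdiff(subjects, test_s)
      tr_labels <- unlist(lapply(ens[train_s],
                                 function(e) e$epochs$labels),
                          use.names = FALSE)
      tr_feats <- if (need_feat) {
        do.call(c, lapply(feats[train_s], identity))
      }
      fit <- classifier$fit(proto$model_kind, tr_feats, tr_labels,
                            derive_seed(rseed, f))
      for (s in test_s) {
        te_labels <- ens[[s]]$epochs$labels
        pred <- classifier$predict(
          fit, if (need_feat) feats[[s]] else seq_along(te_labels))
        rec[[length(rec) + 1L]] <- data.frame(
          run = r, fold = f, subject = s, n_tested = length(te_labels),
          n_correct = sum(pred == te_labels))
      }
    }
  }
  .new_cv_result(do.call(rbind, rec), proto)
}

#' Summarize cross-validation results
#'
#' Per-subject accuracy is 100 x (total correct / total tested) pooled
#' over folds and runs; the overall figure is the mean of the per-subject
#' accuracies.
#'
#' @param results A `cv_result`.
#' @param by `"subject"` (default), `"overall"`, or `"run"`.
#' @return A data.frame of accuracies (percent).
#' @export
summarize_cv <- function(results, by = c("subject", "overall", "run")) {
  stopifnot(inherits(results, "cv_result"))
  by <- match.arg(by)
  rec <- results$records
  per_subject <- do.call(rbind, lapply(split(rec, rec$subject), function(d) {
    data.frame(subject = d$subject[1], n_tested = sum(d$n_tested),
               n_correct = sum(d$n_correct),
               accuracy = 100 * sum(d$n_correct) / sum(d$n_tested))
  }))
  rownames(per_subject) <- NULL
  switch(by,
    subject = per_subject,
    overall = data.frame(model = results$proto$model_kind,
                         D = results$proto$D, m = results$proto$m,
                         accuracy = mean(per_subject$accuracy)),
    run = {
      out <- do.call(rbind, lapply(split(rec, rec$run), function(d) {
        data.frame(run = d$run[1],
                   accuracy = 100 * sum(d$n_correct) / sum(d$n_tested))
      }))
      rownames(out) <- NULL
      out
    })
}

#' Pivot a set of CV results into a model x D x m accuracy table
#'
#' Mirrors the customary layout of multidomain ERP accuracy tables: one
#' row per (model, D, m), one column per subject, plus the subject mean.
#'
#' @param results_list List of `cv_result` objects.
#' @return A data.frame.
#' @export
pivot_accuracy <- function(results_list) {
  stopifnot(length(results_list) >= 1)
  subjects <- sort(unique(unlist(lapply(results_list, function(r) {
    unique(r$records$subject)
  }))))
  rows <- lapply(results_list, function(r) {
    ps <- summarize_cv(r)
    acc <- stats::setNames(ps$accuracy, ps$subject)[subjects]
    out <- data.frame(model = r$proto$model_kind, D = r$proto$D,
                      m = r$proto$m, mode = r$proto$mode)
    for (s in subjects) out[[s]] <- unname(acc[s])
    out$mean <- mean(acc, na.rm = TRUE)
    out
  })
  do.call(rbind, rows)
}
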