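stub_set <- function(q_per_class = 20, classes = 2, subjects = "s1",
                     t = 4, seed = 1) {
  set.seed(seed)
  q <- q_per_class * classes * length(subjects)
  epoch_set(array(rnorm(q * t), dim = c(q, 1, t)), fs = 4,
            labels = rep(rep(seq_len(classes), each = q_per_class),
                         length(subjects)),
            subjects = rep(subjects, each = q_per_class * classes),
            channel_names = "chA")
}

test_that("customized CV accounting: every m-ERP tested once per run", {
  ep <- stub_set(q_per_class = 195)
  proto <- cv_protocol("customized", k = 5, runs = 50, m = 1, D = 1,
                       seed = 3)
  res <- run_customized_cv(ep, proto, constant_classifier(1L))
  ps <- summarize_cv(res)
  expect_equal(ps$n_tested, 195 * 2 * 50)   # 19,500 per subject
  # balanced two-class data, constant answers -> exactly chance
  expect_equal(ps$accuracy, 50)
  # per-fold test sizes: 39 per class
  expect_true(all(res$records$n_tested == 78))
  expect_equal(nrow(res$records), 250)
})

test_that("subsample accounting holds for m > 1", {
  ep <- stub_set(q_per_class = 195)
  for (m in c(2L, 4L)) {
    proto <- cv_protocol("customized", k = 5, runs = 2, m = m, D = 1)
    res <- run_customized_cv(ep, proto, constant_classifier(1L))
    # equal number of m-ERPs as trials, so the totals are unchanged
    expect_equal(sum(res$records$n_tested), 195 * 2 * 2)
  }
})

test_that("customized CV rejects bad inputs", {
  ep2 <- stub_set(subjects = c("a", "b"))
  proto <- cv_protocol("customized", k = 5, runs = 1)
  expect_error(run_customized_cv(ep2, proto, constant_classifier()),
               "single subject")
  tiny <- stub_set(q_per_class = 3)
  expect_error(
    run_customized_cv(tiny, cv_protocol("customized", k = 5, runs = 1),
                      constant_classifier()),
    "fewer trials")
})

test_that("group CV partitions subjects, never trials", {
  ep <- stub_set(q_per_class = 12, subjects = paste0("S", 1:5))
  proto <- cv_protocol("group", k = 5, runs = 3, m = 1, D = 1, seed = 2)
  res <- run_group_cv(ep, proto, constant_classifier(1L))
  rec <- res$records
  # leave-one-subject-out: one subject per fold, each tested once per run
  for (r in unique(rec$run)) {
    rr <- rec[rec$run == r, ]
    expect_equal(nrow(rr), 5)
    expect_setequal(rr$subject, paste0("S", 1:5))
    expect_equal(sort(rr$fold), 1:5)
  }
  expect_true(all(rec$n_tested == 24))

  ep4 <- stub_set(q_per_class = 6, subjects = paste0("S", 1:4))
  res2 <- run_group_cv(ep4, cv_protocol("group", k = 2, runs = 4, seed = 5),
                       constant_classifier(1L))
  for (r in 1:4) {
    rr <- res2$records[res2$records$run == r, ]
    expect_equal(nrow(rr), 4)                  # every subject tested once
    expect_setequal(rr$subject, paste0("S", 1:4))
    expect_equal(as.integer(table(rr$fold)), c(2L, 2L))
  }

  expect_error(run_group_cv(ep4, cv_protocol("group", k = 8),
                            constant_classifier()), "exceeds")
  expect_error(run_group_cv(ep4, cv_protocol("group", k = 3),
                            constant_classifier()), "divide")
})

test_that("partition-mode m-ERPs never mix train and test trials", {
  ep <- stub_set(q_per_class = 24)
  rng <- merpnet:::new_rng(7)
  fold_of <- merpnet:::.stratified_folds(ep$labels, 3, rng)
  for (f in 1:3) {
    tr_ids <- which(fold_of != f)
    te_ids <- which(fold_of == f)
    tr_ens <- merpnet:::.m_ensemble(subset_epochs(ep, trials = fold_of != f),
                                    m = 2, seed = 11)
    te_ens <- merpnet:::.m_ensemble(subset_epochs(ep, trials = fold_of == f),
                                    m = 2, seed = 12)
    # map grouping-log indices back to original trial ids
    class_of <- function(ids) split(ids, ep$labels[ids])
    tr_by_class <- class_of(tr_ids)
    te_by_class <- class_of(te_ids)
    used_tr <- unlist(lapply(seq_along(tr_ens$trials_by_set), function(ci) {
      tr_by_class[[ci]][unlist(tr_ens$trials_by_set[[ci]]$trials)]
    }))
    used_te <- unlist(lapply(seq_along(te_ens$trials_by_set), function(ci) {
      te_by_class[[ci]][unlist(te_ens$trials_by_set[[ci]]$trials)]
    }))
    expect_length(intersect(used_tr, used_te), 0)
  }
})

test_that("summaries match a brute-force re-summation of the raw records", {
  ep <- stub_set(q_per_class = 10, subjects = c("u", "v"))
  proto <- cv_protocol("group", k = 2, runs = 5, seed = 9)
  res <- run_group_cv(ep, proto, constant_classifier(2L))
  rec <- res$records
  ps <- summarize_cv(res)
  for (s in unique(rec$subject)) {
    rr <- rec[rec$subject == s, ]
    expect_equal(ps$accuracy[ps$subject == s],
                 100 * sum(rr$n_correct) / sum(rr$n_tested))
  }
  ov <- summarize_cv(res, by = "overall")
  expect_equal(ov$accuracy, mean(ps$accuracy))
  # subject relabeling leaves per-subject values unchanged
  res2 <- res
  res2$records$subject <- factor(rec$subject, levels = c("v", "u"))
  ps2 <- summarize_cv(res2)
  expect_equal(sort(ps2$accuracy), sort(ps$accuracy))
})

test_that("pivot_accuracy mirrors the model x D x m table layout", {
  ep <- stub_set(q_per_class = 10, subjects = c("u", "v"))
  res <- run_group_cv(ep, cv_protocol("group", k = 2, runs = 2, m = 1,
                                      D = 1, model_kind = "z_matrix"),
                      constant_classifier(1L))
  tab <- pivot_accuracy(list(res))
  expect_equal(tab$model, "z_matrix")
  expect_true(all(c("u", "v", "mean") %in% names(tab)))
  expect_equal(tab$mean, mean(c(tab$u, tab$v)))
})

test_that("a real CNN learns the easy fixture through the CV driver", {
  ep <- make_fixture("easy")
  s1 <- subset_epochs(ep, trials = ep$subjects == "S1")
  # coarse 6-band grid keeps the NV-sized head small
  grid <- suppressWarnings(build_scale_grid(64, 64, voices_per_octave = 2,
                                            octaves = 3))
  accs <- vapply(1:3, function(sd) {
    proto <- cv_protocol("customized", k = 2, runs = 1, m = 1, D = 1,
                         model_kind = "v_vector", seed = sd)
    res <- run_customized_cv(s1, proto,
                             cnn_classifier(epochs = 5L, batch_size = 40L),
                             channels = 2, grid = grid)
    summarize_cv(res)$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 90)
})

test_that("pool-first leakage mode splits pre-generated m-ERPs", {
  ep <- stub_set(q_per_class = 20)
  proto <- cv_protocol("customized", k = 4, runs = 3, m = 2, D = 1,
                       seed = 6, leakage = "pool")
  res <- run_customized_cv(ep, proto, constant_classifier(1L))
  # 20 m-ERPs per class per run, every one tested exactly once
  expect_equal(sum(res$records$n_tested), 40 * 3)
  expect_true(all(res$records$n_tested == 10))
  expect_equal(summarize_cv(res)$accuracy, 50)
})
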