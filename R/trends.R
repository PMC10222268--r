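#' Scaled-down end-to-end trend experiment
#'
#' Reruns the method's headline comparisons on the synthetic `medium`
#' fixture at desk scale: (a) multichannel fusion (D = 4, cuboid model)
#' against the best unichannel classifier, (b) the effect of the subsample
#' averaging parameter m in \{1, 2, 4\} at fixed D, and (c) group-based
#' (leave-one-subject-out) against customized training at small D and m.
#' One row is produced per seed; trend claims are asserted on the means
#' over seeds.
#'
#' Problem sizes are deliberately small (8 channels, 40 trials per class,
#' 64-sample epochs, a 16-band grid, 3-fold single-run CV, 12 training
#' epochs) so the full experiment stays in the minutes range; see the
#' package vignette for what this does and does not establish.
#'
#' @param seeds Integer vector of simulation seeds (one experiment each).
#' @param level Fixture difficulty for [make_fixture()].
#' @param epochs CNN training epochs per fold.
#' @param voices_per_octave,octaves Scale-grid size for the feature
#'   pipeline.
#' @param k Customized CV folds.
#' @param ms Subsample parameters for the m-trend.
#' @param D Channels fused in the multichannel model.
#' @param verbose Print one line per seed.
#' @return data.frame, one row per seed: accuracies of the two unichannel
#'   candidate classifiers (`uni_cand1/2`, channels picked by the Fisher
#'   criterion), `best_uni`, `fusion_m1/m2/m4`, `customized` (subject mean
#'   at m = 1, D = 4), `group` (leave-one-subject-out, same setting).
#' @export
trend_experiment <- function(seeds = 1:5, level = "medium", epochs = 12L,
                             voices_per_octave = 4L, octaves = 4L,
                             k = 3L, ms = c(1L, 2L, 4L), D = 4L,
                             verbose = FALSE) {
  rows <- lapply(seeds, function(sd) {
    ep <- make_fixture(level, seed = 1000L + sd)
    cfg <- attr(ep, "config")
    grid <- suppressWarnings(build_scale_grid(
      cfg$fs, cfg$n_samples, voices_per_octave = voices_per_octave,
      octaves = octaves))
    cls <- cnn_classifier(epochs = epochs, batch_size = 16L)
    subjects <- unique(ep$subjects)
    chans <- seq_len(D)

    # unichannel candidates: the two most discriminable channels by the
    # (cheap) Fisher criterion on the first subject, mirroring how the
    # best unichannel classifier is picked among top-ranked channels
    s1 <- subset_epochs(ep, ep$subjects == subjects[1])
    fsc <- score_channels(subset_epochs(s1, channels = chans),
                          method = "fisher", grid = grid)
    uni_chans <- chans[order(rank_channels(fsc))[1:2]]
    uni <- vapply(uni_chans, function(ch) {
      pr <- cv_protocol("customized", k = k, runs = 1L, m = 1L, D = 1L,
                        model_kind = "z_matrix", seed = derive_seed(sd, ch))
      r <- run_customized_cv(subset_epochs(ep, ep$subjects == subjects[1]),
                             pr, cls, channels = ch, grid = grid)
      summarize_cv(r)$accuracy
    }, numeric(1))

    fus <- vapply(ms, function(m) {
      pr <- cv_protocol("customized", k = k, runs = 1L, m = m, D = D,
                        model_kind = "z_cuboid",
                        seed = derive_seed(sd, 50L, m))
      r <- run_customized_cv(subset_epochs(ep, ep$subjects == subjects[1]),
                             pr, cls, channels = chans, grid = grid)
      summarize_cv(r)$accuracy
    }, numeric(1))

    cust <- vapply(subjects, function(s) {
      if (s == subjects[1]) return(fus[1])
      pr <- cv_protocol("customized", k = k, runs = 1L, m = 1L, D = D,
                        model_kind = "z_cuboid",
                        seed = derive_seed(sd, 60L, match(s, subjects)))
      r <- run_customized_cv(subset_epochs(ep, ep$subjects == s), pr, cls,
                             channels = chans, grid = grid)
      summarize_cv(r)$accuracy
    }, numeric(1))

    prg <- cv_protocol("group", k = length(subjects), runs = 1L, m = 1L,
                       D = D, model_kind = "z_cuboid",
                       seed = derive_seed(sd, 70L))
    grp <- run_group_cv(ep, prg, cls, channels = chans, grid = grid)

    out <- data.frame(seed = sd)
    for (i in seq_along(uni_chans)) out[[paste0("uni_cand", i)]] <- uni[i]
    out$best_uni <- max(uni)
    for (i in seq_along(ms)) out[[paste0("fusion_m", ms[i])]] <- fus[i]
    out$customized <- mean(cust)
    out$group <- mean(summarize_cv(grp)$accuracy)
    if (verbose) {
      message(sprintf(
        "seed %d: best uni %.1f | fusion m=1 %.1f m=2 %.1f m=4 %.1f | cust %.1f grp %.1f",
        sd, out$best_uni, out$fusion_m1,
        if ("fusion_m2" %in% names(out)) out$fusion_m2 else NA,
        if ("fusion_m4" %in% names(out)) out$fusion_m4 else NA,
        out$customized, out$group))
    }
    out
  })
  do.call(rbind, rows)
}
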