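test_that("scale grid geometry follows the voices/octaves construction", {
  g <- build_scale_grid(fs = 200, n_samples = 200)
  expect_length(g$frequencies, 108)
  expect_true(all(diff(g$frequencies) < 0))
  ratios <- g$frequencies[-1] / g$frequencies[-length(g$frequencies)]
  expect_equal(ratios, rep(2^(-1 / g$voices_per_octave), 107),
               tolerance = 1e-12)
  expect_equal(g$scales, g$f0 * 200 / g$frequencies)

  g3 <- build_scale_grid(fs = 200, n_samples = 200, voices_per_octave = 1,
                         octaves = 3)
  expect_length(g3$frequencies, 3)
  expect_equal(g3$frequencies[-1] / g3$frequencies[-3], c(0.5, 0.5))
})

test_that("grid construction rejects super-Nyquist bands and warns on slow bands", {
  expect_error(build_scale_grid(fs = 100, n_samples = 64, fmax = 60),
               "Nyquist")
  expect_warning(
    build_scale_grid(fs = 64, n_samples = 32, voices_per_octave = 2,
                     octaves = 6),
    "less than one cycle")
})

test_that("every daughter wavelet has unit discrete L2 energy", {
  g <- build_scale_grid(fs = 200, n_samples = 200, voices_per_octave = 6,
                        octaves = 4)
  for (f in seq_along(g$frequencies)) {
    psi <- morlet_daughter(g, f)
    expect_equal(sum(Mod(psi)^2), 1, tolerance = 1e-6)
  }
})

test_that("FFT-based CWT matches the direct inner-product oracle", {
  g <- build_scale_grid(fs = 64, n_samples = 48, voices_per_octave = 2,
                        octaves = 4)
  set.seed(7)
  for (sig in list(rnorm(48), cos(2 * pi * 8 * (0:47) / 64))) {
    s <- morlet_cwt(sig, g)
    expect_equal(s$values, oracle_cwt(sig, g), tolerance = 1e-8)
  }
})

test_that("CWT linearity: zero input, homogeneity, triangle inequality", {
  g <- build_scale_grid(fs = 32, n_samples = 32, voices_per_octave = 3,
                        octaves = 3)
  z <- morlet_cwt(rep(0, 32), g)
  expect_true(all(z$values == 0))

  set.seed(1)
  x <- rnorm(32); y <- rnorm(32)
  sx <- morlet_cwt(x, g)$values
  expect_equal(morlet_cwt(3.5 * x, g)$values, 3.5 * sx, tolerance = 1e-12)
  sy <- morlet_cwt(y, g)$values
  sxy <- morlet_cwt(x + y, g)$values
  expect_true(all(sxy <= sx + sy + 1e-12))
})

test_that("CWT rejects non-finite samples naming the offending index", {
  g <- build_scale_grid(fs = 32, n_samples = 16, voices_per_octave = 2,
                        octaves = 2)
  x <- rep(0, 16); x[5] <- NA
  expect_error(morlet_cwt(x, g), "index 5")
})

test_that("a pure tone's in-COI column argmax lands on its own band", {
  fs <- 200; T_ <- 200
  g <- build_scale_grid(fs = fs, n_samples = T_)
  mask <- compute_coi(g, T_)
  band <- 30L  # interior band with a wide in-COI run
  f_sig <- g$frequencies[band]
  s <- morlet_cwt(cos(2 * pi * f_sig * (0:(T_ - 1)) / fs), g)
  inside <- which(mask$mask[band, ])
  for (t in inside) {
    cands <- which(mask$mask[, t])
    expect_equal(cands[which.max(s$values[cands, t])], band)
  }
})

test_that("COI mask is centered, contiguous, and monotone across bands", {
  g <- build_scale_grid(fs = 200, n_samples = 200, voices_per_octave = 9,
                        octaves = 4)
  T_ <- 200
  mask <- compute_coi(g, T_)
  expect_equal(mask$nv, sum(mask$nf))
  expect_true(all(diff(mask$nf) <= 0))
  for (f in seq_along(mask$nf)) {
    run <- which(mask$mask[f, ])
    if (length(run)) {
      expect_equal(run, run[1]:(run[1] + length(run) - 1))  # contiguous
      # symmetric about the epoch center
      expect_equal(run[1] - 1, T_ - run[length(run)])
    }
    # guard-width arithmetic straight from the rule
    expect_equal(mask$nf[f],
                 max(0, T_ - 2 * ceiling(mask$e_fold * g$scales[f])))
  }
  # highest-frequency band: small guard, so nf close to T
  expect_equal(mask$nf[1], T_ - 2 * ceiling(mask$e_fold * g$scales[1]))
  expect_gt(mask$nf[1], T_ - 12)
})

test_that("default grid on a 1 s, 200 Hz epoch reproduces the reference COI geometry", {
  g <- build_scale_grid(fs = 200, n_samples = 200)
  mask <- compute_coi(g, 200)
  expect_identical(length(g$frequencies), 108L)
  expect_identical(mask$nv, 17056L)
})

test_that("Z-scalogram zeroes exactly the outside-COI cells and is idempotent", {
  g <- build_scale_grid(fs = 64, n_samples = 64, voices_per_octave = 4,
                        octaves = 3)
  set.seed(3)
  s <- morlet_cwt(rnorm(64), g)
  mask <- compute_coi(g, 64)
  z <- make_z_scalogram(s, mask)
  expect_identical(z$kind, "Z")
  expect_equal(z$values[mask$mask], s$values[mask$mask])
  expect_true(all(z$values[!mask$mask] == 0))
  expect_equal(make_z_scalogram(z, mask)$values, z$values)
  # input untouched
  expect_false(all(s$values[!mask$mask] == 0))

  bad <- compute_coi(g, 32)
  expect_error(make_z_scalogram(s, bad), "shapes disagree")
})

test_that("V-vector concatenates bands in grid order, times increasing", {
  g <- build_scale_grid(fs = 64, n_samples = 64, voices_per_octave = 4,
                        octaves = 3)
  set.seed(4)
  s <- morlet_cwt(rnorm(64), g)
  mask <- compute_coi(g, 64)
  v <- make_v_vector(s, mask)
  expect_length(v$values, mask$nv)
  expect_equal(v$values[seq_len(mask$nf[1])], s$values[1, mask$mask[1, ]])
  f2 <- v$band_offsets[2]:(v$band_offsets[2] + mask$nf[2] - 1)
  expect_equal(v$values[f2], s$values[2, mask$mask[2, ]])

  ones <- s; ones$values[] <- 1
  expect_equal(make_v_vector(ones, mask)$values, rep(1, mask$nv))

  # consistency with the Z-scalogram: same multiset of in-COI values
  z <- make_z_scalogram(s, mask)
  expect_equal(sort(v$values), sort(z$values[mask$mask]))
})
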