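#' Analytic Morlet scale grid
#'
#' Builds the geometric frequency/scale grid used by all scalogram
#' computations. Bands descend from `fmax` (default Nyquist) in steps of
#' `2^(-1/voices_per_octave)`, spanning `octaves` octaves, so the grid has
#' `voices_per_octave * octaves` bands. The scale of a band is the number of
#' samples per Gaussian-envelope standard deviation of its wavelet,
#' `scale = f0 * fs / frequency`, where `f0` is the Morlet center frequency
#' in cycles per sample.
#'
#' The defaults (27 voices, 4 octaves, `omega0 = 6`) give a 108-band grid
#' spanning 6.4--100 Hz for a 1 s epoch sampled at 200 Hz, matching the
#' reference scalogram geometry (108 bands, 17,056 in-COI coefficients with
#' the default cone-of-influence rule, see [compute_coi()]).
#'
#' @param fs Sampling rate in Hz.
#' @param n_samples Epoch length in samples (used only to warn when the
#'   lowest band completes less than one cycle in the epoch).
#' @param voices_per_octave Bands per octave (integer >= 1).
#' @param octaves Number of octaves spanned (integer >= 1).
#' @param f0 Morlet center frequency in cycles per sample; the default
#'   corresponds to the canonical `omega0 = 6` rad/sample.
#' @param fmax Highest band center frequency in Hz; must not exceed Nyquist.
#' @param sigma Gaussian window standard deviation of the mother wavelet in
#'   scale units (leave at 1 for the standard Morlet).
#' @return A `scale_grid` object with fields `frequencies` (Hz, strictly
#'   decreasing), `scales` (samples), `voices_per_octave`, `octaves`, `f0`,
#'   `sigma`, `fs`, and `norm_constant` (per-band unit-energy constants A).
#' @seealso [morlet_cwt()], [compute_coi()], [morlet_daughter()]
#' @export
#' @examples
#' g <- build_scale_grid(fs = 200, n_samples = 200)
#' length(g$frequencies)  # 108
build_scale_grid <- function(fs, n_samples,
                             voices_per_octave = 27L, octaves = 4L,
                             f0 = 6 / (2 * pi), fmax = fs / 2,
                             sigma = 1) {
  stopifnot(fs > 0, n_samples >= 4, voices_per_octave >= 1, octaves >= 1,
            f0 > 0, sigma > 0)
  if (fmax > fs / 2 + 1e-12) {
    stop("highest band frequency (", fmax, " Hz) exceeds Nyquist (",
         fs / 2, " Hz)")
  }
  nb <- as.integer(voices_per_octave) * as.integer(octaves)
  freqs <- fmax * 2^(-(seq_len(nb) - 1) / voices_per_octave)
  scales <- f0 * fs / freqs
  if (min(freqs) < fs / n_samples) {
    warning("lowest band (", signif(min(freqs), 4),
            " Hz) completes less than one cycle in ", n_samples,
            " samples; its coefficients fall outside the COI")
  }
  grid <- structure(
    list(frequencies = freqs, scales = scales,
         voices_per_octave = as.integer(voices_per_octave),
         octaves = as.integer(octaves),
         f0 = f0, sigma = sigma, fs = fs,
         norm_constant = rep(NA_real_, nb),
         cache = new.env(parent = emptyenv())),   # daughter-spectrum memo
    class = "scale_grid")
  grid$norm_constant <- vapply(seq_len(nb), function(f) {
    attr(morlet_daughter(grid, f, normalized = FALSE), "norm_constant")
  }, numeric(1))
  grid
}

#' @export
print.scale_grid <- function(x, ...) {
  cat(sprintf(
    "<scale_grid> %d bands (%d voices x %d octaves), %.3f-%.3f Hz, fs=%g Hz\n",
    length(x$frequencies), x$voices_per_octave, x$octaves,
    min(x$frequencies), max(x$frequencies), x$fs))
  invisible(x)
}

#' Sampled analytic Morlet daughter wavelet
#'
#' Returns the discrete daughter wavelet of one band: a complex exponential
#' at the band frequency under a Gaussian envelope whose standard deviation
#' equals the band scale (in samples), truncated at six envelope SDs and
#' normalized to unit discrete L2 energy.
#'
#' @param grid A [build_scale_grid()] grid.
#' @param band Band index (1 = highest frequency).
#' @param normalized If `FALSE`, return the unnormalized samples (the
#'   unit-energy constant is attached as attribute `norm_constant` either way).
#' @return Complex vector over sample offsets `-L..L`, with attributes
#'   `offsets` and `norm_constant`.
#' @export
morlet_daughter <- function(grid, band, normalized = TRUE) {
  stopifnot(inherits(grid, "scale_grid"),
            band >= 1, band <= length(grid$scales))
  a <- grid$scales[band]
  sd_samp <- grid$sigma * a
  L <- ceiling(6 * sd_samp)
  n <- seq.int(-L, L)
  psi <- exp(-n^2 / (2 * sd_samp^2)) * exp(1i * 2 * pi * grid$f0 * n / a)
  A <- 1 / sqrt(sum(Mod(psi)^2))
  out <- if (normalized) A * psi else psi
  attr(out, "offsets") <- n
  attr(out, "norm_constant") <- A
  out
}

# Daughter spectra for a given epoch length, shared across calls: one
# nfft-point FFT per band of Conj(rev(psi)) (correlation kernels), at a
# common nfft that accommodates the widest daughter without wraparound.
.daughter_spectra <- function(grid, T_) {
  Ls <- ceiling(6 * grid$sigma * grid$scales)
  nfft <- stats::nextn(T_ + 2 * max(Ls), 2)
  key <- sprintf("T%d", T_)
  memo <- grid$cache[[key]]
  if (is.null(memo)) {
    nb <- length(grid$scales)
    HF <- matrix(0 + 0i, nfft, nb)
    for (f in seq_len(nb)) {
      g <- Conj(rev(morlet_daughter(grid, f)))
      HF[, f] <- stats::fft(c(g, rep(0, nfft - length(g))))
    }
    memo <- list(HF = HF, L = Ls, nfft = nfft)
    grid$cache[[key]] <- memo
  }
  memo
}

#' Morlet scalogram of a single epoch (S-scalogram)
#'
#' Computes the amplitude scalogram `|G[f, t]|` of the analytic Morlet
#' continuous wavelet transform, one row per grid band, using zero-padded
#' "same" convolution so the output has the same duration as the input.
#' Daughters have unit L2 energy; each band is then rescaled by
#' `scale^(-1/2)` so a pure sinusoid elicits the same peak amplitude in
#' every band (the L1 convention used for display scalograms), which keeps
#' the band of maximal response aligned with a tone's frequency.
#'
#' @param signal Numeric vector (one epoch, length T).
#' @param grid A [build_scale_grid()] grid.
#' @param power If `TRUE` return squared magnitudes instead of amplitudes.
#' @return A `scalogram` object: `values` (F x T, non-negative), `grid`,
#'   `fs`, `kind = "S"`, `power`.
#' @export
morlet_cwt <- function(signal, grid, power = FALSE) {
  stopifnot(inherits(grid, "scale_grid"), is.numeric(signal))
  bad <- which(!is.finite(signal))
  if (length(bad)) {
    stop("non-finite sample(s) in signal at index ", bad[1])
  }
  T_ <- length(signal)
  nb <- length(grid$frequencies)
  sp <- .daughter_spectra(grid, T_)
  X <- stats::fft(c(signal, rep(0, sp$nfft - T_)))
  vals <- matrix(0, nrow = nb, ncol = T_)
  for (f in seq_len(nb)) {
    full <- stats::fft(X * sp$HF[, f], inverse = TRUE) / sp$nfft
    w <- Mod(full[(sp$L[f] + 1L):(sp$L[f] + T_)]) / sqrt(grid$scales[f])
    vals[f, ] <- if (power) w^2 else w
  }
  structure(list(values = vals, grid = grid, fs = grid$fs,
                 kind = "S", power = power),
            class = "scalogram")
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("<scalogram kind=%s> %d bands x %d samples, fs=%g Hz\n",
              x$kind, nrow(x$values), ncol(x$values), x$fs))
  invisible(x)
}

#' Cone of influence of a scale grid
#'
#' For each band, coefficients are flagged accurate (inside the COI) when
#' they lie at least `w(f) = ceiling(e_fold * scale(f))` samples from both
#' epoch edges; edge-padded coefficients outside that guard are artifacts.
#' Bands whose guard covers the whole epoch have no accurate coefficients.
#'
#' The default `e_fold = 2.0147` (about two Gaussian-envelope standard
#' deviations) is calibrated so that the default 108-band grid on a
#' 200-sample, 200 Hz epoch retains exactly 17,056 in-COI coefficients, the
#' reference COI geometry of the method. It is exposed so other COI
#' conventions (e.g. the sqrt(2) e-folding guard) can be selected.
#'
#' @param grid A [build_scale_grid()] grid.
#' @param n_samples Epoch duration T in samples.
#' @param e_fold COI guard width in units of the band scale.
#' @return A `coi_mask` object: `mask` (F x T logical, `TRUE` = accurate),
#'   `nf` (per-band in-COI durations), `nv` (total in-COI count), `width`
#'   (per-band guard widths), `e_fold`.
#' @export
#' @examples
#' g <- build_scale_grid(fs = 200, n_samples = 200)
#' compute_coi(g, 200)$nv  # 17056
compute_coi <- function(grid, n_samples, e_fold = 2.0147) {
  stopifnot(inherits(grid, "scale_grid"), n_samples >= 1, e_fold > 0)
  nb <- length(grid$scales)
  w <- as.integer(ceiling(e_fold * grid$scales))
  mask <- matrix(FALSE, nrow = nb, ncol = n_samples)
  for (f in seq_len(nb)) {
    if (2L * w[f] < n_samples) {
      mask[f, (w[f] + 1L):(n_samples - w[f])] <- TRUE
    }
  }
  nf <- as.integer(rowSums(mask))
  structure(list(mask = mask, nf = nf, nv = sum(nf), width = w,
                 e_fold = e_fold),
            class = "coi_mask")
}

#' @export
print.coi_mask <- function(x, ...) {
  cat(sprintf("<coi_mask> %d bands x %d samples, NV=%d (e_fold=%g)\n",
              nrow(x$mask), ncol(x$mask), x$nv, x$e_fold))
  invisible(x)
}

.check_scalogram_mask <- function(s, mask) {
  stopifnot(inherits(s, "scalogram"), inherits(mask, "coi_mask"))
  if (!all(dim(s$values) == dim(mask$mask))) {
    stop("scalogram (", paste(dim(s$values), collapse = "x"),
         ") and COI mask (", paste(dim(mask$mask), collapse = "x"),
         ") shapes disagree")
  }
}

#' Z-scalogram: zero out coefficients outside the COI
#'
#' @param s An S-scalogram from [morlet_cwt()].
#' @param mask A [compute_coi()] mask of matching shape.
#' @return A `scalogram` with `kind = "Z"`; values equal `s` inside the COI
#'   and are exactly 0 outside. The input is not modified.
#' @export
make_z_scalogram <- function(s, mask) {
  .check_scalogram_mask(s, mask)
  z <- s
  z$values <- s$values * mask$mask
  z$kind <- "Z"
  z
}

#' V-feature vector: concatenated in-COI coefficients
#'
#' Concatenates, band 1 (highest frequency) first, each band's in-COI
#' coefficients in increasing time order. This is the row-concatenation of
#' the V-scalogram (the coefficients a "valid" convolution would produce).
#'
#' @inheritParams make_z_scalogram
#' @return A `v_vector` object: `values` (length `mask$nv`), `band_offsets`
#'   (1-based start index of each band's segment), `nf`.
#' @export
make_v_vector <- function(s, mask) {
  .check_scalogram_mask(s, mask)
  vals <- as.numeric(t(s$values)[t(mask$mask)])
  offs <- cumsum(c(1L, mask$nf[-length(mask$nf)]))
  structure(list(values = vals, band_offsets = as.integer(offs),
                 nf = mask$nf),
            class = "v_vector")
}

#' @export
print.v_vector <- function(x, ...) {
  cat(sprintf("<v_vector> NV=%d over %d bands\n",
              length(x$values), length(x$nf)))
  invisible(x)
}
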