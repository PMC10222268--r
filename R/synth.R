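#' Configuration for the synthetic multi-subject ERP simulator
#'
#' Describes a two-or-more-class, multichannel, multi-subject ERP study in
#' which classes differ by channel-specific oscillatory bursts embedded in
#' 1/f background noise. The defaults emulate the shape of the 5-subject,
#' 64-channel, 200 Hz, 1 s, 195-trials-per-class auditory ERP study the
#' method was demonstrated on: two classes distinguished by burst frequency
#' and latency differences on eight posterior-like channels.
#'
#' @param n_subjects,n_channels,n_trials_per_class,n_classes,fs,n_samples
#'   Study shape; `fs` in Hz, `n_samples` per epoch.
#' @param bursts data.frame with columns `class`, `channel`, `freq` (Hz),
#'   `latency` (s), `duration` (s, full width of the Gaussian envelope at
#'   ~2 SD), `amplitude` (microvolt scale). One row per burst; channels
#'   whose burst sets differ between classes are the discriminative
#'   channels.
#' @param noise_exponent 1/f spectral exponent of the background noise.
#' @param noise_sd Broadband background noise SD per channel (microvolts).
#' @param alpha_amplitude Amplitude of a 10 Hz rhythm shared by all
#'   channels within a trial (makes channels correlated, random phase per
#'   trial).
#' @param amp_jitter_sd Subject-level multiplicative amplitude jitter
#'   (lognormal sdlog).
#' @param latency_jitter_sd Subject-level latency jitter SD in seconds.
#' @param freq_jitter_sd Subject-level burst-frequency jitter SD in Hz
#'   (the individual-rhythm-frequency analog; shifts all of a subject's
#'   bursts by one draw).
#' @param channels_per_trial If set, each trial expresses its class's
#'   bursts on a random subset of this many of the class's burst channels
#'   (complementary-information regime: no single channel carries the
#'   class difference on every trial, but the channel ensemble always
#'   does). `NULL` expresses every burst on every trial.
#' @param snr Global multiplier on all burst amplitudes.
#' @param seed Simulation seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects = 5L, n_channels = 64L,
                         n_trials_per_class = 195L, n_classes = 2L,
                         fs = 200, n_samples = 200L,
                         bursts = NULL,
                         noise_exponent = 1, noise_sd = 1,
                         alpha_amplitude = 0.5,
                         amp_jitter_sd = 0.2, latency_jitter_sd = 0.02,
                         freq_jitter_sd = 0, channels_per_trial = NULL,
                         snr = 1, seed = 1L) {
  if (is.null(bursts)) {
    bursts <- rbind(
      data.frame(class = 1L, channel = 1:8, freq = 8, latency = 0.40,
                 duration = 0.30, amplitude = 2),
      data.frame(class = 2L, channel = 1:8, freq = 12, latency = 0.45,
                 duration = 0.30, amplitude = 2))
  }
  stopifnot(all(c("class", "channel", "freq", "latency", "duration",
                  "amplitude") %in% names(bursts)),
            all(bursts$class %in% seq_len(n_classes)),
            all(bursts$channel %in% seq_len(n_channels)))
  if (any(bursts$freq >= fs / 2)) {
    stop("burst frequency at or above Nyquist (", fs / 2, " Hz)")
  }
  if (any(bursts$latency + bursts$duration > n_samples / fs)) {
    stop("burst latency + duration exceeds the epoch duration")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_channels = as.integer(n_channels),
    n_trials_per_class = as.integer(n_trials_per_class),
    n_classes = as.integer(n_classes), fs = fs,
    n_samples = as.integer(n_samples), bursts = bursts,
    noise_exponent = noise_exponent, noise_sd = noise_sd,
    alpha_amplitude = alpha_amplitude, amp_jitter_sd = amp_jitter_sd,
    latency_jitter_sd = latency_jitter_sd,
    freq_jitter_sd = freq_jitter_sd,
    channels_per_trial = if (is.null(channels_per_trial)) NULL else
      as.integer(channels_per_trial),
    snr = snr,
    seed = as.integer(seed)), class = "synth_config")
}

#' Channels carrying class information under a configuration
#'
#' @param cfg A [synth_config()].
#' @return Sorted integer vector of channels whose burst parameters differ
#'   between at least two classes.
#' @export
discriminative_channels <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  chans <- sort(unique(cfg$bursts$channel))
  keep <- vapply(chans, function(ch) {
    per_class <- lapply(seq_len(cfg$n_classes), function(cl) {
      b <- cfg$bursts[cfg$bursts$channel == ch & cfg$bursts$class == cl,
                      c("freq", "latency", "duration", "amplitude")]
      b[order(b$freq, b$latency), , drop = FALSE]
    })
    rows <- vapply(per_class, nrow, integer(1))
    length(unique(rows)) > 1 ||
      any(!vapply(per_class[-1], function(b) {
        isTRUE(all.equal(as.matrix(b), as.matrix(per_class[[1]]),
                         check.attributes = FALSE))
      }, logical(1)))
  }, logical(1))
  chans[keep]
}

# 1/f^exponent noise via spectral shaping of white noise, unit SD.
.pink_noise <- function(n, exponent, rng) {
  w <- rng$rnorm(n)
  if (exponent == 0) return(w)
  sp <- stats::fft(w)
  k <- seq_len(n - 1)
  shape <- c(0, pmin(k, n - k)^(-exponent / 2))  # symmetric, DC removed
  x <- Re(stats::fft(sp * shape, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

.gauss_burst <- function(tgrid, freq, latency, duration, amplitude) {
  sdv <- duration / 4               # ~2 SD each side inside `duration`
  center <- latency + duration / 2
  amplitude * exp(-(tgrid - center)^2 / (2 * sdv^2)) *
    sin(2 * pi * freq * (tgrid - center))
}

#' Simulate a multi-subject, multichannel ERP study
#'
#' For each subject, class and trial the signal on every channel is the sum
#' of that class's Gaussian-windowed sinusoidal bursts on its burst
#' channels (with subject-level amplitude and latency jitter), 1/f
#' background noise (independent across channels), and a shared 10 Hz
#' rhythm (common to all channels within a trial). Deterministic per seed.
#'
#' @param cfg A [synth_config()].
#' @return An [epoch_set()]; trials are ordered subject-major, then class,
#'   then trial. Subjects are `"S1" ... "Sn"`.
#' @export
simulate_group <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  rng <- new_rng(cfg$seed)
  T_ <- cfg$n_samples
  tgrid <- (seq_len(T_) - 1) / cfg$fs
  q_total <- cfg$n_subjects * cfg$n_classes * cfg$n_trials_per_class
  dat <- array(0, dim = c(q_total, cfg$n_channels, T_))
  labels <- integer(q_total)
  subjects <- character(q_total)
  # class templates per channel (before subject jitter)
  i <- 0L
  for (s in seq_len(cfg$n_subjects)) {
    amp_fac <- rng$rlnorm(1, 0, cfg$amp_jitter_sd)
    lat_off <- rng$rnorm(1, 0, cfg$latency_jitter_sd)
    frq_off <- rng$rnorm(1, 0, cfg$freq_jitter_sd)
    for (cl in seq_len(cfg$n_classes)) {
      bs <- cfg$bursts[cfg$bursts$class == cl, , drop = FALSE]
      template <- matrix(0, cfg$n_channels, T_)
      for (b in seq_len(nrow(bs))) {
        template[bs$channel[b], ] <- template[bs$channel[b], ] +
          .gauss_burst(tgrid, bs$freq[b] + frq_off,
                       bs$latency[b] + lat_off,
                       bs$duration[b], bs$amplitude[b] * cfg$snr * amp_fac)
      }
      burst_chans <- sort(unique(bs$channel))
      gate_k <- cfg$channels_per_trial
      for (tr in seq_len(cfg$n_trials_per_class)) {
        i <- i + 1L
        sig <- template
        if (!is.null(gate_k) && gate_k < length(burst_chans)) {
          off <- burst_chans[-rng$sample(length(burst_chans), gate_k)]
          sig[off, ] <- 0
        }
        if (cfg$noise_sd > 0) {
          for (ch in seq_len(cfg$n_channels)) {
            sig[ch, ] <- sig[ch, ] +
              cfg$noise_sd * .pink_noise(T_, cfg$noise_exponent, rng)
          }
        }
        if (cfg$alpha_amplitude > 0) {
          phase <- rng$runif(1, 0, 2 * pi)
          alpha <- cfg$alpha_amplitude * sin(2 * pi * 10 * tgrid + phase)
          sig <- sig + rep(alpha, each = cfg$n_channels)
        }
        dat[i, , ] <- sig
        labels[i] <- cl
        subjects[i] <- paste0("S", s)
      }
    }
  }
  epoch_set(dat, cfg$fs, labels, subjects,
            sprintf("ch%02d", seq_len(cfg$n_channels)))
}

#' Canned small simulation fixtures
#'
#' Three fixed-seed configurations sized for fast end-to-end tests
#' (8 channels, 40 trials/class, 64 samples at 64 Hz):
#' \describe{
#'   \item{easy}{high SNR; only channels 2 and 5 carry class information
#'     (burst frequency 6 vs 10 Hz), 2 subjects.}
#'   \item{medium}{complementary-information regime: class difference is
#'     a 6 vs 9 Hz burst on channels 1--4, but each trial expresses it on
#'     a random 2 of the 4 (so no single channel sees the difference on
#'     every trial while the 4-channel ensemble always does); marked
#'     subject-level amplitude/latency/frequency variability; 3 subjects.}
#'   \item{hard}{the medium design at half the burst amplitude.}
#' }
#'
#' @param level `"easy"`, `"medium"` or `"hard"`.
#' @param seed Simulation seed (fixed default per level).
#' @return An [epoch_set()]; the generating `synth_config` is attached as
#'   attribute `"config"`.
#' @export
make_fixture <- function(level = c("easy", "medium", "hard"), seed = NULL) {
  level <- match.arg(level)
  base <- list(n_channels = 8L, n_trials_per_class = 40L, n_classes = 2L,
               fs = 64, n_samples = 64L, noise_exponent = 1,
               alpha_amplitude = 0.3)
  cfg <- switch(level,
    easy = do.call(synth_config, c(base, list(
      n_subjects = 2L, noise_sd = 0.6,
      amp_jitter_sd = 0.1, latency_jitter_sd = 0.01,
      bursts = rbind(
        data.frame(class = 1L, channel = c(2L, 5L), freq = 6, latency = 0.3,
                   duration = 0.4, amplitude = 3),
        data.frame(class = 2L, channel = c(2L, 5L), freq = 10, latency = 0.35,
                   duration = 0.4, amplitude = 3)),
      seed = if (is.null(seed)) 101L else seed))),
    medium = do.call(synth_config, c(base, list(
      n_subjects = 3L, noise_sd = 1, channels_per_trial = 2L,
      amp_jitter_sd = 0.4, latency_jitter_sd = 0.05, freq_jitter_sd = 1.8,
      bursts = rbind(
        data.frame(class = 1L, channel = 1:4, freq = 6, latency = 0.3,
                   duration = 0.35, amplitude = 1.6),
        data.frame(class = 2L, channel = 1:4, freq = 9, latency = 0.33,
                   duration = 0.35, amplitude = 1.6)),
      seed = if (is.null(seed)) 202L else seed))),
    hard = do.call(synth_config, c(base, list(
      n_subjects = 3L, noise_sd = 1, channels_per_trial = 2L,
      amp_jitter_sd = 0.4, latency_jitter_sd = 0.05, freq_jitter_sd = 1.8,
      bursts = rbind(
        data.frame(class = 1L, channel = 1:4, freq = 6, latency = 0.3,
                   duration = 0.35, amplitude = 0.8),
        data.frame(class = 2L, channel = 1:4, freq = 9, latency = 0.33,
                   duration = 0.35, amplitude = 0.8)),
      seed = if (is.null(seed)) 303L else seed))))
  out <- simulate_group(cfg)
  attr(out, "config") <- cfg
  out
}
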