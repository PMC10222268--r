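# Independent brute-force oracles used across the suite. These deliberately
# re-derive results from definitions (direct sums, explicit loops) and share
# no code with the implementation paths they check.

# Direct inner-product CWT: G[f, t] = sum_n x[n] * conj(psi_f[n - t]),
# evaluated term by term, then the same per-band 1/sqrt(scale) rescaling.
oracle_cwt <- function(signal, grid) {
  T_ <- length(signal)
  nb <- length(grid$frequencies)
  out <- matrix(0, nb, T_)
  for (f in seq_len(nb)) {
    h <- merpnet::morlet_daughter(grid, f)
    off <- attr(h, "offsets")
    for (t in seq_len(T_)) {
      acc <- 0 + 0i
      for (k in seq_along(off)) {
        n <- t + off[k]
        if (n >= 1 && n <= T_) acc <- acc + signal[n] * Conj(h[k])
      }
      out[f, t] <- Mod(acc) / sqrt(grid$scales[f])
    }
  }
  out
}

# Brute-force full-depth "same" cross-correlation of an H x W x C input with
# one kh x kw x C filter (quadruple loop over the definition).
oracle_conv_full_depth <- function(x, w, b = 0) {
  dh <- dim(x)[1]; dw <- dim(x)[2]; dc <- dim(x)[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]
  a <- (kh - 1) %/% 2; bb <- (kw - 1) %/% 2
  out <- matrix(0, dh, dw)
  for (i in seq_len(dh)) for (j in seq_len(dw)) {
    acc <- b
    for (r in -a:a) for (u in -bb:bb) for (c in seq_len(dc)) {
      ii <- i + r; jj <- j + u
      if (ii >= 1 && ii <= dh && jj >= 1 && jj <= dw) {
        acc <- acc + w[r + a + 1, u + bb + 1, c] * x[ii, jj, c]
      }
    }
    out[i, j] <- acc
  }
  out
}

make_tiny_epochs <- function(q = 6, c = 3, t = 16, fs = 16, seed = 42,
                             labels = rep(1:2, length.out = q),
                             subjects = rep("s1", q)) {
  set.seed(seed)
  merpnet::epoch_set(array(rnorm(q * c * t), dim = c(q, c, t)), fs,
                     labels, subjects, paste0("ch", seq_len(c)))
}
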