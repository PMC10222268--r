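# Internal CNN engine.
#
# Feature maps live in a batched "column" layout: a (N*H*W) x C matrix whose
# rows are sample-major blocks of H*W grid positions (column-major within the
# H x W grid). Convolutions are computed by gathering im2col patches and
# multiplying with BLAS; backward scatters through the same index maps. All
# convolutions are zero-padded "same" cross-correlations, matching the
# models' stated convention.

# (H*W) x (kh*kw) patch index map; 0 marks an out-of-bounds (zero-padded)
# tap. Kernel offsets are centered: r in -a..a, u in -b..b.
.im2col_idx <- function(H, W, kh, kw) {
  a <- (kh - 1L) %/% 2L
  b <- (kw - 1L) %/% 2L
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, kh * kw)
  k <- 0L
  for (u in -b:b) for (r in -a:a) {
    k <- k + 1L
    ii <- i + r
    jj <- j + u
    ok <- ii >= 1L & ii <= H & jj >= 1L & jj <= W
    idx[, k] <- ifelse(ok, ii + (jj - 1L) * H, 0L)
  }
  idx
}

# Absolute batched indices: base map shifted per sample block (0 stays 0).
.batch_idx <- function(idx0, N, HW) {
  shift <- rep((seq_len(N) - 1L) * HW, each = nrow(idx0))
  out <- idx0[rep(seq_len(nrow(idx0)), N), , drop = FALSE]
  out + (out > 0L) * shift
}

.conv_def <- function(kh, kw, cin, nf, H, W) {
  list(type = "conv", kh = kh, kw = kw, cin = cin, nf = nf, H = H, W = W,
       idx0 = .im2col_idx(H, W, kh, kw),
       cache = new.env(parent = emptyenv()),   # batch-index memo per N
       out = c(H, W, nf))
}

.conv_big <- function(def, N) {
  key <- as.character(N)
  big <- def$cache[[key]]
  if (is.null(big)) {
    big <- .batch_idx(def$idx0, N, def$H * def$W) + 1L  # 1-based into Aaug
    def$cache[[key]] <- big
  }
  big
}

.pool_def <- function(H, W, C) {
  H <- as.integer(H); W <- as.integer(W); C <- as.integer(C)
  H2 <- H %/% 2L
  W2 <- W %/% 2L
  i2 <- rep(seq_len(H2), times = W2)
  j2 <- rep(seq_len(W2), each = H2)
  taps <- cbind((2L * i2 - 1L) + (2L * j2 - 2L) * H,
                (2L * i2) + (2L * j2 - 2L) * H,
                (2L * i2 - 1L) + (2L * j2 - 1L) * H,
                (2L * i2) + (2L * j2 - 1L) * H)
  list(type = "pool", H = H, W = W, C = C, H2 = H2, W2 = W2, taps = taps,
       cache = new.env(parent = emptyenv()),
       out = c(H2, W2, C))
}

.pool_rows <- function(def, N) {
  key <- as.character(N)
  rows <- def$cache[[key]]
  if (is.null(rows)) {
    shift <- rep((seq_len(N) - 1L) * def$H * def$W,
                 each = def$H2 * def$W2)
    rows <- vapply(1:4, function(t) rep(def$taps[, t], N) + shift,
                   integer(N * def$H2 * def$W2))
    rows <- matrix(rows, ncol = 4)
    def$cache[[key]] <- rows
  }
  rows
}

.conv_forward <- function(def, par, A, N) {
  big <- .conv_big(def, N)
  Y <- .cpp_conv_fwd(A, par$W, par$b, big, def$kh * def$kw, def$cin)
  list(Y = Y, X = A, big = big)
}

.conv_backward <- function(def, par, cache, dY, N, need_input_grad = TRUE) {
  r <- .cpp_conv_bwd(cache$X, par$W, dY, cache$big, def$kh * def$kw,
                     def$cin, need_input_grad)
  list(dA = r$dA, dW = r$dW, db = as.numeric(r$db))
}

.pool_forward <- function(def, A, N) {
  .cpp_pool_fwd(A, .pool_rows(def, N))
}

.pool_backward <- function(def, cache, dY, N) {
  .cpp_pool_bwd(dY, cache$arg, .pool_rows(def, N), N * def$H * def$W)
}

# Reshape an (N*HW) x C map to an N x (HW*C) matrix (channel-major columns,
# grid position fastest), and back.
.flatten_fw <- function(A, HW, N) {
  matrix(aperm(array(A, dim = c(HW, N, ncol(A))), c(2, 1, 3)), nrow = N)
}
.flatten_bw <- function(dF, HW, N, C) {
  matrix(aperm(array(dF, dim = c(N, HW, C)), c(2, 1, 3)), ncol = C)
}

# Reinterpret an (N*H) x C map as a single-channel (N*(H*C)) x 1 image of
# height H and width C (the matrix-as-image step of the vector model).
.as_image_fw <- function(A, H, N) {
  matrix(aperm(array(A, dim = c(H, N, ncol(A))), c(1, 3, 2)), ncol = 1)
}
.as_image_bw <- function(dA, H, N, C) {
  matrix(aperm(array(dA, dim = c(H, C, N)), c(1, 3, 2)), ncol = C)
}

.init_params <- function(def, rng) {
  lapply(def$layers, function(ly) {
    switch(ly$type,
      conv = {
        fan_in <- ly$kh * ly$kw * ly$cin
        lim <- sqrt(1 / fan_in)
        list(W = matrix(rng$runif(fan_in * ly$nf, -lim, lim),
                        fan_in, ly$nf),
             b = rep(0, ly$nf))
      },
      dense = {
        lim <- sqrt(1 / ly$nin)
        list(W = matrix(rng$runif(ly$nin * ly$nout, -lim, lim),
                        ly$nin, ly$nout),
             b = rep(0, ly$nout))
      },
      NULL)
  })
}

# Forward pass; returns probabilities and (when `keep` is TRUE) the caches
# needed by the backward pass. Dropout masks are drawn from `rng` only when
# `train` is TRUE (inverted dropout).
.net_forward <- function(def, params, A0, N, train = FALSE, rng = NULL,
                         keep = train) {
  A <- A0
  caches <- vector("list", length(def$layers))
  for (li in seq_along(def$layers)) {
    ly <- def$layers[[li]]
    pa <- params[[li]]
    if (ly$type == "conv") {
      cf <- .conv_forward(ly, pa, A, N)
      if (keep) caches[[li]] <- cf[c("X", "big")]
      A <- cf$Y
    } else if (ly$type == "relu") {
      A <- pmax(A, 0)
      if (keep) caches[[li]] <- list(mask = A > 0)
    } else if (ly$type == "pool") {
      pf <- .pool_forward(ly, A, N)
      if (keep) caches[[li]] <- pf["arg"]
      A <- pf$Y
    } else if (ly$type == "flatten") {
      A <- .flatten_fw(A, ly$HW, N)
      if (keep) caches[[li]] <- list(C = ly$C)
    } else if (ly$type == "as_image") {
      if (keep) caches[[li]] <- list(C = ncol(A))
      A <- .as_image_fw(A, ly$H, N)
    } else if (ly$type == "dense") {
      if (keep) caches[[li]] <- list(X = A)
      A <- A %*% pa$W + rep(pa$b, each = nrow(A))
    } else if (ly$type == "tanh") {
      A <- tanh(A)
      if (keep) caches[[li]] <- list(Y = A)
    } else if (ly$type == "dropout") {
      if (train) {
        m <- (rng$runif(length(A)) >= ly$p) / (1 - ly$p)
        dim(m) <- dim(A)
        A <- A * m
        if (keep) caches[[li]] <- list(m = m)
      } else if (keep) {
        caches[[li]] <- list(m = 1)
      }
    }
  }
  # softmax over the final logits
  z <- A - apply(A, 1, max)
  ez <- exp(z)
  probs <- ez / rowSums(ez)
  list(probs = probs, caches = caches)
}

.net_backward <- function(def, params, caches, probs, labels, N) {
  grads <- vector("list", length(def$layers))
  G <- probs
  G[cbind(seq_len(nrow(G)), labels)] <-
    G[cbind(seq_len(nrow(G)), labels)] - 1
  G <- G / nrow(G)                       # d(mean CE)/d(logits)
  for (li in rev(seq_along(def$layers))) {
    ly <- def$layers[[li]]
    pa <- params[[li]]
    ca <- caches[[li]]
    if (ly$type == "dense") {
      grads[[li]] <- list(W = crossprod(ca$X, G), b = colSums(G))
      G <- tcrossprod(G, pa$W)
    } else if (ly$type == "tanh") {
      G <- G * (1 - ca$Y^2)
    } else if (ly$type == "dropout") {
      G <- G * ca$m
    } else if (ly$type == "flatten") {
      G <- .flatten_bw(G, ly$HW, N, ly$C)
    } else if (ly$type == "as_image") {
      G <- .as_image_bw(G, ly$H, N, ca$C)
    } else if (ly$type == "pool") {
      G <- .pool_backward(ly, ca, G, N)
    } else if (ly$type == "relu") {
      G <- G * ca$mask
    } else if (ly$type == "conv") {
      cb <- .conv_backward(ly, pa, ca, G, N, need_input_grad = li > 1L)
      grads[[li]] <- list(W = cb$dW, b = cb$db)
      G <- cb$dA
    }
  }
  grads
}

.adam_init <- function(params) {
  lapply(params, function(pa) {
    if (is.null(pa)) return(NULL)
    list(mW = pa$W * 0, vW = pa$W * 0, mb = pa$b * 0, vb = pa$b * 0)
  })
}

# Updates parameters and moment estimates in place: the caller must own
# them privately (train_model deep-copies the initial weights first).
.adam_step <- function(params, grads, state, t, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (li in seq_along(params)) {
    pa <- params[[li]]
    if (is.null(pa)) next
    g <- grads[[li]]
    st <- state[[li]]
    .cpp_adam_step(pa$W, st$mW, st$vW, g$W, lr, beta1, beta2, eps, c1, c2)
    .cpp_adam_step(pa$b, st$mb, st$vb, g$b, lr, beta1, beta2, eps, c1, c2)
  }
  list(params = params, state = state)
}
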