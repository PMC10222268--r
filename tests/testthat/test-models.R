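small_spec <- function(kind, dims, ...) {
  model_spec(kind, dims, epochs = 5L, batch_size = 8L, ...)
}

test_that("layer shapes follow the four architectures", {
  sp <- model_spec("z_cuboid", c(108, 200, 4))
  def <- merpnet:::.build_def(sp)
  expect_equal(def$layers[[1]]$out, c(108, 200, 32))   # conv1 feature cuboid
  expect_equal(def$layers[[1]]$cin, 4)                 # full-depth filters
  expect_equal(sp$fcn_sizes, c(256L, 128L, 2L))

  spm <- model_spec("z_matrix", c(108, 200))
  defm <- merpnet:::.build_def(spm)
  pool <- defm$layers[[5]]
  expect_equal(pool$out, c(54, 100, 32))               # 2x2 stride-2 pool
  expect_equal(spm$fcn_sizes, c(128L, 64L, 2L))

  spv <- model_spec("v_vector", 500)
  defv <- merpnet:::.build_def(spv)
  expect_equal(defv$layers[[1]]$out, c(500, 1, 32))    # 32 column maps
  expect_equal(defv$layers[[4]]$cin, 1)                # NV x 32 as an image
  expect_equal(defv$layers[[4]]$H, 500)
  expect_equal(defv$layers[[4]]$W, 32)

  expect_error(model_spec("v_matrix", c(500, 1)), "v_vector")
})

test_that("conv layers match the brute-force cross-correlation oracle", {
  set.seed(21)
  for (dims in list(c(6, 8, 1), c(8, 8, 2), c(5, 7, 3))) {
    x <- array(rnorm(prod(dims)), dim = dims)
    def <- merpnet:::.conv_def(3L, 3L, dims[3], 2L, dims[1], dims[2])
    W <- matrix(rnorm(9 * dims[3] * 2, sd = 0.5), 9 * dims[3], 2)
    b <- rnorm(2)
    A <- matrix(as.numeric(x), ncol = dims[3])
    out <- merpnet:::.conv_forward(def, list(W = W, b = b), A, 1L)$Y
    for (n in 1:2) {
      # reorder flat weights (offset-major, channel fastest) into the
      # kh x kw x cin filter tensor the oracle loops over
      wt <- aperm(array(W[, n], dim = c(dims[3], 3, 3)), c(2, 3, 1))
      expect_equal(matrix(out[, n], dims[1], dims[2]),
                   oracle_conv_full_depth(x, wt, b[n]), tolerance = 1e-10)
    }
  }
})

test_that("the 1-D column convolution matches its direct-sum definition", {
  set.seed(22)
  nv <- 30
  x <- rnorm(nv)
  def <- merpnet:::.conv_def(9L, 1L, 1L, 1L, nv, 1L)
  w <- rnorm(9, sd = 0.5)
  out <- merpnet:::.conv_forward(def, list(W = matrix(w), b = 0),
                                 matrix(x), 1L)$Y
  direct <- sapply(seq_len(nv), function(ft) {
    acc <- 0
    for (r in -4:4) {
      n <- ft + r
      if (n >= 1 && n <= nv) acc <- acc + w[r + 5] * x[n]
    }
    acc
  })
  expect_equal(as.numeric(out), direct, tolerance = 1e-10)
})

test_that("max pooling halves dimensions and never exceeds pre-pool maxima", {
  set.seed(23)
  H <- 7; W <- 9; C <- 3  # odd dims: trailing row/column dropped
  A <- matrix(rnorm(H * W * C), H * W, C)
  def <- merpnet:::.pool_def(H, W, C)
  expect_equal(def$out, c(3, 4, 3))
  out <- merpnet:::.pool_forward(def, A, 1L)
  expect_true(all(out$Y <= max(A)))
  for (ch in 1:C) {
    img <- matrix(A[, ch], H, W)
    pooled <- matrix(out$Y[, ch], 3, 4)
    for (i in 1:3) for (j in 1:4) {
      expect_equal(pooled[i, j],
                   max(img[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)]))
    }
  }
})

test_that("forward posteriors normalize; zero input with zero bias is uniform", {
  for (kind in c("z_cuboid", "z_matrix", "v_matrix", "v_vector")) {
    dims <- switch(kind, z_cuboid = c(10, 12, 3), z_matrix = c(10, 12),
                   v_matrix = c(40, 4), v_vector = 40)
    m <- build_model(small_spec(kind, dims, n_classes = 3L), seed = 2)
    x <- switch(kind,
                z_cuboid = array(rnorm(360), dim = dims),
                z_matrix = matrix(rnorm(120), 10, 12),
                v_matrix = matrix(rnorm(160), 40, 4),
                v_vector = rnorm(40))
    p <- forward(m, x)
    expect_length(p, 3)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(sum(p), 1, tolerance = 1e-6)
    zero <- if (is.null(dim(x))) x * 0 else x * 0
    expect_equal(forward(m, zero), rep(1 / 3, 3), tolerance = 1e-12)
  }
})

test_that("shape mismatches are reported with expected vs got", {
  m <- build_model(small_spec("z_matrix", c(10, 12)))
  expect_error(forward(m, matrix(0, 10, 13)),
               "expected 10x12, got 10x13")
})

test_that("cuboid model at D=1 equals the matrix model in the conv stack", {
  set.seed(31)
  F_ <- 8; T_ <- 10
  mc <- build_model(small_spec("z_cuboid", c(F_, T_, 1)), seed = 5)
  mm <- build_model(small_spec("z_matrix", c(F_, T_)), seed = 6)
  # copy conv weights; heads differ per the architecture table
  mm$params[[1]] <- mc$params[[1]]
  mm$params[[3]] <- mc$params[[3]]
  x <- matrix(rnorm(F_ * T_), F_, T_)
  A <- matrix(as.numeric(x), ncol = 1)
  # run just the conv+pool stack
  run_stack <- function(m) {
    Acur <- A
    for (li in 1:5) {
      ly <- m$def$layers[[li]]
      if (ly$type == "conv") {
        Acur <- merpnet:::.conv_forward(ly, m$params[[li]], Acur, 1L)$Y
      } else if (ly$type == "relu") {
        Acur <- pmax(Acur, 0)
      } else if (ly$type == "pool") {
        Acur <- merpnet:::.pool_forward(ly, Acur, 1L)$Y
      }
    }
    Acur
  }
  expect_equal(run_stack(mc), run_stack(mm), tolerance = 1e-12)
})

test_that("decide applies the maximum response rule with low-index ties", {
  expect_equal(decide(c(0.7, 0.3)), 1L)
  expect_equal(decide(c(0.5, 0.5)), 1L)
  expect_equal(decide(c(0.2, 0.3, 0.5)), 3L)
  expect_equal(decide(rbind(c(0.1, 0.9), c(0.6, 0.4))), c(2L, 1L))
})

test_that("training is deterministic, separates easy classes, and logs loss", {
  set.seed(41)
  nv <- 60
  mk <- function(cl) {
    base <- rep(0, nv)
    if (cl == 1) base[10:20] <- 2 else base[35:45] <- 2
    base + rnorm(nv, sd = 0.3)
  }
  labels <- rep(1:2, each = 20)
  inputs <- lapply(labels, mk)
  # dropout off so the logged loss tracks the deterministic objective the
  # optimizer minimizes (dropout noise, not the optimizer, wobbles it)
  sp <- model_spec("v_vector", nv, epochs = 30L, batch_size = 40L,
                   dropout = 0)
  m1 <- train_model(build_model(sp, seed = 3), inputs, labels)
  expect_equal(m1$training_log$accuracy[30], 1)
  # loss mostly decreasing
  dl <- diff(m1$training_log$loss)
  expect_gte(mean(dl <= 1e-8), 0.9)
  m2 <- train_model(build_model(sp, seed = 3), inputs, labels)
  expect_identical(m1$params, m2$params)
  expect_identical(predict(m1, inputs[1:3]), predict(m2, inputs[1:3]))
  m3 <- train_model(build_model(sp, seed = 4), inputs, labels)
  expect_false(identical(m1$params, m3$params))
})

test_that("training rejects missing classes and out-of-range labels", {
  sp <- small_spec("v_vector", 20)
  m <- build_model(sp)
  xs <- lapply(1:6, function(i) rnorm(20))
  expect_error(train_model(m, xs, rep(1L, 6)), "absent")
  expect_error(train_model(m, xs, c(1L, 2L, 3L, 1L, 2L, 1L)), "1..2")
})

test_that("full-batch training is invariant to training-set permutation", {
  set.seed(51)
  nv <- 40
  labels <- rep(1:2, each = 10)
  inputs <- lapply(labels, function(cl) rnorm(nv) + (cl == 2) * 1.5)
  sp <- model_spec("v_vector", nv, epochs = 10L, batch_size = 20L)
  m1 <- train_model(build_model(sp, seed = 9), inputs, labels,
                    shuffle = FALSE)
  perm <- sample(20)
  m2 <- train_model(build_model(sp, seed = 9), inputs[perm], labels[perm],
                    shuffle = FALSE)
  test_in <- lapply(1:8, function(i) rnorm(nv))
  expect_equal(decide(predict(m1, test_in)), decide(predict(m2, test_in)))
})

test_that("checkpoints round-trip trained models", {
  sp <- small_spec("v_vector", 15)
  labels <- rep(1:2, 4)
  m <- train_model(build_model(sp, seed = 1),
                   lapply(labels, function(cl) rnorm(15) + cl), labels)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  xs <- lapply(1:3, function(i) rnorm(15))
  expect_identical(predict(back, xs), predict(m, xs))
})

test_that("numeric gradients confirm the backward pass end to end", {
  set.seed(61)
  sp <- model_spec("z_matrix", c(6, 6), epochs = 1L, dropout = 0,
                   n_filters = c(2L, 2L))
  m <- build_model(sp, seed = 8)
  inputs <- lapply(1:4, function(i) matrix(rnorm(36), 6, 6))
  labels <- c(1L, 2L, 1L, 2L)
  A0 <- merpnet:::.stack_inputs(sp, inputs)
  loss_at <- function(params) {
    out <- merpnet:::.net_forward(m$def, params, A0, 4L, keep = FALSE)
    -mean(log(out$probs[cbind(1:4, labels)]))
  }
  fw <- merpnet:::.net_forward(m$def, m$params, A0, 4L, train = FALSE,
                               keep = TRUE)
  grads <- merpnet:::.net_backward(m$def, m$params, fw$caches, fw$probs,
                                   labels, 4L)
  eps <- 1e-6
  for (li in c(1, 3, 7, 10)) {  # conv1, conv2, dense1, dense2
    pa <- m$params[[li]]
    if (is.null(pa)) next
    for (probe in list(c(1, 1), c(2, 1))) {
      pp <- m$params
      pp[[li]]$W[probe[1], probe[2]] <- pa$W[probe[1], probe[2]] + eps
      up <- loss_at(pp)
      pp[[li]]$W[probe[1], probe[2]] <- pa$W[probe[1], probe[2]] - eps
      dn <- loss_at(pp)
      expect_equal(grads[[li]]$W[probe[1], probe[2]], (up - dn) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})
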