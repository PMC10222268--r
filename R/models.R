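#' Specification of one of the four scalogram classification models
#'
#' The four convolutional classifiers share a common backbone -- two
#' zero-padded "same" convolution layers (32 filters each, ReLU), one 2x2
#' max-pooling layer with stride 2, and a three-layer fully connected head
#' (tanh, tanh, softmax) with dropout 0.15 on the two hidden layers --
#' and differ in their inputs and first-layer filters:
#' \describe{
#'   \item{z_cuboid}{input F x T x D cuboid of fused Z-scalograms; conv-1
#'     filters are 3 x 3 x D cuboids spanning all channels, conv-2 filters
#'     3 x 3 x 32; head 256, 128, classes.}
#'   \item{z_matrix}{input F x T Z-scalogram (unichannel); conv-1 filters
#'     3 x 3, conv-2 3 x 3 x 32; head 128, 64, classes.}
#'   \item{v_matrix}{input NV x D matrix of fused V-vectors; conv-1 filters
#'     3 x 3 sliding over both the frequency-time and the spatial axis,
#'     conv-2 3 x 3 x 32; head 256, 128, classes.}
#'   \item{v_vector}{input NV x 1 V-vector (unichannel); conv-1 filters
#'     9 x 1 columns, whose 32 output columns form an NV x 32 matrix that
#'     conv-2 scans with a single-channel 3 x 3 filter; head 128, 64,
#'     classes.}
#' }
#'
#' @param model_kind One of `"z_cuboid"`, `"z_matrix"`, `"v_matrix"`,
#'   `"v_vector"`.
#' @param input_dims Input shape: `c(F, T, D)` for `z_cuboid`, `c(F, T)`
#'   for `z_matrix`, `c(NV, D)` for `v_matrix` (`D >= 2`), `NV` for
#'   `v_vector`.
#' @param n_classes Number of classes (softmax width).
#' @param epochs,learning_rate,batch_size Training options (Adam).
#' @param dropout Dropout probability on the two hidden head layers.
#' @param n_filters Filters per convolution layer, `c(N1, N2)`.
#' @param normalize If `TRUE` (default) inputs are divided by the
#'   training-ensemble maximum absolute value (one global scalar stored
#'   with the model); `FALSE` trains on raw magnitudes.
#' @return A `model_spec` object.
#' @export
model_spec <- function(model_kind = c("z_cuboid", "z_matrix", "v_matrix",
                                      "v_vector"),
                       input_dims, n_classes = 2L, epochs = 50L,
                       learning_rate = 0.001, batch_size = 32L,
                       dropout = 0.15, n_filters = c(32L, 32L),
                       normalize = TRUE) {
  model_kind <- match.arg(model_kind)
  input_dims <- as.integer(input_dims)
  need <- switch(model_kind, z_cuboid = 3L, z_matrix = 2L, v_matrix = 2L,
                 v_vector = 1L)
  if (length(input_dims) != need) {
    stop(model_kind, " expects ", need, "-dimensional input_dims")
  }
  if (model_kind == "v_matrix" && input_dims[2] < 2L) {
    stop("v_matrix with D=1 is degenerate; use model_kind = \"v_vector\"")
  }
  fcn <- switch(model_kind,
                z_cuboid = c(256L, 128L), v_matrix = c(256L, 128L),
                z_matrix = c(128L, 64L), v_vector = c(128L, 64L))
  structure(list(model_kind = model_kind, input_dims = input_dims,
                 n_classes = as.integer(n_classes),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), dropout = dropout,
                 n_filters = as.integer(n_filters),
                 normalize = isTRUE(normalize),
                 fcn_sizes = c(fcn, as.integer(n_classes)),
                 fcn_activations = c("tanh", "tanh", "softmax")),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec %s> input %s, %d classes, head %s\n",
              x$model_kind, paste(x$input_dims, collapse = "x"),
              x$n_classes, paste(x$fcn_sizes, collapse = "-")))
  invisible(x)
}

# Static layer graph for a spec (shapes resolved once).
.build_def <- function(spec) {
  n1 <- spec$n_filters[1]
  n2 <- spec$n_filters[2]
  k <- spec$model_kind
  layers <- list()
  if (k == "z_cuboid" || k == "z_matrix") {
    H <- spec$input_dims[1]; W <- spec$input_dims[2]
    cin <- if (k == "z_cuboid") spec$input_dims[3] else 1L
    layers <- c(layers, list(.conv_def(3L, 3L, cin, n1, H, W),
                             list(type = "relu"),
                             .conv_def(3L, 3L, n1, n2, H, W),
                             list(type = "relu")))
    pool <- .pool_def(H, W, n2)
  } else if (k == "v_matrix") {
    H <- spec$input_dims[1]; W <- spec$input_dims[2]
    layers <- c(layers, list(.conv_def(3L, 3L, 1L, n1, H, W),
                             list(type = "relu"),
                             .conv_def(3L, 3L, n1, n2, H, W),
                             list(type = "relu")))
    pool <- .pool_def(H, W, n2)
  } else {  # v_vector
    H <- spec$input_dims[1]
    layers <- c(layers, list(.conv_def(9L, 1L, 1L, n1, H, 1L),
                             list(type = "relu"),
                             list(type = "as_image", H = H),
                             .conv_def(3L, 3L, 1L, n2, H, n1),
                             list(type = "relu")))
    pool <- .pool_def(H, n1, n2)
  }
  layers <- c(layers, list(pool))
  flat <- prod(pool$out)
  layers <- c(layers, list(list(type = "flatten",
                                HW = pool$H2 * pool$W2, C = pool$C)))
  nin <- flat
  for (h in seq_along(spec$fcn_sizes)) {
    nout <- spec$fcn_sizes[h]
    layers <- c(layers, list(list(type = "dense", nin = nin, nout = nout)))
    if (h < length(spec$fcn_sizes)) {
      layers <- c(layers, list(list(type = "tanh"),
                               list(type = "dropout", p = spec$dropout)))
    }
    nin <- nout
  }
  list(layers = layers)
}

#' Construct an (untrained) model from a specification
#'
#' Builds the layer graph and initializes weights with fan-in-scaled
#' uniform draws (zero biases), deterministically from `seed`.
#'
#' @param spec A [model_spec()].
#' @param seed Weight-initialization seed.
#' @return A `merp_model` with fields `spec`, `params`, `input_scale`
#'   (set during training), `training_log`, `seed`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  def <- .build_def(spec)
  rng <- new_rng(derive_seed(seed, 7))
  structure(list(spec = spec, def = def, params = .init_params(def, rng),
                 input_scale = 1, training_log = NULL,
                 seed = as.integer(seed), trained = FALSE),
            class = "merp_model")
}

#' @export
print.merp_model <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  %strained (seed %d)\n", if (x$trained) "" else "un",
              x$seed))
  invisible(x)
}

# Coerce a user-facing input (or a plain array) to the internal batched
# column layout; checks the shape against the spec.
.input_matrix <- function(spec, input) {
  vals <- if (inherits(input, "fusion_cuboid") ||
              inherits(input, "fusion_matrix")) {
    input$values
  } else if (inherits(input, "scalogram")) {
    input$values
  } else if (inherits(input, "v_vector")) {
    input$values
  } else {
    input
  }
  k <- spec$model_kind
  dims <- if (is.null(dim(vals))) length(vals) else dim(vals)
  want <- spec$input_dims
  if (k == "v_vector") {
    if (length(vals) != want[1]) {
      stop("input shape mismatch: expected length ", want[1], ", got ",
           length(vals))
    }
    return(matrix(as.numeric(vals), ncol = 1))
  }
  if (length(dims) != length(want) || !all(dims == want)) {
    stop("input shape mismatch: expected ", paste(want, collapse = "x"),
         ", got ", paste(dims, collapse = "x"))
  }
  if (k == "z_cuboid") {
    matrix(as.numeric(vals), ncol = want[3])  # columns = channels
  } else {
    matrix(as.numeric(vals), ncol = 1)
  }
}

.stack_inputs <- function(spec, inputs) {
  mats <- lapply(inputs, .input_matrix, spec = spec)
  do.call(rbind, mats)
}

#' Posterior class probabilities for one input
#'
#' Runs a forward pass (dropout inactive) and returns the softmax
#' posterior, one probability per class, summing to one.
#'
#' @param model A [build_model()] / [train_model()] model.
#' @param input A [fuse_cuboid()] cuboid, [morlet_cwt()]/Z scalogram,
#'   [fuse_matrix()] matrix, [make_v_vector()] vector, or a plain array of
#'   the spec's input shape.
#' @return Numeric vector of length `n_classes`.
#' @export
forward <- function(model, input) {
  stopifnot(inherits(model, "merp_model"))
  as.numeric(predict(model, list(input)))
}

#' @export
#' @rdname forward
#' @param object A `merp_model`.
#' @param inputs List of inputs (see [forward()]).
#' @param ... Unused.
predict.merp_model <- function(object, inputs, ...) {
  A0 <- .stack_inputs(object$spec, inputs) / object$input_scale
  out <- .net_forward(object$def, object$params, A0, length(inputs),
                      train = FALSE, keep = FALSE)
  out$probs
}

#' Maximum-response decision rule
#'
#' Assigns the class with the largest posterior probability; exact ties go
#' to the lowest class index.
#'
#' @param p Posterior probability vector (or matrix, one row per input).
#' @return Integer class label(s).
#' @export
decide <- function(p) {
  if (is.matrix(p)) return(max.col(p, ties.method = "first"))
  which.max(p)
}

#' Train a model by backpropagation
#'
#' Minimizes the cross-entropy loss for exactly `spec$epochs` passes of
#' mini-batch gradient descent with the Adam optimizer (learning rate
#' 0.001 by default), dropout active only during training. The epoch order
#' is reshuffled each epoch from the model seed, so training is
#' deterministic given the seed. When `spec$normalize` was left `TRUE`
#' at [model_spec()] time the single scalar `max(abs(inputs))` of the
#' training ensemble is stored and divides all inputs, at train and test
#' time alike.
#'
#' @param model A [build_model()] model.
#' @param inputs List of training inputs conforming to the spec.
#' @param labels Integer class labels in `1..n_classes`.
#' @param shuffle Reshuffle batch composition every epoch (default TRUE;
#'   with `FALSE` batches follow the given order).
#' @param normalize Override the spec's input normalization flag.
#' @return The trained `merp_model`; `training_log` holds per-epoch mean
#'   loss and training accuracy.
#' @export
train_model <- function(model, inputs, labels, shuffle = TRUE,
                        normalize = NULL) {
  stopifnot(inherits(model, "merp_model"), length(inputs) == length(labels))
  spec <- model$spec
  labels <- as.integer(labels)
  if (!all(labels %in% seq_len(spec$n_classes))) {
    stop("labels must lie in 1..", spec$n_classes)
  }
  if (!all(seq_len(spec$n_classes) %in% labels)) {
    stop("class ", setdiff(seq_len(spec$n_classes), labels)[1],
         " is absent from the training set")
  }
  if (is.null(normalize)) normalize <- isTRUE(spec$normalize %||% TRUE)
  A0 <- .stack_inputs(spec, inputs)
  model$input_scale <- if (normalize) max(abs(A0), 1e-12) else 1
  A0 <- A0 / model$input_scale
  N <- length(inputs)
  HWblock <- nrow(A0) / N
  rng <- new_rng(derive_seed(model$seed, 13))
  # private deep copy: the optimizer updates weights in place
  params <- lapply(model$params, function(pa) {
    if (is.null(pa)) NULL else list(W = pa$W + 0, b = pa$b + 0)
  })
  state <- .adam_init(params)
  bs <- min(spec$batch_size, N)
  n_batch <- ceiling(N / bs)
  log_loss <- numeric(spec$epochs)
  log_acc <- numeric(spec$epochs)
  t_step <- 0L
  for (ep in seq_len(spec$epochs)) {
    ord <- if (shuffle) rng$sample(N) else seq_len(N)
    ep_loss <- 0
    ep_correct <- 0L
    for (bi in seq_len(n_batch)) {
      idx <- ord[((bi - 1L) * bs + 1L):min(bi * bs, N)]
      rows <- as.vector(outer(seq_len(HWblock), (idx - 1L) * HWblock, `+`))
      Ab <- A0[rows, , drop = FALSE]
      yb <- labels[idx]
      fw <- .net_forward(model$def, params, Ab, length(idx), train = TRUE,
                         rng = rng)
      pr <- fw$probs
      ep_loss <- ep_loss -
        sum(log(pmax(pr[cbind(seq_along(idx), yb)], 1e-300)))
      ep_correct <- ep_correct + sum(max.col(pr, "first") == yb)
      grads <- .net_backward(model$def, params, fw$caches, pr, yb,
                             length(idx))
      t_step <- t_step + 1L
      upd <- .adam_step(params, grads, state, t_step,
                        lr = spec$learning_rate)
      params <- upd$params
      state <- upd$state
    }
    log_loss[ep] <- ep_loss / N
    log_acc[ep] <- ep_correct / N
  }
  model$params <- params
  model$training_log <- data.frame(epoch = seq_len(spec$epochs),
                                   loss = log_loss, accuracy = log_acc)
  model$trained <- TRUE
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS archive of the full model (spec, weights,
#' input scale, training log, seed). `write.csv(model$training_log, ...)`
#' exports the log separately.
#'
#' @param model A `merp_model`.
#' @param path Checkpoint file.
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "merp_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "merp_model")) stop("not a model checkpoint: ", path)
  m
}
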