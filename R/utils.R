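# Internal RNG helpers: every randomized operation draws from its own
# stream so package calls never disturb (or depend on) the caller's
# .Random.seed, and every draw is reproducible from an integer seed.

new_rng <- function(seed) {
  state <- local({
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    set.seed(as.integer(seed))
    s <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    s
  })
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    assign(".Random.seed", state, globalenv())
    on.exit({
      state <<- get(".Random.seed", globalenv())
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    })
    force(expr)
  }
  list(
    sample  = function(n, size = n, replace = FALSE) {
      with_state(sample.int(n, size, replace))
    },
    runif   = function(n, min = 0, max = 1) with_state(stats::runif(n, min, max)),
    rnorm   = function(n, mean = 0, sd = 1) with_state(stats::rnorm(n, mean, sd)),
    rlnorm  = function(n, meanlog = 0, sdlog = 1) {
      with_state(stats::rlnorm(n, meanlog, sdlog))
    }
  )
}

# Deterministic child seeds (kept well below 2^31).
derive_seed <- function(seed, ...) {
  k <- c(...)
  x <- as.double(seed) %% 2147483629
  for (ki in k) {
    x <- (x * 48271 + as.double(ki) * 9973 + 1) %% 2147483629
  }
  as.integer(x)
}
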