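# internal helpers shared across modules

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# complex circular Gaussian noise, sd per real/imag channel
cnoise <- function(n, sigma) {
  complex(real = stats::rnorm(n, 0, sigma), imaginary = stats::rnorm(n, 0, sigma))
}

# centered moving average; width in samples (>=1), edges use shrunken windows
moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w == 1L) return(x)
  k <- rep(1 / w, w)
  n <- length(x)
  y <- stats::filter(x, k, sides = 2)
  y <- as.numeric(y)
  # fill edges with partial-window means
  half <- (w - 1L) %/% 2L
  for (i in seq_len(min(half + 1L, n))) {
    y[i] <- mean(x[1:min(n, i + half)])
    j <- n - i + 1L
    y[j] <- mean(x[max(1L, j - half):n])
  }
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
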