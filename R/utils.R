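# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    abort(sprintf("non-finite values in %s", what))
  }
  invisible(x)
}

# draw from N(mean, Sigma) parameterized by precision matrix Q and linear
# term b (mean = Q^{-1} b), via Cholesky of Q
rmvnorm_prec <- function(b, Q) {
  R <- chol(Q)
  mu <- backsolve(R, forwardsolve(t(R), b))
  z <- rnorm(length(b))
  drop(mu + backsolve(R, z))
}

# univariate slice sampler (Neal 2003, stepping out + shrinkage)
slice_sample1 <- function(logf, x0, w = 1, max_steps = 50) {
  f0 <- logf(x0)
  if (!is.finite(f0)) abort("slice sampler started at a zero-density point")
  y <- f0 - stats::rexp(1)
  u <- runif(1)
  L <- x0 - w * u
  R <- L + w
  k <- max_steps
  while (k > 0 && logf(L) > y) { L <- L - w; k <- k - 1 }
  k <- max_steps
  while (k > 0 && logf(R) > y) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- runif(1, L, R)
    if (logf(x1) >= y) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

# split-Rhat (Gelman et al.), x: iterations x chains matrix
split_rhat <- function(x) {
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(xs)
  mu <- colMeans(xs)
  s2 <- apply(xs, 2, var)
  W <- mean(s2)
  B <- half * var(mu)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# effective sample size via initial monotone positive-sequence estimator
ess_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 4) return(NA_real_)
  v <- mean(apply(x, 2, var))
  if (v <= 0) return(n * m)
  max_lag <- min(n - 2, 200)
  rho <- rep(0, max_lag)
  for (k in seq_len(max_lag)) {
    num <- 0
    for (j in seq_len(m)) {
      xc <- x[, j] - mean(x[, j])
      num <- num + sum(xc[1:(n - k)] * xc[(k + 1):n]) / (n - k)
    }
    rho[k] <- (num / m) / v
  }
  s <- 0; k <- 1
  while (k + 1 <= max_lag) {
    pair <- rho[k] + rho[k + 1]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  ess <- n * m / (1 + 2 * s)
  min(ess, n * m)
}
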