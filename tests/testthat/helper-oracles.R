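# Independent brute-force oracles used across the suite.

# marginal probability of a detection history by exhaustive enumeration over
# z in {0,1} and all 2^J availability sequences
brute_marglik <- function(h, psi, pi_t, theta, theta_prime, p) {
  J <- length(h)
  tot <- 0
  for (z in 0:1) {
    for (k in 0:(2^J - 1)) {
      y <- as.integer(intToBits(k))[1:J]
      if (z == 0) {
        py <- as.numeric(all(y == 0))
      } else {
        py <- if (y[1] == 1) pi_t else 1 - pi_t
        for (j in 2:J) {
          py <- py * if (y[j - 1] == 1) {
            if (y[j] == 1) theta_prime else 1 - theta_prime
          } else {
            if (y[j] == 1) theta else 1 - theta
          }
        }
      }
      pe <- prod(ifelse(h == 1, z * y * p, 1 - z * y * p))
      tot <- tot + (if (z == 0) 1 - psi else psi) * py * pe
    }
  }
  log(tot)
}

# naive term-by-term log-joint: prior + loop over surveyed route-years
naive_log_joint <- function(params, data, basis, gvs, hyper = occu_hyper()) {
  lp <- log_prior(params, basis, gvs, hyper)
  for (i in seq_len(data$N)) {
    for (t in seq_len(data$T)) {
      if (!data$surveyed[i, t]) next
      psi <- occupancy_prob(params, basis, data$X[i, t, 1:5], i, t)
      o <- data$observer[i, t]
      eta_o <- if (length(params$eta)) params$eta[o] else 0
      p <- detection_prob(params$alpha, data$wind[i, t],
                          data$first_year[i, t], data$protocol[i, t], eta_o)
      lp <- lp + brute_marglik(data$h[i, , t], psi, params$pi_t[t],
                               params$theta, params$theta_prime, p)
    }
  }
  lp
}

# random valid parameter set for a given basis/data shape
random_params <- function(K, T, n_obs = 0, active = NULL) {
  omega <- rep(0L, 10)
  if (!is.null(active)) omega[active] <- 1L
  occu_params(
    nu = matrix(rnorm(K * T, 0, 0.5), K, T),
    beta = rnorm(10, 0, 0.5), omega = omega,
    sigma2_rw = runif(1, 0.01, 0.5), lam = runif(1, 0.5, 3),
    pi_t = runif(T, 0.2, 0.8), theta = runif(1, 0.2, 0.8),
    theta_prime = runif(1, 0.2, 0.8), alpha = rnorm(4, 0, 0.5),
    eta = if (n_obs) rnorm(n_obs, 0, 0.3) else numeric(0),
    sigma2_obs = 0.25
  )
}

# small simulated dataset reused by several test files
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(n_sites = 40, n_periods = 3, K = 8,
                                 seed = 11)
    }
    cache
  }
})
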