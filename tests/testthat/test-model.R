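set.seed(202)
sim <- small_sim()
data <- sim$data
basis <- sim$truth$basis
gvs <- gvs_config()

test_that("occupancy_prob respects the link, masking and null coefficients", {
  pars <- random_params(basis$k, data$T)
  pars$nu[] <- 0
  pars$omega[] <- 0L
  expect_equal(occupancy_prob(pars, basis, rep(0, 5), 1, 1), 0.5)
  # excluded covariates contribute nothing regardless of beta
  pars$beta[] <- 1e6
  expect_equal(occupancy_prob(pars, basis, rnorm(5), 2, 1), 0.5)
  # a nu row reproducing logit 1 at site i
  f <- rep(1, data$N)
  pars$nu[, 1] <- qr.solve(basis$basis_matrix, f)
  expect_equal(occupancy_prob(pars, basis, rep(0, 5), 3, 1),
               plogis(1), tolerance = 1e-6)
  expect_error(occupancy_prob(pars, basis, c(NA, 1, 1, 1, 1), 1, 1),
               "finite")
})

test_that("detection_prob matches hand evaluations and is monotone in wind", {
  expect_equal(detection_prob(rep(0, 4), 0), 0.5)
  expect_equal(detection_prob(c(0, -0.5, 0, 0), 2), plogis(-1),
               tolerance = 1e-10)
  p_seq <- detection_prob(c(0.3, -0.4, 0, 0), 0:5)
  expect_true(all(diff(p_seq) < 0))
})

test_that("enumerate_histories lists every distinct history once", {
  h5 <- enumerate_histories(5)
  expect_equal(nrow(h5), 32L)
  expect_equal(nrow(unique(h5)), 32L)
  expect_equal(enumerate_histories(1), matrix(0:1, ncol = 1))
  h3 <- enumerate_histories(3)
  expect_equal(nrow(h3), 8L)
  # brute-force set comparison
  all3 <- unique(t(sapply(0:7, function(k) as.integer(intToBits(k))[3:1])))
  expect_setequal(apply(h3, 1, paste, collapse = ""),
                  apply(all3, 1, paste, collapse = ""))
})

test_that("marginal loglik agrees with exhaustive enumeration", {
  set.seed(33)
  for (r in 1:300) {
    ps <- runif(5)
    h <- rbinom(5, 1, 0.5)
    expect_equal(route_year_marginal_loglik(h, ps[1], ps[2], ps[3], ps[4],
                                            ps[5]),
                 brute_marglik(h, ps[1], ps[2], ps[3], ps[4], ps[5]),
                 tolerance = 1e-12)
  }
})

test_that("history probabilities are normalized and handle edge cases", {
  H <- enumerate_histories(5)
  set.seed(34)
  for (r in 1:20) {
    ps <- runif(5)
    ll <- route_year_marginal_loglik(H, ps[1], ps[2], ps[3], ps[4], ps[5])
    expect_equal(sum(exp(ll)), 1, tolerance = 1e-12)
  }
  # perfect availability and detection: only all-zero / all-one histories
  ll <- route_year_marginal_loglik(H, 0.6, 1, 1, 1, 1)
  pr <- exp(ll)
  expect_equal(pr[1], 0.4, tolerance = 1e-12)
  expect_equal(pr[32], 0.6, tolerance = 1e-12)
  expect_true(all(pr[2:31] < 1e-12))
  expect_error(route_year_marginal_loglik(c(0, 2, 0, 0, 0), .5, .5, .5, .5,
                                          .5), "0/1")
})

test_that("log_prior behaves like the declared kernel", {
  K <- basis$k
  pars <- random_params(K, 3, active = c(1, 2, 6))
  lp0 <- log_prior(pars, basis, gvs)
  expect_true(is.finite(lp0))
  # widening the final random-walk increment strictly decreases the prior
  prev <- Inf
  for (step in c(1, 2, 4)) {
    p2 <- pars
    p2$nu[1, 3] <- pars$nu[1, 2] + step
    lp <- log_prior(p2, basis, gvs)
    expect_lt(lp, prev)
    prev <- lp
  }
  # slab vs pseudo-prior contribution for a single beta
  g2 <- gvs_config(mu_pseudo = rep(0.7, 10), sigma_pseudo = rep(0.2, 10))
  for (om in 0:1) {
    pa <- pars
    pa$omega <- rep(0L, 10); pa$omega[3] <- as.integer(om)
    pb <- pa; pb$beta[3] <- pa$beta[3] + 0.5
    delta <- log_prior(pb, basis, g2) - log_prior(pa, basis, g2)
    expected <- if (om == 1) {
      dnorm(pb$beta[3], 0, 10, log = TRUE) -
        dnorm(pa$beta[3], 0, 10, log = TRUE)
    } else {
      dnorm(pb$beta[3], 0.7, 0.2, log = TRUE) -
        dnorm(pa$beta[3], 0.7, 0.2, log = TRUE)
    }
    expect_equal(delta, expected, tolerance = 1e-10)
  }
  # marginality violation is impossible under the prior
  pv <- pars
  pv$omega <- rep(0L, 10); pv$omega[6] <- 1L
  expect_equal(log_prior(pv, basis, gvs), -Inf)
})

test_that("the marginality prior gives Pr(quadratic included) = 0.25", {
  set.seed(35)
  n <- 1e5
  om_lin <- rbinom(n, 1, 0.5)
  om_quad <- rbinom(n, 1, 0.5 * om_lin)
  expect_equal(mean(om_quad), 0.25, tolerance = 0.01)
})

test_that("log_joint equals the naive term-by-term summation", {
  tiny <- make_fixture("tiny", seed = 5)
  d <- tiny$data; b <- tiny$truth$basis
  set.seed(36)
  for (r in 1:3) {
    pars <- random_params(b$k, d$T, n_obs = length(d$observer_levels),
                          active = c(1, 4))
    expect_equal(log_joint(pars, d, b, gvs),
                 naive_log_joint(pars, d, b, gvs), tolerance = 1e-10)
  }
})

test_that("log_joint is additive over surveyed route-years", {
  pars <- random_params(basis$k, data$T,
                        n_obs = length(data$observer_levels))
  lj_full <- log_joint(pars, data, basis, gvs)
  it <- which(data$surveyed, arr.ind = TRUE)[1, ]
  d2 <- data
  d2$surveyed[it[1], it[2]] <- FALSE
  psi <- occupancy_prob(pars, basis, data$X[it[1], it[2], 1:5], it[1],
                        it[2])
  p <- detection_prob(pars$alpha, data$wind[it[1], it[2]],
                      data$first_year[it[1], it[2]],
                      data$protocol[it[1], it[2]],
                      pars$eta[data$observer[it[1], it[2]]])
  term <- route_year_marginal_loglik(data$h[it[1], , it[2]], psi,
                                     pars$pi_t[it[2]], pars$theta,
                                     pars$theta_prime, p)
  expect_equal(lj_full - log_joint(pars, d2, basis, gvs), term,
               tolerance = 1e-10)
})

test_that("the penalized quadratic form ignores null-space shifts", {
  pars <- random_params(basis$k, data$T)
  S <- basis$penalty_matrix
  q0 <- drop(t(pars$nu[, 1]) %*% S %*% pars$nu[, 1])
  affine <- 2 - 0.1 * basis$coords$latitude + 0.05 * basis$coords$longitude
  shift <- qr.solve(basis$basis_matrix, affine)
  nu2 <- pars$nu[, 1] + shift
  expect_equal(drop(t(nu2) %*% S %*% nu2), q0, tolerance = 1e-8)
})

test_that("excluded coefficients change log_joint only through the prior", {
  pars <- random_params(basis$k, data$T,
                        n_obs = length(data$observer_levels))
  pars$omega[] <- 0L
  p2 <- pars
  p2$beta[4] <- pars$beta[4] + 3
  lik1 <- log_joint(pars, data, basis, gvs) - log_prior(pars, basis, gvs)
  lik2 <- log_joint(p2, data, basis, gvs) - log_prior(p2, basis, gvs)
  expect_equal(lik1, lik2, tolerance = 1e-10)
})

test_that("with J = 1 and perfect availability the single-visit form holds", {
  set.seed(37)
  for (r in 1:50) {
    psi <- runif(1); p <- runif(1)
    ll0 <- route_year_marginal_loglik(matrix(0L, 1, 1), psi, 1, 1, 1, p)
    ll1 <- route_year_marginal_loglik(matrix(1L, 1, 1), psi, 1, 1, 1, p)
    expect_equal(exp(ll0), (1 - psi) + psi * (1 - p), tolerance = 1e-12)
    expect_equal(exp(ll1), psi * p, tolerance = 1e-12)
  }
})
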