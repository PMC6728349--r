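set.seed(303)

test_that("Polya-Gamma draws match the series-representation mean", {
  # independent oracle: E[PG(1, c)] from the infinite-series representation
  pg_mean_series <- function(c0, terms = 2000) {
    k <- seq_len(terms) - 0.5
    sum(1 / (2 * pi^2 * (k^2 + c0^2 / (4 * pi^2))))
  }
  set.seed(1)
  for (c0 in c(0, 0.3, 1.5, 4)) {
    x <- rpg(1, rep(c0, 30000))
    expect_equal(mean(x), pg_mean_series(c0), tolerance = 0.02)
    expect_true(all(x > 0))
  }
  # PG(b, c) is the b-fold convolution
  xb <- rpg(3, rep(1, 30000))
  expect_equal(mean(xb), 3 * pg_mean_series(1), tolerance = 0.02)
})

test_that("latent-state draws respect forced values and the exact law", {
  sim <- small_sim()
  data <- sim$data; basis <- sim$truth$basis
  pars <- random_params(basis$k, data$T,
                        n_obs = length(data$observer_levels))
  lat <- update_latent_states(pars, data, basis)
  idx <- which(data$surveyed, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; t <- idx[r, 2]
    if (any(data$h[i, , t] == 1)) {
      expect_equal(lat$z[i, t], 1L)
      expect_true(all(lat$y[i, , t][data$h[i, , t] == 1] == 1L))
    }
  }
  expect_true(all(is.na(lat$z[!data$surveyed])))
})

test_that("FFBS matches the enumerated conditional at J = 2", {
  psi <- 0.6; pi_t <- 0.5; th <- 0.4; thp <- 0.8; p <- 0.55
  h <- c(0L, 1L)
  # exact conditional over (z, y1, y2) given h
  pr <- c(); lab <- c()
  for (z in 0:1) for (y1 in 0:1) for (y2 in 0:1) {
    pz <- if (z == 1) psi else 1 - psi
    py <- (if (y1 == 1) z * pi_t else 1 - z * pi_t) *
      (if (y1 == 1) (if (y2 == 1) z * thp else 1 - z * thp)
       else (if (y2 == 1) z * th else 1 - z * th))
    pe <- prod(ifelse(h == 1, z * c(y1, y2) * p, 1 - z * c(y1, y2) * p))
    pr <- c(pr, pz * py * pe)
    lab <- c(lab, paste(z, y1, y2))
  }
  pr <- pr / sum(pr)
  n <- 1e5
  set.seed(2)
  lat <- occugam:::.ffbs_cpp(matrix(rep(h, n), ncol = 2, byrow = TRUE),
                             rep(psi, n), rep(pi_t, n), rep(th, n),
                             rep(thp, n), rep(p, n))
  emp <- table(factor(paste(lat$z, lat$y[, 1], lat$y[, 2]), levels = lab)) / n
  expect_lt(sum(abs(emp - pr)) / 2, 0.01)  # total variation
})

test_that("with p = 0 the availability draw reverts to the prior chain", {
  n <- 4e4
  set.seed(3)
  lat <- occugam:::.ffbs_cpp(matrix(0L, n, 3), rep(1, n), rep(0.5, n),
                             rep(0.3, n), rep(0.9, n), rep(0, n))
  expect_equal(mean(lat$y[, 1]), 0.5, tolerance = 0.02)
  y1 <- lat$y[, 2] == 1
  expect_equal(mean(lat$y[y1, 3]), 0.9, tolerance = 0.02)
  expect_equal(mean(lat$y[!y1, 3]), 0.3, tolerance = 0.02)
})

test_that("GVS updates preserve marginality and track the likelihood", {
  sim <- small_sim()
  data <- sim$data; basis <- sim$truth$basis
  gvs <- gvs_config()
  pars <- random_params(basis$k, data$T,
                        n_obs = length(data$observer_levels),
                        active = c(1, 6))
  set.seed(4)
  for (r in 1:25) {
    pars <- update_gvs(pars, data, basis, gvs)
    expect_true(all(pars$omega[6:10] <= pars$omega[1:5]))
  }
})

test_that("identical seed and configuration give bit-identical draws", {
  sim <- small_sim()
  f1 <- fit_occupancy(sim$data, sim$truth$basis, gvs_config(), chains = 1,
                      iter = 30, warmup = 10, seed = 99)
  f2 <- fit_occupancy(sim$data, sim$truth$basis, gvs_config(), chains = 1,
                      iter = 30, warmup = 10, seed = 99)
  expect_identical(f1$draws, f2$draws)
})

test_that("pilot pseudo-prior estimation is deterministic with positive SEs", {
  sim <- small_sim()
  g1 <- estimate_pseudopriors(sim$data, sim$truth$basis,
                              n_pilot_periods = 3)
  g2 <- estimate_pseudopriors(sim$data, sim$truth$basis,
                              n_pilot_periods = 3)
  expect_identical(g1, g2)
  expect_true(all(g1$sigma_pseudo > 0))
  expect_true(all(is.finite(g1$mu_pseudo)))
})

test_that("pilot MLE recovers a strong simulated covariate effect", {
  # x1 active with beta = 1; the MLE should land within 3 SEs
  sim <- simulate_dataset(n_sites = 200, n_periods = 4, K = 8,
                          beta = c(1, rep(0, 9)), missing_rate = 0,
                          seed = 21)
  g <- estimate_pseudopriors(sim$data, sim$truth$basis,
                             n_pilot_periods = 4)
  expect_lt(abs(g$mu_pseudo[1] - 1) / g$sigma_pseudo[1], 3)
})

test_that("collapsed model matches direct optimization of the plane fit", {
  # no covariate signal, plane-only (null space) basis, near-static truth:
  # the posterior mean trend surface should agree with the direct
  # maximum-likelihood optimum within posterior Monte-Carlo error
  sim <- simulate_dataset(n_sites = 150, n_periods = 2, K = 3,
                          missing_rate = 0, sigma2_rw = 1e-4,
                          pi_t = 0.8, theta = 0.6, theta_prime = 0.9,
                          alpha = c(1.5, 0, 0, 0), sigma_obs = 0.05,
                          seed = 31)
  basis <- sim$truth$basis
  gvs <- gvs_config(sigma_pseudo = rep(0.3, 10))
  fit <- suppressWarnings(
    fit_occupancy(sim$data, basis, gvs, chains = 1, iter = 800,
                  warmup = 400, seed = 13))
  td <- tidy(fit)
  g <- estimate_pseudopriors(sim$data, basis, n_pilot_periods = 2,
                             lambda_pilot = 0)
  mle <- attr(g, "pilot")
  nu_rows <- grep("^nu\\[", td$term)
  nu_mean <- rowMeans(matrix(td$estimate[nu_rows], 3, 2))
  nu_sd <- rowMeans(matrix(td$std.error[nu_rows], 3, 2))
  expect_true(all(abs(nu_mean - mle$nu) <= 3 * pmax(nu_sd, 0.05)))
  psi_mcmc <- plogis(drop(basis$basis_matrix %*% nu_mean))
  psi_mle <- plogis(drop(basis$basis_matrix %*% mle$nu))
  expect_lt(mean(abs(psi_mcmc - psi_mle)), 0.05)
})
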