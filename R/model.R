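# Probability model: state process, availability process, detection process,
# priors (including Gibbs variable selection), and exact evaluators.

# occupancy-scale linear predictor for all site-years (N x T)
occ_linpred <- function(params, data, basis) {
  lp <- basis$basis_matrix %*% params$nu
  wb <- params$omega * params$beta
  act <- which(wb != 0)
  for (m in act) lp <- lp + data$X[, , m] * wb[m]
  lp
}

# detection-scale linear predictor for all site-years (N x T)
det_linpred <- function(params, data) {
  a <- params$alpha
  lp <- a[1] + a[2] * data$wind + a[3] * data$first_year +
    a[4] * data$protocol
  if (length(params$eta)) {
    idx <- data$observer
    eta_m <- matrix(0, data$N, data$T)
    ok <- !is.na(idx)
    eta_m[ok] <- params$eta[idx[ok]]
    lp <- lp + eta_m
  }
  lp
}

#' Occupancy probability for one site-year
#'
#' Evaluates `psi = plogis(sum_k g_k(i) nu[k, t] + sum_m omega_m beta_m x_m)`
#' where the sum over `m` runs over the five linear climate terms and their
#' squares (computed internally from the standardized linear terms). Excluded
#' covariates (`omega_m = 0`) do not contribute regardless of `beta_m`.
#'
#' @param params An [occu_params()] object.
#' @param basis An `occu_basis` from [build_tprs_basis()].
#' @param x_row Numeric length-5 vector of standardized linear climate terms.
#' @param i Site index (row of the basis matrix).
#' @param t Period index (column of `nu`).
#' @return Occupancy probability in (0, 1).
#' @export
occupancy_prob <- function(params, basis, x_row, i, t) {
  if (length(x_row) != 5) abort("`x_row` must contain the 5 linear terms")
  assert_finite(x_row, "x_row")
  x10 <- c(x_row, x_row^2)
  lp <- sum(basis$basis_matrix[i, ] * params$nu[, t]) +
    sum(params$omega * params$beta * x10)
  plogis(lp)
}

#' Stop-level detection probability
#'
#' `p = plogis(alpha0 + alpha1 * wind + alpha2 * first_year +
#' alpha3 * protocol + eta_o)` with `eta_o` the observer random effect.
#' Vectorized over its arguments.
#'
#' @param alpha Numeric length-4 coefficient vector.
#' @param wind Integer Beaufort-scale wind score.
#' @param first_year Binary first-year-observer flag.
#' @param protocol Binary protocol flag (0 standard, 1 time-distance).
#' @param eta_o Observer random effect (default 0).
#' @return Detection probability in (0, 1).
#' @export
detection_prob <- function(alpha, wind, first_year = 0, protocol = 0,
                           eta_o = 0) {
  if (length(alpha) != 4) abort("`alpha` must have length 4")
  assert_finite(c(alpha, wind, first_year, protocol, eta_o),
                "detection_prob inputs")
  plogis(alpha[1] + alpha[2] * wind + alpha[3] * first_year +
           alpha[4] * protocol + eta_o)
}

#' Marginal log-likelihood of a route-year detection history
#'
#' Computes `log Pr(h)` with the route-level occupancy state `z` and the
#' stop-level availability sequence `y` summed out: the all-zero history
#' receives mass `(1 - psi)` plus the occupied-but-undetected paths, and the
#' occupied branch is evaluated by a forward recursion over the availability
#' Markov chain with initial probability `pi_t`, transitions
#' `(theta, theta_prime)` and emission `h_j ~ Bernoulli(y_j p)`.
#'
#' All arguments after `h` are vectorized over route-years when `h` is a
#' matrix (rows = route-years).
#'
#' @param h Binary vector of length `J`, or a matrix with `J` columns.
#' @param psi Occupancy probability.
#' @param pi_t First-stop availability probability.
#' @param theta,theta_prime Availability transition probabilities.
#' @param p Detection probability.
#' @return Log-probability (vector if `h` is a matrix).
#' @export
route_year_marginal_loglik <- function(h, psi, pi_t, theta, theta_prime, p) {
  if (is.null(dim(h))) h <- matrix(as.integer(h), nrow = 1)
  storage.mode(h) <- "integer"
  if (any(is.na(h)) || any(!h %in% c(0L, 1L))) {
    abort("`h` must contain only 0/1 values")
  }
  n <- nrow(h)
  rep_n <- function(x) if (length(x) == 1) rep(x, n) else as.numeric(x)
  pr <- c(psi, pi_t, theta, theta_prime, p)
  if (any(pr < 0 | pr > 1)) abort("probabilities must lie in [0, 1]")
  out <- .route_marglik_cpp(h, rep_n(psi), rep_n(pi_t), rep_n(theta),
                            rep_n(theta_prime), rep_n(p))
  if (n == 1) out[1] else out
}

#' Enumerate all detection histories of length J
#'
#' Returns all `2^J` distinct binary replicate histories in lexicographic
#' order (first replicate is the most significant digit), e.g. 32 histories
#' for the standard five 10-stop segments of a BBS route.
#'
#' @param J Number of replicates (>= 1).
#' @return An integer `2^J` x `J` matrix, one history per row.
#' @export
enumerate_histories <- function(J) {
  J <- as.integer(J)
  if (J < 1) abort("`J` must be >= 1")
  idx <- 0:(2^J - 1)
  m <- sapply(seq_len(J), function(j) bitwAnd(bitwShiftR(idx, J - j), 1L))
  matrix(as.integer(m), ncol = J)
}

#' Log-prior density of the model parameters
#'
#' Sum of: the penalized multivariate-normal log-density for the first-year
#' spline coefficients (precision `lam * S`, flat on the 3-dimensional
#' penalty null space, using the pseudo-determinant of `S`); independent
#' `Normal(nu[k, t-1], sigma2_rw)` random-walk terms for `t > 1`; the GVS
#' slab/pseudo-prior mixture for each covariate coefficient given its
#' indicator; Bernoulli(0.5) masses for the linear indicators and
#' Bernoulli(0.5 * omega_m) for the quadratic ones (marginality); and the
#' hyperpriors of [occu_hyper()] plus `Normal(0, sigma2_obs)` for each
#' observer effect. Marginality violations return `-Inf`.
#'
#' @param params An [occu_params()] object.
#' @param basis An `occu_basis`.
#' @param gvs A [gvs_config()].
#' @param hyper An [occu_hyper()].
#' @return Scalar log-density (up to additive constants in the flat
#'   directions).
#' @export
log_prior <- function(params, basis, gvs, hyper = occu_hyper()) {
  om <- params$omega
  if (any(om[6:10] == 1 & om[1:5] == 0)) return(-Inf)
  nu <- params$nu
  K <- nrow(nu); T <- ncol(nu)
  S <- basis$penalty_matrix
  r <- basis$penalty_rank
  q1 <- drop(t(nu[, 1]) %*% S %*% nu[, 1])
  lp <- r / 2 * log(params$lam) - params$lam / 2 * q1 +
    0.5 * basis$penalty_logpdet - r / 2 * log(2 * pi)
  if (T > 1) {
    inc <- nu[, -1, drop = FALSE] - nu[, -T, drop = FALSE]
    lp <- lp + sum(dnorm(inc, 0, sqrt(params$sigma2_rw), log = TRUE))
  }
  # GVS mixture: slab when included, pseudo-prior when excluded
  sl <- sqrt(gvs$slab_variance)
  lp <- lp + sum(ifelse(om == 1,
                        dnorm(params$beta, 0, sl, log = TRUE),
                        dnorm(params$beta, gvs$mu_pseudo,
                              gvs$sigma_pseudo, log = TRUE)))
  # indicator masses with marginality
  lp <- lp + 5 * log(0.5)                                   # linear terms
  pq <- ifelse(om[1:5] == 1, 0.5, 0)                        # P(omega_q = 1)
  lp <- lp + sum(log(ifelse(om[6:10] == 1, pq, 1 - pq)))
  # hyperpriors
  lp <- lp + dgamma(params$lam, hyper$lam_shape, rate = hyper$lam_rate,
                    log = TRUE)
  lp <- lp + dnorm(sqrt(params$sigma2_rw), 0, hyper$sd_scale, log = TRUE) +
    log(2)
  lp <- lp + dnorm(sqrt(params$sigma2_obs), 0, hyper$sd_scale, log = TRUE) +
    log(2)
  lp <- lp + sum(dnorm(params$alpha, 0, sqrt(hyper$alpha_var), log = TRUE))
  if (any(c(params$pi_t, params$theta, params$theta_prime) < 0 |
            c(params$pi_t, params$theta, params$theta_prime) > 1)) {
    return(-Inf)
  }
  if (length(params$eta)) {
    lp <- lp + sum(dnorm(params$eta, 0, sqrt(params$sigma2_obs), log = TRUE))
  }
  lp
}

#' Joint log-density of parameters and data
#'
#' `log_prior()` plus the sum over all surveyed route-years of the marginal
#' detection-history log-likelihood. Unsurveyed route-years contribute
#' nothing.
#'
#' @param params An [occu_params()] object.
#' @param data An [occu_data()] object.
#' @param basis An `occu_basis`.
#' @param gvs A [gvs_config()].
#' @param hyper An [occu_hyper()].
#' @return Scalar log-density.
#' @export
log_joint <- function(params, data, basis, gvs, hyper = occu_hyper()) {
  if (nrow(params$nu) != basis$k || ncol(params$nu) != data$T) {
    abort("`nu` dimensions do not match the basis / number of periods")
  }
  if (nrow(basis$basis_matrix) != data$N) {
    abort("basis was built on a different number of sites")
  }
  lp <- log_prior(params, basis, gvs, hyper)
  if (!is.finite(lp)) return(lp)
  lp + sum(data_loglik_terms(params, data, basis))
}

# marginal loglik per surveyed route-year (vector)
data_loglik_terms <- function(params, data, basis) {
  idx <- which(data$surveyed, arr.ind = TRUE)
  if (nrow(idx) == 0) return(numeric(0))
  psi <- plogis(occ_linpred(params, data, basis)[idx])
  p <- plogis(det_linpred(params, data)[idx])
  hmat <- t(vapply(seq_len(nrow(idx)),
                   function(r) data$h[idx[r, 1], , idx[r, 2]],
                   integer(data$J)))
  .route_marglik_cpp(hmat, psi, params$pi_t[idx[, 2]],
                     rep(params$theta, nrow(idx)),
                     rep(params$theta_prime, nrow(idx)), p)
}
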