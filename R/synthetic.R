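# Synthetic-data generator: datasets with the exact statistical structure the
# model assumes, with known truth, so every stage is testable end to end.

default_window <- list(lon = c(-95, -70), lat = c(28, 48))

#' Simulate a time-evolving smooth occupancy surface
#'
#' Draws site locations uniformly over a latitude/longitude window, builds
#' the thin-plate spline basis, draws the first-year coefficients from the
#' penalized prior (null-space coefficients from a proper wide Gaussian),
#' evolves them by the Gaussian random walk, and evaluates the smooth at the
#' sites.
#'
#' @param n_sites Number of sites.
#' @param n_periods Number of primary periods (years).
#' @param K Basis dimension.
#' @param sigma2_rw Random-walk variance of the coefficients.
#' @param lam Smoothing penalty used for the first-year draw.
#' @param seed Integer seed.
#' @param window List with `lon` and `lat` ranges (default: an eastern
#'   North America window, lon -95..-70, lat 28..48).
#' @param null_sd Standard deviation of the proper prior on the null-space
#'   coefficients (default 1).
#' @return A list with `coords`, `basis`, `nu` (K x T) and `f` (N x T).
#' @export
simulate_surface <- function(n_sites, n_periods, K, sigma2_rw = 0.05,
                             lam = 1, seed = 1, window = default_window,
                             null_sd = 1) {
  if (K > n_sites) abort("K must not exceed the number of sites")
  set.seed(seed)
  coords <- tibble(
    site_id = sprintf("s%04d", seq_len(n_sites)),
    latitude = runif(n_sites, window$lat[1], window$lat[2]),
    longitude = runif(n_sites, window$lon[1], window$lon[2])
  )
  # K = 3 requests the degenerate plane-only (null-space) surface
  basis <- if (K == 3) null_space_basis(coords) else
    build_tprs_basis(coords, K)
  eg <- eigen(basis$penalty_matrix, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  # penalized directions ~ N(0, 1/(lam e)); null space ~ N(0, null_sd^2)
  coefs <- rnorm(K)
  coefs[pos] <- coefs[pos] / sqrt(lam * eg$values[pos])
  coefs[!pos] <- coefs[!pos] * null_sd
  nu <- matrix(0, K, n_periods)
  nu[, 1] <- eg$vectors %*% coefs
  if (n_periods > 1) {
    for (t in 2:n_periods) {
      nu[, t] <- nu[, t - 1] + rnorm(K, 0, sqrt(sigma2_rw))
    }
  }
  list(coords = coords, basis = basis, nu = nu,
       f = basis$basis_matrix %*% nu)
}

#' Simulate a full detection dataset from the generative model
#'
#' Composes the state, availability and detection processes: occupancy
#' states from the (supplied or simulated) surface plus covariate effects,
#' stop-level availability as the first-order Markov chain, and detections
#' with the logit-linear detection model including block-assigned observers
#' with Gaussian random effects. Climate covariates are standard normal with
#' AR(1) year-to-year correlation; wind scores are uniform on 0..5; survey
#' missingness is independent Bernoulli per route-year.
#'
#' @param n_sites,n_periods,K,J Design dimensions.
#' @param beta Length-10 truth for the covariate coefficients (5 linear then
#'   5 quadratic); the active set is `which(beta != 0)`.
#' @param sigma2_rw,lam Surface dynamics parameters.
#' @param pi_t First-stop availability (scalar or length `n_periods`).
#' @param theta,theta_prime Availability transitions.
#' @param alpha Length-4 detection coefficients.
#' @param sigma_obs Observer effect standard deviation.
#' @param ar1 Year-to-year AR(1) correlation of the covariates (default
#'   0.8).
#' @param missing_rate Route-year missingness rate (default 0.15).
#' @param protocol_rate Fraction of route-years on the alternative protocol
#'   (default 0.03).
#' @param obs_block Number of sites sharing one observer (default 10).
#' @param seed Integer seed; identical seed and design reproduce the
#'   dataset bit for bit.
#' @param nu Optional K x T truth for the surface coefficients (overrides
#'   the simulated random-walk surface).
#' @param window Coordinate window passed to [simulate_surface()].
#' @return A list of class `occu_sim` with `data` (an [occu_data()]) and
#'   `truth` (all latent quantities: `nu`, `beta`, `active`, `psi`, `z`,
#'   `y`, parameters, seed and design).
#' @export
simulate_dataset <- function(n_sites = 150, n_periods = 6, K = 12, J = 5,
                             beta = rep(0, 10), sigma2_rw = 0.05, lam = 1,
                             pi_t = 0.5, theta = 0.4, theta_prime = 0.8,
                             alpha = c(0.8, -0.3, -0.5, -0.3),
                             sigma_obs = 0.5, ar1 = 0.8,
                             missing_rate = 0.15, protocol_rate = 0.03,
                             obs_block = 10, seed = 1, nu = NULL,
                             window = default_window) {
  surf <- simulate_surface(n_sites, n_periods, K, sigma2_rw, lam,
                           seed = seed, window = window)
  set.seed(seed + 1L)
  if (!is.null(nu)) {
    stopifnot(nrow(nu) == K, ncol(nu) == n_periods)
    surf$nu <- nu
    surf$f <- surf$basis$basis_matrix %*% nu
  }
  if (length(pi_t) == 1) pi_t <- rep(pi_t, n_periods)
  N <- n_sites; T <- n_periods

  # AR(1) climate covariates, standard normal marginally
  Xlin <- array(0, dim = c(N, T, 5))
  for (m in 1:5) {
    x <- rnorm(N)
    Xlin[, 1, m] <- x
    if (T > 1) for (t in 2:T) {
      x <- ar1 * x + sqrt(1 - ar1^2) * rnorm(N)
      Xlin[, t, m] <- x
    }
  }
  X10 <- array(0, dim = c(N, T, 10))
  X10[, , 1:5] <- Xlin
  X10[, , 6:10] <- Xlin^2

  # occupancy states
  lp <- surf$f
  for (m in which(beta != 0)) lp <- lp + X10[, , m] * beta[m]
  psi <- plogis(lp)
  z <- matrix(rbinom(N * T, 1, psi), N, T)

  # observers in site blocks with one mid-series turnover
  n_blocks <- ceiling(N / obs_block)
  block <- rep(seq_len(n_blocks), each = obs_block)[1:N]
  switch_year <- sample(seq_len(max(T, 2)), n_blocks, replace = TRUE)
  obs_id <- matrix("", N, T)
  for (b in seq_len(n_blocks)) {
    rows <- which(block == b)
    for (t in seq_len(T)) {
      obs_id[rows, t] <- if (t < switch_year[b]) sprintf("obs%03da", b)
                         else sprintf("obs%03db", b)
    }
  }
  observer_levels <- sort(unique(as.vector(obs_id)))
  eta <- rnorm(length(observer_levels), 0, sigma_obs)
  names(eta) <- observer_levels
  first_year <- matrix(0L, N, T)
  for (i in seq_len(N)) {
    seen <- character(0)
    for (t in seq_len(T)) {
      if (!obs_id[i, t] %in% seen) {
        first_year[i, t] <- 1L
        seen <- c(seen, obs_id[i, t])
      }
    }
  }
  wind <- matrix(sample(0:5, N * T, replace = TRUE), N, T)
  protocol <- matrix(rbinom(N * T, 1, protocol_rate), N, T)
  p <- plogis(alpha[1] + alpha[2] * wind + alpha[3] * first_year +
                alpha[4] * protocol +
                matrix(eta[obs_id], N, T))

  # availability chain and detections
  y <- array(0L, dim = c(N, J, T))
  h <- array(0L, dim = c(N, J, T))
  for (t in seq_len(T)) {
    y[, 1, t] <- rbinom(N, 1, z[, t] * pi_t[t])
    for (j in 2:J) {
      pr <- ifelse(y[, j - 1, t] == 1, theta_prime, theta)
      y[, j, t] <- rbinom(N, 1, z[, t] * pr)
    }
    for (j in 1:J) h[, j, t] <- rbinom(N, 1, z[, t] * y[, j, t] * p[, t])
  }

  surveyed <- matrix(rbinom(N * T, 1, 1 - missing_rate) == 1, N, T)
  rows <- which(surveyed, arr.ind = TRUE)
  det <- dplyr::bind_rows(lapply(seq_len(nrow(rows)), function(r) {
    i <- rows[r, 1]; t <- rows[r, 2]
    tibble(site_id = surf$coords$site_id[i], year = 2000L + t,
           replicate = 1:J, detected = h[i, , t],
           wind = wind[i, t], first_year = first_year[i, t],
           protocol = protocol[i, t], observer_id = obs_id[i, t])
  }))
  covs <- dplyr::bind_rows(lapply(seq_len(T), function(t) {
    tibble(site_id = surf$coords$site_id, year = 2000L + t,
           var1 = Xlin[, t, 1], var2 = Xlin[, t, 2], var3 = Xlin[, t, 3],
           var4 = Xlin[, t, 4], var5 = Xlin[, t, 5])
  }))
  data <- occu_data(det, surf$coords, covs, J = J, standardize = FALSE)
  truth <- list(
    nu = surf$nu, beta = beta, active = which(beta != 0),
    sigma2_rw = sigma2_rw, lam = lam, pi_t = pi_t, theta = theta,
    theta_prime = theta_prime, alpha = alpha, sigma_obs = sigma_obs,
    eta = eta, psi = psi, z = z, y = y, seed = seed,
    basis = surf$basis, coords = surf$coords,
    design = list(n_sites = N, n_periods = T, K = K, J = J,
                  missing_rate = missing_rate, ar1 = ar1)
  )
  structure(list(data = data, truth = truth), class = "occu_sim")
}

#' Canned simulation fixtures
#'
#' Three fixed designs used throughout the test suite and examples:
#' `tiny` (3 sites x 2 years, no missingness, for exact oracles),
#' `selection` (300 sites x 6 years with 2 of the 5 linear climate terms
#' active, for variable-selection recovery) and `shift` (150 sites x 10
#' years with an imposed northward trend in the occupancy surface, for the
#' range-shift indices).
#'
#' @param name One of `"tiny"`, `"selection"`, `"shift"`.
#' @param seed Integer seed (defaults differ per fixture only through the
#'   design).
#' @return An `occu_sim` list (`data` + `truth`).
#' @export
make_fixture <- function(name = c("tiny", "selection", "shift"), seed = 42) {
  name <- match.arg(name)
  if (name == "tiny") {
    return(simulate_dataset(n_sites = 3, n_periods = 2, K = 3, J = 5,
                            missing_rate = 0, obs_block = 2, seed = seed))
  }
  if (name == "selection") {
    beta <- c(1.0, -0.8, rep(0, 8))
    return(simulate_dataset(n_sites = 300, n_periods = 6, K = 12, J = 5,
                            beta = beta, seed = seed))
  }
  # shift: northward-moving logistic band, represented in the basis by
  # least squares (the constant and latitude terms lie in the null space)
  n_sites <- 150; n_periods <- 10; K <- 12
  surf <- simulate_surface(n_sites, n_periods, K, seed = seed)
  B <- surf$basis$basis_matrix
  lat <- surf$coords$latitude
  nu <- matrix(0, K, n_periods)
  for (t in seq_len(n_periods)) {
    target <- 2.0 - 0.9 * (lat - (33 + 0.25 * (t - 1)))
    nu[, t] <- qr.solve(B, target)
  }
  simulate_dataset(n_sites = n_sites, n_periods = n_periods, K = K, J = 5,
                   seed = seed, nu = nu)
}

#' Inject gross detection misfit into a simulated dataset
#'
#' Overwrites the detection histories of a scattered subset of surveyed
#' route-years drawn from the lowest-occupancy third of sites with all-ones
#' histories (every replicate a detection). Because the injected sites are
#' spatially interleaved with unmodified ones, no smooth occupancy surface
#' or shared detection/availability parameters can reproduce the resulting
#' detection-history frequencies, so a correctly working posterior
#' predictive check must flag the fit.
#'
#' @param sim An `occu_sim` from [simulate_dataset()] or [make_fixture()].
#' @param fraction Fraction of surveyed route-years at low-occupancy sites
#'   to overwrite (default 0.5).
#' @param seed Integer seed for the site subset.
#' @return The `occu_sim` with modified `data$h` and an `injected` index
#'   matrix recorded in `truth`.
#' @export
inject_misfit <- function(sim, fraction = 0.5, seed = 1) {
  stopifnot(inherits(sim, "occu_sim"))
  set.seed(seed)
  d <- sim$data
  mean_psi <- rowMeans(sim$truth$psi)
  low <- which(mean_psi <= quantile(mean_psi, 1 / 3))
  idx <- which(d$surveyed, arr.ind = TRUE)
  cand <- idx[idx[, 1] %in% low, , drop = FALSE]
  pick <- cand[runif(nrow(cand)) < fraction, , drop = FALSE]
  for (r in seq_len(nrow(pick))) {
    d$h[pick[r, 1], , pick[r, 2]] <- 1L
  }
  sim$data <- d
  sim$truth$injected <- pick
  sim
}

#' @export
print.occu_sim <- function(x, ...) {
  d <- x$truth$design
  cat(sprintf(
    "<occu_sim> %d sites x %d years (K = %d, J = %d), active covariates: %s\n",
    d$n_sites, d$n_periods, d$K, d$J,
    if (length(x$truth$active)) paste(x$truth$active, collapse = ", ")
    else "none"))
  invisible(x)
}
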