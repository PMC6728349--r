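#' Assemble a detection/covariate dataset for occupancy modeling
#'
#' Bundles long-format detection records, site coordinates and site-year
#' climate covariates into the internal arrays the model and sampler consume.
#' Detection data follow the BBS-style layout: each surveyed route-year has
#' exactly `J` spatial replicates (10-stop segments) with binary
#' detected/not-detected outcomes, a wind score, a first-year-observer flag,
#' a survey-protocol flag and an observer identifier. A route-year is either
#' surveyed as a whole (all `J` replicates present) or missing as a whole.
#'
#' Quadratic climate terms are formed internally as squares of the
#' standardized linear terms (they are not re-standardized), so the
#' marginality constraint of the variable-selection prior keeps its
#' interpretation.
#'
#' @param detections Data frame with columns `site_id`, `year`, `replicate`,
#'   `detected`, `wind`, `first_year`, `protocol`, `observer_id`.
#' @param sites Data frame with columns `site_id`, `latitude`, `longitude`.
#' @param covariates Data frame with columns `site_id`, `year` and the five
#'   climate variables (any names; order is kept).
#' @param J Number of replicates per route-year (default 5).
#' @param standardize Standardize covariate columns to mean 0, sd 1 over
#'   observed site-years (default TRUE). The transform is stored so
#'   prediction grids can be standardized identically.
#' @return An object of class `occu_data`.
#' @export
occu_data <- function(detections, sites, covariates, J = 5L,
                      standardize = TRUE) {
  J <- as.integer(J)
  sites <- validate_coords(sites)
  detections <- as_tibble(detections)
  need <- c("site_id", "year", "replicate", "detected", "wind",
            "first_year", "protocol", "observer_id")
  miss <- setdiff(need, names(detections))
  if (length(miss)) abort(paste("detections missing columns:",
                                paste(miss, collapse = ", ")))
  bad <- which(!detections$detected %in% c(0L, 1L))
  if (length(bad)) abort(sprintf(
    "detections row %d: `detected` must be 0 or 1", bad[1]))
  bad <- which(!detections$site_id %in% sites$site_id)
  if (length(bad)) abort(sprintf(
    "detections row %d: unknown site_id '%s'", bad[1],
    detections$site_id[bad[1]]))

  site_ids <- sites$site_id
  years <- sort(unique(detections$year))
  N <- length(site_ids); T <- length(years)
  si <- match(detections$site_id, site_ids)
  ti <- match(detections$year, years)

  # every surveyed route-year must carry exactly J replicates
  key <- paste(si, ti)
  tab <- table(key)
  if (any(tab != J)) {
    k <- names(tab)[tab != J][1]
    abort(sprintf(
      "route-year (%s) has %d replicates, expected %d",
      k, tab[[k]], J))
  }

  h <- array(NA_integer_, dim = c(N, J, T))
  h[cbind(si, detections$replicate, ti)] <- as.integer(detections$detected)
  surveyed <- !is.na(h[, 1, , drop = FALSE])[, 1, ]
  surveyed <- matrix(surveyed, N, T)

  fill_mat <- function(vals, what) {
    m <- matrix(NA_real_, N, T)
    m[cbind(si, ti)] <- vals
    m
  }
  wind <- fill_mat(as.numeric(detections$wind))
  first_year <- fill_mat(as.numeric(detections$first_year))
  protocol <- fill_mat(as.numeric(detections$protocol))
  obs_chr <- matrix(NA_character_, N, T)
  obs_chr[cbind(si, ti)] <- as.character(detections$observer_id)
  observer_levels <- sort(unique(stats::na.omit(as.vector(obs_chr))))
  observer <- matrix(match(obs_chr, observer_levels), N, T)

  covariates <- as_tibble(covariates)
  if (!all(c("site_id", "year") %in% names(covariates))) {
    abort("covariates need `site_id` and `year` columns")
  }
  var_names <- setdiff(names(covariates), c("site_id", "year"))
  if (length(var_names) != 5) {
    abort(sprintf("expected 5 covariate columns, found %d",
                  length(var_names)))
  }
  transform <- NULL
  if (standardize) {
    std <- standardize_covariates(covariates, vars = var_names)
    covariates <- std$data
    transform <- std$transform
  }
  X <- array(NA_real_, dim = c(N, T, 10),
             dimnames = list(NULL, NULL,
                             c(var_names, paste0(var_names, "_sq"))))
  ci <- match(covariates$site_id, site_ids)
  cti <- match(covariates$year, years)
  keep <- !is.na(ci) & !is.na(cti)
  for (m in seq_along(var_names)) {
    v <- covariates[[var_names[m]]]
    X[cbind(ci[keep], cti[keep], m)] <- v[keep]
    X[cbind(ci[keep], cti[keep], m + 5)] <- v[keep]^2
  }
  if (any(surveyed & is.na(X[, , 1]))) {
    abort("surveyed route-years with missing covariate values")
  }

  structure(
    list(
      h = h, J = J, N = N, T = T,
      site_ids = site_ids, years = years,
      surveyed = surveyed,
      wind = wind, first_year = first_year, protocol = protocol,
      observer = observer, observer_levels = observer_levels,
      X = X, var_names = var_names,
      coords = sites, cov_transform = transform
    ),
    class = "occu_data"
  )
}

#' @export
print.occu_data <- function(x, ...) {
  cat(sprintf(
    "<occu_data> %d sites x %d years, J = %d (%d surveyed route-years, %d observers)\n",
    x$N, x$T, x$J, sum(x$surveyed), length(x$observer_levels)))
  invisible(x)
}

#' Model parameter bundle for the dynamic occupancy model
#'
#' Collects every latent quantity of the model: spline coefficients
#' `nu` (k x T), covariate effects `beta` (length 10: five linear then five
#' quadratic terms), inclusion indicators `omega` (same layout), the
#' random-walk variance `sigma2_rw`, smoothing penalty `lam`, first-stop
#' availability `pi_t` (length T), availability transition probabilities
#' `theta` (previous stop unavailable) and `theta_prime` (previous stop
#' available), the detection coefficients `alpha`
#' (intercept, wind, first-year, protocol), observer effects `eta` and their
#' variance `sigma2_obs`.
#'
#' @param nu Numeric k x T matrix of basis coefficients.
#' @param beta Numeric length-10 vector.
#' @param omega Binary length-10 vector; marginality requires
#'   `omega[m + 5] == 1` only when `omega[m] == 1`.
#' @param sigma2_rw,sigma2_obs Positive variances.
#' @param lam Positive smoothing penalty.
#' @param pi_t Length-T vector of first-stop availability probabilities.
#' @param theta,theta_prime Availability transition probabilities.
#' @param alpha Numeric length-4 detection coefficients.
#' @param eta Numeric vector of observer effects (possibly empty).
#' @return An object of class `occu_params`.
#' @export
occu_params <- function(nu, beta = rep(0, 10), omega = rep(1L, 10),
                        sigma2_rw = 0.1, lam = 1, pi_t = 0.5, theta = 0.5,
                        theta_prime = 0.5, alpha = rep(0, 4),
                        eta = numeric(0), sigma2_obs = 0.25) {
  nu <- as.matrix(nu)
  if (length(beta) != 10 || length(omega) != 10) {
    abort("`beta` and `omega` must have length 10 (5 linear + 5 quadratic)")
  }
  if (length(pi_t) == 1) pi_t <- rep(pi_t, ncol(nu))
  probs <- c(pi_t, theta, theta_prime)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (sigma2_rw <= 0 || sigma2_obs <= 0 || lam <= 0) {
    abort("variances and the smoothing penalty must be positive")
  }
  omega <- as.integer(omega)
  if (any(omega[6:10] == 1 & omega[1:5] == 0)) {
    abort("marginality violated: quadratic term included without its linear term")
  }
  structure(
    list(nu = nu, beta = as.numeric(beta), omega = omega,
         sigma2_rw = sigma2_rw, lam = lam, pi_t = pi_t, theta = theta,
         theta_prime = theta_prime, alpha = as.numeric(alpha),
         eta = as.numeric(eta), sigma2_obs = sigma2_obs),
    class = "occu_params"
  )
}

#' Gibbs variable selection configuration
#'
#' Pseudo-prior means and standard deviations for each of the 10 covariate
#' coefficients (sampled when the coefficient is excluded), and the slab
#' variance of the `N(0, slab_variance)` prior used when it is included.
#'
#' @param mu_pseudo Numeric length-10 vector of pseudo-prior means.
#' @param sigma_pseudo Positive length-10 vector of pseudo-prior sds.
#' @param slab_variance Positive scalar, default 100.
#' @return An object of class `gvs_config`.
#' @export
gvs_config <- function(mu_pseudo = rep(0, 10), sigma_pseudo = rep(1, 10),
                       slab_variance = 100) {
  if (length(mu_pseudo) != 10 || length(sigma_pseudo) != 10) {
    abort("pseudo-prior vectors must have length 10")
  }
  if (any(sigma_pseudo <= 0)) abort("sigma_pseudo must be positive")
  if (slab_variance <= 0) abort("slab_variance must be positive")
  structure(list(mu_pseudo = as.numeric(mu_pseudo),
                 sigma_pseudo = as.numeric(sigma_pseudo),
                 slab_variance = slab_variance),
            class = "gvs_config")
}

#' Hyperprior settings
#'
#' Vague hyperpriors used by [log_prior()] and [fit_occupancy()]:
#' `lam ~ Gamma(lam_shape, lam_rate)`, half-Normal(0, `sd_scale`) on the
#' random-walk and observer standard deviations, `alpha ~ N(0, alpha_var)`
#' and Uniform(0, 1) on all availability probabilities.
#'
#' @param lam_shape,lam_rate Gamma hyperprior for the smoothing penalty.
#' @param sd_scale Scale of the half-Normal priors on sd parameters.
#' @param alpha_var Variance of the Normal prior on detection coefficients.
#' @return A list of class `occu_hyper`.
#' @export
occu_hyper <- function(lam_shape = 0.05, lam_rate = 0.005, sd_scale = 2,
                       alpha_var = 10) {
  structure(list(lam_shape = lam_shape, lam_rate = lam_rate,
                 sd_scale = sd_scale, alpha_var = alpha_var),
            class = "occu_hyper")
}
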