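#' Estimate GVS pseudo-priors from a pilot maximum-likelihood fit
#'
#' Fits the correlated-detection occupancy model by direct maximization of
#' the marginalized log-likelihood over the first `n_pilot_periods` years,
#' with all covariates included, a static spatial smooth (single coefficient
#' vector, lightly ridge-penalized through the spline penalty), and no
#' observer random effects. The coefficient MLEs become the pseudo-prior
#' means and the asymptotic standard errors (from the inverse observed
#' information) the pseudo-prior standard deviations.
#'
#' @param data An [occu_data()] object.
#' @param basis An `occu_basis`.
#' @param n_pilot_periods Number of initial periods used (default 10, capped
#'   at `data$T`).
#' @param lambda_pilot Fixed ridge weight on the spline penalty during the
#'   pilot fit (default 1).
#' @param ridge Small ridge on all working parameters (default 1e-3). The
#'   marginal occupancy likelihood has a weakly identified direction
#'   (occupancy traded against availability) along which an unpenalized
#'   optimizer can drift to extreme logits; the ridge pins it without
#'   materially moving well-identified coefficients.
#' @param maxit Optimizer iteration cap.
#' @return A [gvs_config()] with `mu_pseudo` and `sigma_pseudo` filled in.
#' @export
estimate_pseudopriors <- function(data, basis, n_pilot_periods = 10,
                                  lambda_pilot = 1, ridge = 1e-3,
                                  maxit = 500) {
  n_pilot_periods <- min(n_pilot_periods, data$T)
  if (n_pilot_periods < 1) abort("need at least one pilot period")
  ry <- ry_index(data)
  keep <- ry$ti <= n_pilot_periods
  if (!any(keep)) abort("no surveyed route-years in the pilot window")
  si <- ry$si[keep]
  hmat <- ry$hmat[keep, , drop = FALSE]
  Xry <- ry$Xry[keep, , drop = FALSE]
  Wd <- ry$Wd[keep, , drop = FALSE]
  B <- basis$basis_matrix[si, , drop = FALSE]
  S <- basis$penalty_matrix
  K <- basis$k
  n <- nrow(hmat)

  unpack <- function(par) {
    list(nu = par[1:K],
         beta = par[K + 1:10],
         alpha = par[K + 10 + 1:4],
         pi = plogis(par[K + 15]),
         theta = plogis(par[K + 16]),
         thetap = plogis(par[K + 17]))
  }
  negll <- function(par) {
    p <- unpack(par)
    psi <- plogis(drop(B %*% p$nu) + drop(Xry %*% p$beta))
    pd <- plogis(drop(Wd %*% p$alpha))
    ll <- sum(.route_marglik_cpp(hmat, psi, rep(p$pi, n), rep(p$theta, n),
                                 rep(p$thetap, n), pd))
    pen <- lambda_pilot / 2 * drop(t(p$nu) %*% S %*% p$nu) +
      ridge / 2 * sum(par^2)
    -ll + pen
  }
  start <- rep(0, K + 17)
  start[K + 11] <- qlogis(min(max(mean(hmat), 0.05), 0.95))
  opt <- optim(start, negll, method = "BFGS", hessian = TRUE,
               control = list(maxit = maxit, reltol = 1e-9))
  if (opt$convergence != 0) {
    abort(sprintf(
      "pilot likelihood maximization did not converge (code %d, %s)",
      opt$convergence, opt$message %||% "no message"))
  }
  H <- opt$hessian
  cv <- tryCatch(solve(H), error = function(e) {
    solve(H + diag(1e-6, nrow(H)))
  })
  se <- sqrt(pmax(diag(cv)[K + 1:10], 1e-12))
  est <- unpack(opt$par)
  out <- gvs_config(mu_pseudo = est$beta, sigma_pseudo = se,
                    slab_variance = 100)
  attr(out, "pilot") <- list(nu = est$nu, alpha = est$alpha, pi = est$pi,
                             theta = est$theta, theta_prime = est$thetap,
                             loglik = -opt$value)
  out
}
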