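# Freeman-Tukey posterior predictive checks on detection-history frequencies.

#' Expected detection-history counts for one year under a parameter draw
#'
#' For each surveyed route in year `t`, adds the probability of each of the
#' `2^J` detection histories (with occupancy and availability marginalized,
#' as in [route_year_marginal_loglik()]) to the per-history expectation.
#' The expectations therefore sum to the number of surveyed routes.
#'
#' @param params An [occu_params()] object.
#' @param data An [occu_data()] object.
#' @param basis The `occu_basis`.
#' @param year Year value (element of `data$years`).
#' @return Numeric vector of length `2^J` in the lexicographic history
#'   order of [enumerate_histories()]; zero-length (with a warning) when no
#'   routes were surveyed that year.
#' @export
expected_history_counts <- function(params, data, basis, year) {
  t <- match(year, data$years)
  if (is.na(t)) abort("`year` is not a modeled period")
  rows <- which(data$surveyed[, t])
  if (!length(rows)) {
    warn(sprintf("no surveyed routes in year %s", year))
    return(numeric(0))
  }
  psi <- plogis(occ_linpred(params, data, basis)[rows, t])
  p <- plogis(det_linpred(params, data)[rows, t])
  probs <- .history_probs_cpp(psi, rep(params$pi_t[t], length(rows)),
                              rep(params$theta, length(rows)),
                              rep(params$theta_prime, length(rows)), p,
                              data$J)
  colSums(probs)
}

#' Freeman-Tukey discrepancy
#'
#' `sum((sqrt(observed) - sqrt(expected))^2)` between observed and expected
#' detection-history counts.
#'
#' @param observed Non-negative count vector.
#' @param expected Non-negative expectation vector, same length.
#' @return Scalar discrepancy.
#' @export
freeman_tukey <- function(observed, expected) {
  if (length(observed) != length(expected)) abort("length mismatch")
  if (any(observed < 0) || any(expected < 0)) {
    abort("counts must be non-negative")
  }
  sum((sqrt(observed) - sqrt(expected))^2)
}

# observed history index (1-based lexicographic) per surveyed route-year
observed_history_index <- function(data) {
  ry <- ry_index(data)
  pw <- 2^((data$J - 1):0)
  idx <- as.integer(ry$hmat %*% pw) + 1L
  list(ry = ry, hist_idx = idx)
}

#' Bayesian p-value from Freeman-Tukey posterior predictive checks
#'
#' For each posterior draw, computes the expected count of every detection
#' history per year, simulates a replicated dataset from the model (new
#' occupancy and availability states, conditioning on the draw's observer
#' effects), and compares the Freeman-Tukey discrepancy of the replicated
#' counts against that of the observed counts, both summed over years. The
#' p-value is the fraction of draws whose replicated discrepancy is at
#' least the observed one; per-year statistics are also reported.
#'
#' @param fit An `occu_fit`.
#' @param draw_ids Optional pooled draw indices (default: all draws).
#' @param seed Integer seed for the replicated-data simulation.
#' @return An object of class `occu_ppc`: a list with `p_value`, a
#'   per-year tibble `by_year` (mean discrepancies and per-year p-values)
#'   and the number of draws used.
#' @export
bayesian_pvalue <- function(fit, draw_ids = NULL, seed = 1) {
  stopifnot(inherits(fit, "occu_fit"))
  data <- fit$data; basis <- fit$basis
  dm <- draw_matrix(fit)
  if (is.null(draw_ids)) draw_ids <- seq_len(nrow(dm))
  set.seed(seed)
  oh <- observed_history_index(data)
  ry <- oh$ry
  H <- 2^data$J
  Tn <- data$T
  obs_counts <- matrix(0, Tn, H)
  for (t in seq_len(Tn)) {
    r <- ry$rows_by_t[[t]]
    if (length(r)) obs_counts[t, ] <- tabulate(oh$hist_idx[r], nbins = H)
  }
  nd <- length(draw_ids)
  ft_obs <- ft_rep <- matrix(0, nd, Tn)
  for (d in seq_len(nd)) {
    pars <- params_from_draw(fit, draw_ids[d])
    psi <- plogis(occ_linpred(pars, data, basis)[cbind(ry$si, ry$ti)])
    p <- plogis(det_linpred(pars, data)[cbind(ry$si, ry$ti)])
    probs <- .history_probs_cpp(psi, pars$pi_t[ry$ti],
                                rep(pars$theta, ry$n),
                                rep(pars$theta_prime, ry$n), p, data$J)
    # one replicated history per route-year, drawn from its history law
    u <- runif(ry$n)
    cum <- t(apply(probs, 1, cumsum))
    rep_idx <- 1L + as.integer(rowSums(cum < u * cum[, H]))
    for (t in seq_len(Tn)) {
      r <- ry$rows_by_t[[t]]
      if (!length(r)) next
      expd <- colSums(probs[r, , drop = FALSE])
      repc <- tabulate(rep_idx[r], nbins = H)
      ft_obs[d, t] <- freeman_tukey(obs_counts[t, ], expd)
      ft_rep[d, t] <- freeman_tukey(repc, expd)
    }
  }
  by_year <- tibble(
    year = data$years,
    ft_obs_mean = colMeans(ft_obs),
    ft_rep_mean = colMeans(ft_rep),
    p_value = colMeans(ft_rep >= ft_obs)
  )
  structure(
    list(p_value = mean(rowSums(ft_rep) >= rowSums(ft_obs)),
         by_year = by_year, n_draws = nd),
    class = "occu_ppc"
  )
}

#' @export
print.occu_ppc <- function(x, ...) {
  cat(sprintf(
    "<occu_ppc> Freeman-Tukey Bayesian p-value = %.3f (%d draws)\n",
    x$p_value, x$n_draws))
  invisible(x)
}
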