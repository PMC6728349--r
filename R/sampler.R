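# Block Gibbs sampler: FFBS latent-state draws, Polya-Gamma augmented
# Gaussian updates for all logistic blocks, Beta/Gamma conjugate updates for
# availability and smoothing parameters, slice sampling for the half-Normal
# scale parameters, and Gibbs variable selection for the climate terms.

#' Draw Polya-Gamma random variates
#'
#' Exact PG(b, c) draws (integer b) via Devroye's alternating-series method,
#' used to make the logistic blocks of the Gibbs sampler conditionally
#' Gaussian. `E[PG(b, c)] = b tanh(c/2) / (2c)`.
#'
#' @param b Integer vector of shape parameters.
#' @param c Numeric vector of tilting parameters.
#' @return Numeric vector of draws.
#' @export
rpg <- function(b, c) {
  n <- max(length(b), length(c))
  .rpg_cpp(as.integer(rep_len(b, n)), as.numeric(rep_len(c, n)))
}

log1pexp <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# flatten surveyed route-years once per fit
ry_index <- function(data) {
  idx <- which(data$surveyed, arr.ind = TRUE)
  n <- nrow(idx)
  si <- idx[, 1]; ti <- idx[, 2]
  hmat <- matrix(0L, n, data$J)
  for (r in seq_len(n)) hmat[r, ] <- data$h[si[r], , ti[r]]
  Xry <- matrix(0, n, 10)
  for (m in 1:10) Xry[, m] <- data$X[cbind(si, ti, m)]
  Wd <- cbind(1, data$wind[idx], data$first_year[idx], data$protocol[idx])
  list(n = n, si = si, ti = ti, hmat = hmat, Xry = Xry, Wd = Wd,
       o_ry = data$observer[idx],
       rows_by_t = lapply(seq_len(data$T), function(t) which(ti == t)))
}

#' Draw the latent occupancy and availability states
#'
#' Exact forward-filtering backward-sampling draw of `(z, y)` from their
#' joint full conditional given the detection histories and current
#' parameters. `z` is 1 with probability 1 for any route-year with a
#' detection, and `y` is 1 wherever `h` is 1.
#'
#' @param params An [occu_params()] object.
#' @param data An [occu_data()] object.
#' @param basis The `occu_basis` used to form the occupancy surface.
#' @return A list with `z` (N x T, NA where unsurveyed) and `y`
#'   (N x J x T).
#' @export
update_latent_states <- function(params, data, basis) {
  ry <- ry_index(data)
  z <- matrix(NA_integer_, data$N, data$T)
  y <- array(NA_integer_, dim = c(data$N, data$J, data$T))
  if (ry$n == 0) return(list(z = z, y = y))
  psi <- plogis(occ_linpred(params, data, basis)[cbind(ry$si, ry$ti)])
  p <- plogis(det_linpred(params, data)[cbind(ry$si, ry$ti)])
  lat <- .ffbs_cpp(ry$hmat, psi, params$pi_t[ry$ti],
                   rep(params$theta, ry$n), rep(params$theta_prime, ry$n), p)
  z[cbind(ry$si, ry$ti)] <- lat$z
  for (r in seq_len(ry$n)) y[ry$si[r], , ry$ti[r]] <- lat$y[r, ]
  list(z = z, y = y)
}

# one GVS sweep on (omega, beta) given imputed z at surveyed route-years;
# internal core shared by update_gvs() and fit_occupancy()
gvs_sweep <- function(omega, beta, lp_occ, z, Xry, gvs) {
  sl <- sqrt(gvs$slab_variance)
  ll <- function(l) sum(z * l - log1pexp(l))
  for (m in 1:10) {
    x <- Xry[, m]
    l0 <- lp_occ - omega[m] * beta[m] * x
    l1 <- l0 + beta[m] * x
    if (m <= 5) {
      if (omega[m + 5] == 1) { omega[m] <- 1L; lp_occ <- l1; next }
      prior_lo <- log(0.5) + log(0.5) - (log(0.5) + log(1))
    } else {
      if (omega[m - 5] == 0) { omega[m] <- 0L; lp_occ <- l0; next }
      prior_lo <- log(0.5) - log(0.5)
    }
    beta_lo <- dnorm(beta[m], 0, sl, log = TRUE) -
      dnorm(beta[m], gvs$mu_pseudo[m], gvs$sigma_pseudo[m], log = TRUE)
    lo <- (if (length(z)) ll(l1) - ll(l0) else 0) + prior_lo + beta_lo
    omega[m] <- as.integer(runif(1) < plogis(lo))
    lp_occ <- if (omega[m] == 1) l1 else l0
  }
  list(omega = omega, lp_occ = lp_occ)
}

# beta update given PG weights w and kappa = z - 1/2 (active terms), or
# pseudo-prior draw (inactive terms); returns updated beta and lp_occ
beta_update <- function(omega, beta, lp_occ, w, kappa, Xry, gvs) {
  for (m in 1:10) {
    x <- Xry[, m]
    if (omega[m] == 1 && length(kappa)) {
      lmin <- lp_occ - beta[m] * x
      prec <- sum(w * x^2) + 1 / gvs$slab_variance
      bb <- sum(x * (kappa - w * lmin))
      newb <- rnorm(1, bb / prec, sqrt(1 / prec))
      lp_occ <- lmin + newb * x
      beta[m] <- newb
    } else {
      beta[m] <- rnorm(1, gvs$mu_pseudo[m], gvs$sigma_pseudo[m])
      if (omega[m] == 1) {
        # no data: conditional is the slab
        beta[m] <- rnorm(1, 0, sqrt(gvs$slab_variance))
      }
    }
  }
  list(beta = beta, lp_occ = lp_occ)
}

#' One Gibbs variable-selection update of the inclusion indicators
#'
#' Updates each inclusion indicator from its Bernoulli full conditional
#' (likelihood ratio given the imputed occupancy states times prior odds,
#' with the coefficient evaluated under the slab or the pseudo-prior), then
#' updates each coefficient from its conditional (a Polya-Gamma-augmented
#' Gaussian draw when included, a pseudo-prior draw when excluded).
#' Marginality is enforced: a quadratic indicator can be 1 only while its
#' linear indicator is 1, and a linear indicator is forced on while its
#' quadratic partner is included.
#'
#' @param params An [occu_params()] object (marginality must hold on input).
#' @param data An [occu_data()] object.
#' @param basis The `occu_basis`.
#' @param gvs A [gvs_config()].
#' @param z Optional N x T matrix of imputed occupancy states; drawn with
#'   [update_latent_states()] when omitted.
#' @return The params object with updated `omega` and `beta`.
#' @export
update_gvs <- function(params, data, basis, gvs, z = NULL) {
  ry <- ry_index(data)
  if (is.null(z)) z <- update_latent_states(params, data, basis)$z
  zv <- if (ry$n) z[cbind(ry$si, ry$ti)] else integer(0)
  lp <- if (ry$n) occ_linpred(params, data, basis)[cbind(ry$si, ry$ti)]
        else numeric(0)
  sw <- gvs_sweep(params$omega, params$beta, lp, zv, ry$Xry, gvs)
  if (ry$n) {
    w <- rpg(1, sw$lp_occ)
    kappa <- zv - 0.5
  } else {
    w <- numeric(0); kappa <- numeric(0)
  }
  bu <- beta_update(sw$omega, params$beta, sw$lp_occ, w, kappa, ry$Xry, gvs)
  params$omega <- sw$omega
  params$beta <- bu$beta
  params
}

#' Fit the dynamic occupancy model by MCMC
#'
#' Runs the block Gibbs sampler: forward-filtering backward-sampling of the
#' latent occupancy/availability states, Polya-Gamma augmented Gaussian
#' updates for the spline coefficients (year by year, tied by the random
#' walk), climate coefficients and detection coefficients, Gibbs variable
#' selection for the inclusion indicators, Beta-conjugate updates for
#' `pi_t`, `theta`, `theta_prime`, a Gamma-conjugate update for the
#' smoothing penalty, and slice updates for the random-walk and observer
#' standard deviations.
#'
#' @param data An [occu_data()] object.
#' @param basis An `occu_basis` built on the same sites.
#' @param gvs A [gvs_config()]; when NULL, pseudo-priors are estimated from
#'   a pilot maximum-likelihood fit via [estimate_pseudopriors()].
#' @param chains Number of chains (default 3).
#' @param iter Kept iterations per chain (default 2000).
#' @param warmup Warm-up iterations discarded per chain (default 2000).
#' @param thin Thinning interval (default 1).
#' @param seed Integer seed; the run is fully reproducible given
#'   `seed`/`chains`/`iter`.
#' @param hyper An [occu_hyper()].
#' @param monitor_nu Number of randomly chosen spline coefficients added to
#'   the convergence-monitored set (default 10).
#' @param mh_sweeps Number of marginal Metropolis refreshes of
#'   `(alpha0, theta, theta_prime)` per iteration (default 2); these
#'   integrate out the latent states and decorrelate the availability /
#'   detection trade-off.
#' @param progress Print progress (default FALSE).
#' @return An object of class `occu_fit` with the posterior draws, chain
#'   metadata and split-Rhat / effective-sample-size diagnostics. Runs with
#'   max Rhat > 1.1 on the monitored set are returned with
#'   `converged = FALSE` and a warning, never silently accepted.
#' @export
fit_occupancy <- function(data, basis, gvs = NULL, chains = 3, iter = 2000,
                          warmup = 2000, thin = 1, seed = 1,
                          hyper = occu_hyper(), monitor_nu = 10,
                          mh_sweeps = 2, progress = FALSE) {
  stopifnot(inherits(data, "occu_data"), inherits(basis, "occu_basis"))
  if (nrow(basis$basis_matrix) != data$N) {
    abort("basis and data refer to different site sets")
  }
  if (is.null(gvs)) {
    gvs <- estimate_pseudopriors(data, basis,
                                 n_pilot_periods = min(10, data$T))
  }
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1, chains)
  ry <- ry_index(data)
  K <- basis$k; T <- data$T
  n_obs_eff <- length(data$observer_levels)
  keep <- floor(iter / thin)
  par_names <- c("theta", "theta_prime", "sigma2_rw", "lam", "sigma2_obs",
                 paste0("alpha", 0:3), paste0("pi[", seq_len(T), "]"),
                 paste0("beta[", 1:10, "]"), paste0("omega[", 1:10, "]"),
                 paste0("nu[", rep(seq_len(K), T), ",",
                        rep(seq_len(T), each = K), "]"),
                 if (n_obs_eff) paste0("eta[", seq_len(n_obs_eff), "]"))
  P <- length(par_names)
  draws <- array(NA_real_, dim = c(keep, chains, P),
                 dimnames = list(NULL, NULL, par_names))
  nu_mon <- sample(K * T, min(monitor_nu, K * T))
  monitored <- c("theta", "theta_prime", "sigma2_rw", "lam",
                 paste0("alpha", 0:3), paste0("omega[", 1:10, "]"),
                 paste0("nu[", (nu_mon - 1) %% K + 1, ",",
                        (nu_mon - 1) %/% K + 1, "]"))

  S <- basis$penalty_matrix
  B <- basis$basis_matrix
  IK <- diag(K)

  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    # initial state
    nu <- matrix(0, K, T)
    beta <- rep(0, 10); omega <- rep(1L, 10)
    lam <- 1; sigma2 <- 0.1
    pi_t <- rep(0.5, T); theta <- 0.5; thetap <- 0.5
    h_rate <- if (ry$n) mean(ry$hmat) else 0.5
    alpha <- c(qlogis(min(max(h_rate, 0.05), 0.95)), 0, 0, 0)
    eta <- rep(0, n_obs_eff); sigma2_obs <- 0.25
    lp_occ <- if (ry$n) drop(B[ry$si, , drop = FALSE] %*% nu[, 1] * 0) +
      drop(ry$Xry %*% (omega * beta)) else numeric(0)

    total <- warmup + iter
    for (it in seq_len(total)) {
      # linear predictors
      if (ry$n) {
        lp_occ <- numeric(ry$n)
        for (t in seq_len(T)) {
          r <- ry$rows_by_t[[t]]
          if (length(r)) {
            lp_occ[r] <- drop(B[ry$si[r], , drop = FALSE] %*% nu[, t])
          }
        }
        covpart <- drop(ry$Xry %*% (omega * beta))
        lp_occ <- lp_occ + covpart
        lp_det <- drop(ry$Wd %*% alpha) +
          (if (n_obs_eff) eta[ry$o_ry] else 0)

        # --- marginal Metropolis refresh of (alpha0, theta, theta') ---
        # (z, y) integrated out; placed immediately before the latent
        # redraw so the composition is a valid partially collapsed Gibbs
        # step. Breaks the slow random walk along the availability /
        # detection ridge that conditioning on imputed y induces.
        psi_v <- plogis(lp_occ)
        off_det <- lp_det - alpha[1]
        marg_ll <- function(a0, th, thp) {
          sum(.route_marglik_cpp(ry$hmat, psi_v, pi_t[ry$ti],
                                 rep(th, ry$n), rep(thp, ry$n),
                                 plogis(off_det + a0)))
        }
        cur_ll <- marg_ll(alpha[1], theta, thetap)
        for (mh in seq_len(mh_sweeps)) {
          a0p <- alpha[1] + rnorm(1, 0, 0.3)
          new_ll <- marg_ll(a0p, theta, thetap)
          lr <- new_ll - cur_ll +
            dnorm(a0p, 0, sqrt(hyper$alpha_var), log = TRUE) -
            dnorm(alpha[1], 0, sqrt(hyper$alpha_var), log = TRUE)
          if (log(runif(1)) < lr) {
            lp_det <- lp_det + (a0p - alpha[1])
            alpha[1] <- a0p; cur_ll <- new_ll
          }
          for (which_th in 1:2) {
            cur <- if (which_th == 1) theta else thetap
            u <- qlogis(cur) + rnorm(1, 0, 0.4)
            prop <- plogis(u)
            new_ll <- if (which_th == 1) marg_ll(alpha[1], prop, thetap)
                      else marg_ll(alpha[1], theta, prop)
            # uniform prior on the probability scale: logit-normal RW needs
            # the Jacobian p(1-p)
            lr <- new_ll - cur_ll + log(prop * (1 - prop)) -
              log(cur * (1 - cur))
            if (log(runif(1)) < lr) {
              if (which_th == 1) theta <- prop else thetap <- prop
              cur_ll <- new_ll
            }
          }
        }

        # --- latent states ---
        lat <- .ffbs_cpp(ry$hmat, plogis(lp_occ), pi_t[ry$ti],
                         rep(theta, ry$n), rep(thetap, ry$n),
                         plogis(lp_det))
        zv <- lat$z; yv <- lat$y

        # --- availability probabilities ---
        occ_rows <- which(zv == 1)
        for (t in seq_len(T)) {
          rt <- intersect(ry$rows_by_t[[t]], occ_rows)
          s1 <- sum(yv[rt, 1]); s0 <- length(rt) - s1
          pi_t[t] <- rbeta(1, 1 + s1, 1 + s0)
        }
        prev <- yv[occ_rows, -data$J, drop = FALSE]
        cur <- yv[occ_rows, -1, drop = FALSE]
        n01 <- sum(prev == 0 & cur == 1); n00 <- sum(prev == 0 & cur == 0)
        n11 <- sum(prev == 1 & cur == 1); n10 <- sum(prev == 1 & cur == 0)
        theta <- rbeta(1, 1 + n01, 1 + n00)
        thetap <- rbeta(1, 1 + n11, 1 + n10)

        # --- GVS indicator sweep (given z, unaugmented) ---
        sw <- gvs_sweep(omega, beta, lp_occ, zv, ry$Xry, gvs)
        omega <- sw$omega; lp_occ <- sw$lp_occ

        # --- Polya-Gamma augmented occupancy-scale updates ---
        w <- rpg(1, lp_occ)
        kappa <- zv - 0.5
        for (t in seq_len(T)) {
          r <- ry$rows_by_t[[t]]
          Pp <- if (t == 1) lam * S + (if (T > 1) IK / sigma2 else 1e-8 * IK)
          else if (t < T) 2 * IK / sigma2
          else IK / sigma2
          bp <- if (t == 1) (if (T > 1) nu[, 2] / sigma2 else rep(0, K))
          else if (t < T) (nu[, t - 1] + nu[, t + 1]) / sigma2
          else nu[, t - 1] / sigma2
          if (length(r)) {
            Bt <- B[ry$si[r], , drop = FALSE]
            cv <- lp_occ[r] - drop(Bt %*% nu[, t])
            Pp <- Pp + crossprod(Bt, Bt * w[r])
            bp <- bp + drop(crossprod(Bt, kappa[r] - w[r] * cv))
            newnu <- rmvnorm_prec(bp, Pp)
            lp_occ[r] <- cv + drop(Bt %*% newnu)
            nu[, t] <- newnu
          } else {
            nu[, t] <- rmvnorm_prec(bp, Pp)
          }
        }
        bu <- beta_update(omega, beta, lp_occ, w, kappa, ry$Xry, gvs)
        beta <- bu$beta; lp_occ <- bu$lp_occ

        # --- detection-scale updates ---
        navail <- rowSums(yv); kdet <- rowSums(ry$hmat)
        d <- which(zv == 1 & navail > 0)
        if (length(d)) {
          lpd <- drop(ry$Wd[d, , drop = FALSE] %*% alpha) +
            (if (n_obs_eff) eta[ry$o_ry[d]] else 0)
          wd <- rpg(navail[d], lpd)
          kap <- kdet[d] - navail[d] / 2
          Xd <- ry$Wd[d, , drop = FALSE]
          off <- if (n_obs_eff) eta[ry$o_ry[d]] else rep(0, length(d))
          A <- crossprod(Xd, Xd * wd) + diag(4) / hyper$alpha_var
          bb <- drop(crossprod(Xd, kap - wd * off))
          alpha <- rmvnorm_prec(bb, A)
          if (n_obs_eff) {
            xb <- drop(Xd %*% alpha)
            og <- ry$o_ry[d]
            sw_o <- rowsum(wd, og)
            sb_o <- rowsum(kap - wd * xb, og)
            ids <- as.integer(rownames(sw_o))
            prec_o <- rep(1 / sigma2_obs, n_obs_eff)
            b_o <- rep(0, n_obs_eff)
            prec_o[ids] <- prec_o[ids] + sw_o[, 1]
            b_o[ids] <- b_o[ids] + sb_o[, 1]
            eta <- rnorm(n_obs_eff, b_o / prec_o, sqrt(1 / prec_o))
          }
        } else {
          alpha <- rnorm(4, 0, sqrt(hyper$alpha_var))
          if (n_obs_eff) eta <- rnorm(n_obs_eff, 0, sqrt(sigma2_obs))
        }
      } else {
        # prior-only run: no data terms anywhere
        for (t in seq_len(T)) pi_t[t] <- rbeta(1, 1, 1)
        theta <- rbeta(1, 1, 1); thetap <- rbeta(1, 1, 1)
        sw <- gvs_sweep(omega, beta, numeric(0), integer(0),
                        matrix(0, 0, 10), gvs)
        omega <- sw$omega
        bu <- beta_update(omega, beta, numeric(0), numeric(0), numeric(0),
                          matrix(0, 0, 10), gvs)
        beta <- bu$beta
        for (t in seq_len(T)) {
          Pp <- if (t == 1) lam * S + (if (T > 1) IK / sigma2 else 1e-8 * IK)
          else if (t < T) 2 * IK / sigma2
          else IK / sigma2
          bp <- if (t == 1) (if (T > 1) nu[, 2] / sigma2 else rep(0, K))
          else if (t < T) (nu[, t - 1] + nu[, t + 1]) / sigma2
          else nu[, t - 1] / sigma2
          nu[, t] <- rmvnorm_prec(bp, Pp)
        }
        alpha <- rnorm(4, 0, sqrt(hyper$alpha_var))
        if (n_obs_eff) eta <- rnorm(n_obs_eff, 0, sqrt(sigma2_obs))
      }

      # --- smoothing penalty (Gamma conjugate) ---
      q1 <- drop(t(nu[, 1]) %*% S %*% nu[, 1])
      lam <- rgamma(1, hyper$lam_shape + basis$penalty_rank / 2,
                    rate = hyper$lam_rate + q1 / 2)

      # --- random-walk sd (slice; half-Normal prior) ---
      if (T > 1) {
        inc <- nu[, -1, drop = FALSE] - nu[, -T, drop = FALSE]
        ssq <- sum(inc^2); nn <- length(inc)
        lf <- function(ls) {
          s <- exp(ls)
          -nn * ls - ssq / (2 * s^2) +
            dnorm(s, 0, hyper$sd_scale, log = TRUE) + ls
        }
        sigma2 <- exp(2 * slice_sample1(lf, 0.5 * log(sigma2)))
      }
      # --- observer sd (slice) ---
      if (n_obs_eff) {
        ssq <- sum(eta^2); nn <- n_obs_eff
        lf <- function(ls) {
          s <- exp(ls)
          -nn * ls - ssq / (2 * s^2) +
            dnorm(s, 0, hyper$sd_scale, log = TRUE) + ls
        }
        sigma2_obs <- exp(2 * slice_sample1(lf, 0.5 * log(sigma2_obs)))
      }

      if (it > warmup && (it - warmup) %% thin == 0) {
        kidx <- (it - warmup) %/% thin
        draws[kidx, ch, ] <- c(theta, thetap, sigma2, lam, sigma2_obs,
                               alpha, pi_t, beta, omega, as.vector(nu),
                               if (n_obs_eff) eta)
      }
      if (progress && it %% 500 == 0) {
        message(sprintf("chain %d iteration %d / %d", ch, it, total))
      }
    }
  }

  diag_tbl <- tibble(
    parameter = monitored,
    rhat = vapply(monitored, function(p) split_rhat(draws[, , p, drop = TRUE]
                                                    |> matrix(nrow = keep)),
                  0),
    ess = vapply(monitored, function(p) ess_basic(matrix(draws[, , p],
                                                         nrow = keep)), 0)
  )
  max_rhat <- max(diag_tbl$rhat, na.rm = TRUE)
  converged <- is.finite(max_rhat) && max_rhat <= 1.1
  if (!converged) {
    warn(sprintf("chains may not have converged: max split-Rhat = %.3f",
                 max_rhat))
  }
  structure(
    list(draws = draws, par_names = par_names, monitored = monitored,
         diagnostics = diag_tbl, converged = converged,
         chain_meta = list(chains = chains, iter = iter, warmup = warmup,
                           thin = thin, seed = seed),
         K = K, T = T, data = data, basis = basis, gvs = gvs,
         hyper = hyper),
    class = "occu_fit"
  )
}

#' @export
print.occu_fit <- function(x, ...) {
  cat(sprintf(
    "<occu_fit> %d chains x %d draws (%d warmup), %d parameters\n",
    x$chain_meta$chains, dim(x$draws)[1], x$chain_meta$warmup,
    length(x$par_names)))
  cat(sprintf("max split-Rhat (monitored): %.3f; converged: %s\n",
              max(x$diagnostics$rhat, na.rm = TRUE), x$converged))
  invisible(x)
}

# pooled draw matrix (all chains stacked)
draw_matrix <- function(fit) {
  d <- fit$draws
  out <- do.call(rbind, lapply(seq_len(dim(d)[2]), function(ch) d[, ch, ]))
  colnames(out) <- fit$par_names
  out
}

# reconstruct an occu_params object from one pooled draw row
params_from_draw <- function(fit, row) {
  v <- draw_matrix(fit)[row, ]
  K <- fit$K; T <- fit$T
  nms <- fit$par_names
  eta <- v[grepl("^eta\\[", nms)]
  occu_params(
    nu = matrix(v[grepl("^nu\\[", nms)], K, T),
    beta = v[grepl("^beta\\[", nms)],
    omega = as.integer(round(v[grepl("^omega\\[", nms)])),
    sigma2_rw = v[["sigma2_rw"]], lam = v[["lam"]],
    pi_t = v[grepl("^pi\\[", nms)],
    theta = v[["theta"]], theta_prime = v[["theta_prime"]],
    alpha = v[paste0("alpha", 0:3)],
    eta = unname(eta), sigma2_obs = v[["sigma2_obs"]]
  )
}

#' @rdname fit_occupancy
#' @param x,object An `occu_fit` object.
#' @param ... Unused.
#' @export
tidy.occu_fit <- function(x, ...) {
  dm <- draw_matrix(x)
  qs <- apply(dm, 2, quantile, probs = c(0.025, 0.975))
  d <- x$diagnostics
  tibble(
    term = colnames(dm),
    estimate = colMeans(dm),
    std.error = apply(dm, 2, sd),
    conf.low = qs[1, ],
    conf.high = qs[2, ],
    rhat = d$rhat[match(colnames(dm), d$parameter)],
    ess = d$ess[match(colnames(dm), d$parameter)]
  )
}

#' @rdname fit_occupancy
#' @export
glance.occu_fit <- function(x, ...) {
  tibble(
    n_sites = x$data$N, n_years = x$data$T,
    n_surveyed = sum(x$data$surveyed),
    chains = x$chain_meta$chains,
    n_draws = dim(x$draws)[1] * x$chain_meta$chains,
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess = min(x$diagnostics$ess, na.rm = TRUE),
    converged = x$converged
  )
}
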