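# MCMC for the data-augmented MSOM: Gibbs updates for the latent
# membership/occupancy indicators and the inclusion probability, adaptive
# random-walk Metropolis (target acceptance 0.44) for species-level
# coefficients and community hyperparameters.

# Clamp probabilities away from {0, 1} so likelihood terms like
# (1 - z) * log(1 - psi) never produce 0 * -Inf at logit extremes.
.clamp01 <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)

# Bivariate-normal log-density of the (delta0, lambda0) pairs.
.bvn_logdens <- function(d0, l0, mu1, mu2, s1, s2, rho) {
  z1 <- (d0 - mu1) / s1
  z2 <- (l0 - mu2) / s2
  q <- (z1^2 - 2 * rho * z1 * z2 + z2^2) / (1 - rho^2)
  -log(2 * pi) - log(s1) - log(s2) - 0.5 * log1p(-rho^2) - 0.5 * q
}

# Conditional normal parameters of one BVN margin given the other.
.bvn_cond <- function(other, mu_self, mu_other, s_self, s_other, rho) {
  list(mean = mu_self + rho * s_self / s_other * (other - mu_other),
       sd = s_self * sqrt(1 - rho^2))
}

# Bernoulli log-likelihood of z rows under occupancy probability psi,
# zeroed out for slots outside the community (omega = 0).
.z_loglik_rows <- function(z, psi, om) {
  ll <- rowSums(z * log(psi) + (1 - z) * log1p(-psi))
  ll * om
}

# One MSOM chain.  Returns hyperparameter traces, retained z draws and
# acceptance diagnostics.
.msom_chain <- function(y, v, x, control, chain_id) {
  m <- nrow(y)
  p <- ncol(y)
  det_any <- rowSums(y) > 0
  forced <- y > 0

  # dispersed initial values
  d0 <- rnorm(m, 0, 1)
  d1 <- rnorm(m, 0, 1)
  l0 <- rnorm(m, 0, 1)
  om <- as.numeric(det_any | runif(m) < 0.5)
  z <- matrix(as.numeric(forced), m, p)
  omega <- runif(1, 0.2, 0.8)
  hyp <- c(mu_d0 = rnorm(1, 0, 0.5), mu_l0 = rnorm(1, 0, 0.5),
           mu_d1 = rnorm(1, 0, 0.5), s_d0 = runif(1, 0.5, 1.5),
           s_l0 = runif(1, 0.5, 1.5), s_d1 = runif(1, 0.5, 1.5),
           rho = runif(1, -0.3, 0.3))

  # adaptive proposal scales: species-level (3) + hyper (7)
  ls_sp <- c(d0 = log(0.5), d1 = log(0.5), l0 = log(0.5))
  ls_hy <- rep(log(0.2), 7)
  names(ls_hy) <- names(hyp)
  acc_sp <- c(d0 = 0, d1 = 0, l0 = 0)
  try_sp <- c(d0 = 0, d1 = 0, l0 = 0)
  acc_hy <- numeric(7)
  try_hy <- numeric(7)

  n_keep <- (control$iterations - control$burn_in) %/% control$thin
  mon <- c(names(hyp), "Omega", "N_tot")
  trace <- matrix(NA_real_, n_keep, length(mon),
                  dimnames = list(NULL, mon))
  z_draws <- if (control$keep_z) array(0L, dim = c(m, p, n_keep)) else NULL
  keep_i <- 0L

  for (it in seq_len(control$iterations)) {
    psi <- .clamp01(plogis(d0 + outer(d1, x)))
    theta <- .clamp01(plogis(l0))
    q_v <- (1 - theta)^v                # P(no detection over V | present)

    # --- omega: Gibbs, z integrated out (undetected slots only) ---
    if (any(!det_any)) {
      idx <- which(!det_any)
      l1 <- exp(rowSums(log(psi[idx, , drop = FALSE] * q_v[idx] +
                              (1 - psi[idx, , drop = FALSE]))))
      p1 <- omega * l1 / (omega * l1 + (1 - omega))
      om[idx] <- as.numeric(runif(length(idx)) < p1)
    }
    om[det_any] <- 1

    # --- z: Gibbs given omega ---
    pz <- psi * q_v / (psi * q_v + (1 - psi))
    z <- matrix(as.numeric(runif(m * p) < pz), m, p)
    z[om == 0, ] <- 0
    z[forced] <- 1

    # --- Omega: conjugate Beta update under Beta(a, 1) prior ---
    omega <- rbeta(1, control$omega_a + sum(om), 1 + m - sum(om))
    omega <- min(max(omega, 1e-12), 1 - 1e-12)

    # --- delta0 (vectorised per-species Metropolis) ---
    prop <- d0 + rnorm(m, 0, exp(ls_sp["d0"]))
    psi_new <- .clamp01(plogis(prop + outer(d1, x)))
    cnd <- .bvn_cond(l0, hyp["mu_d0"], hyp["mu_l0"], hyp["s_d0"],
                     hyp["s_l0"], hyp["rho"])
    lr <- .z_loglik_rows(z, psi_new, om) - .z_loglik_rows(z, psi, om) +
      dnorm(prop, cnd$mean, cnd$sd, log = TRUE) -
      dnorm(d0, cnd$mean, cnd$sd, log = TRUE)
    acc <- log(runif(m)) < lr
    d0[acc] <- prop[acc]
    psi[acc, ] <- psi_new[acc, ]
    acc_sp["d0"] <- acc_sp["d0"] + mean(acc)
    try_sp["d0"] <- try_sp["d0"] + 1

    # --- delta1 ---
    prop <- d1 + rnorm(m, 0, exp(ls_sp["d1"]))
    psi_new <- .clamp01(plogis(d0 + outer(prop, x)))
    lr <- .z_loglik_rows(z, psi_new, om) - .z_loglik_rows(z, psi, om) +
      dnorm(prop, hyp["mu_d1"], hyp["s_d1"], log = TRUE) -
      dnorm(d1, hyp["mu_d1"], hyp["s_d1"], log = TRUE)
    acc <- log(runif(m)) < lr
    d1[acc] <- prop[acc]
    psi[acc, ] <- psi_new[acc, ]
    acc_sp["d1"] <- acc_sp["d1"] + mean(acc)
    try_sp["d1"] <- try_sp["d1"] + 1

    # --- lambda0 ---
    prop <- l0 + rnorm(m, 0, exp(ls_sp["l0"]))
    th_new <- .clamp01(plogis(prop))
    # detection likelihood: only occupied patch-slots contribute
    det_ll <- function(th) {
      rowSums(z * (y * log(th) + (v - y) * log1p(-th)))
    }
    cnd <- .bvn_cond(d0, hyp["mu_l0"], hyp["mu_d0"], hyp["s_l0"],
                     hyp["s_d0"], hyp["rho"])
    lr <- det_ll(th_new) - det_ll(theta) +
      dnorm(prop, cnd$mean, cnd$sd, log = TRUE) -
      dnorm(l0, cnd$mean, cnd$sd, log = TRUE)
    acc <- log(runif(m)) < lr
    l0[acc] <- prop[acc]
    acc_sp["l0"] <- acc_sp["l0"] + mean(acc)
    try_sp["l0"] <- try_sp["l0"] + 1

    # --- hyperparameters: scalar Metropolis each ---
    hyper_logpost <- function(h) {
      if (h["s_d0"] <= 0 || h["s_d0"] > control$sd_max ||
          h["s_l0"] <= 0 || h["s_l0"] > control$sd_max ||
          h["s_d1"] <= 0 || h["s_d1"] > control$sd_max ||
          abs(h["rho"]) >= 1) return(-Inf)
      sum(.bvn_logdens(d0, l0, h["mu_d0"], h["mu_l0"], h["s_d0"],
                       h["s_l0"], h["rho"])) +
        sum(dnorm(d1, h["mu_d1"], h["s_d1"], log = TRUE)) +
        dlogis(h["mu_d0"], log = TRUE) +   # Beta(1,1) on plogis scale
        dlogis(h["mu_l0"], log = TRUE) +
        dnorm(h["mu_d1"], 0, 1, log = TRUE)
    }
    lp_cur <- hyper_logpost(hyp)
    for (j in seq_along(hyp)) {
      h_new <- hyp
      h_new[j] <- h_new[j] + rnorm(1, 0, exp(ls_hy[j]))
      lp_new <- hyper_logpost(h_new)
      if (log(runif(1)) < lp_new - lp_cur) {
        hyp <- h_new
        lp_cur <- lp_new
        acc_hy[j] <- acc_hy[j] + 1
      }
      try_hy[j] <- try_hy[j] + 1
    }

    # --- adaptation during burn-in ---
    if (it <= control$burn_in && it %% control$adapt_batch == 0) {
      step <- min(0.1, 1 / sqrt(it / control$adapt_batch))
      ls_sp <- ls_sp + ifelse(acc_sp / try_sp > 0.44, step, -step)
      ls_hy <- ls_hy + ifelse(acc_hy / try_hy > 0.44, step, -step)
      acc_sp[] <- 0; try_sp[] <- 0
      acc_hy[] <- 0; try_hy[] <- 0
    }

    # --- retention ---
    if (it > control$burn_in &&
        (it - control$burn_in) %% control$thin == 0) {
      keep_i <- keep_i + 1L
      trace[keep_i, ] <- c(hyp, omega, sum(om))
      if (control$keep_z) z_draws[, , keep_i] <- as.integer(z)
    }
  }
  list(trace = trace, z_draws = z_draws, chain_id = chain_id,
       accept_species = acc_sp / pmax(try_sp, 1),
       accept_hyper = acc_hy / pmax(try_hy, 1))
}

#' Fit the data-augmented multi-species occupancy model
#'
#' Gibbs updates for community membership `omega_m` and occupancy `z_pm`
#' (with `z` forced to 1 wherever a detection occurred), a conjugate Beta
#' update for the inclusion probability Omega, and adaptive
#' Metropolis-within-Gibbs for species coefficients and community
#' hyperparameters.  Convergence of monitored parameters (hyper-means,
#' hyper-SDs, intercept correlation, Omega, total community size) is
#' summarised by the Gelman-Rubin diagnostic; any R-hat at or above 1.05
#' flags non-convergence in the output (not fatal).
#'
#' @param data an [augment()]ed incidence object.
#' @param areas per-patch areas (ha), aligned with the columns of
#'   `data$Y_aug`.
#' @param control an [msom_control()] configuration.
#' @return object of class `"msom_fit"`: list with `z_draws`
#'   (`M` x patches x retained draws), `traces` (per-chain matrices of
#'   monitored parameters), `rhat`, `converged`, `n_retained`, `control`,
#'   `data`, `covariate` metadata.
#' @export
fit_msom <- function(data, areas, control = msom_control()) {
  stopifnot(inherits(data, "augmented_incidence"),
            length(areas) == ncol(data$Y_aug))
  x <- switch(control$covariate,
              log_std = as.numeric(scale(log(areas))),
              raw = areas)
  chains <- lapply(seq_len(control$chains), function(ch) {
    .msom_chain(data$Y_aug, data$V, x, control, ch)
  })
  traces <- lapply(chains, `[[`, "trace")
  rhat <- if (control$chains >= 2 && nrow(traces[[1]]) >= 2)
    gelman_rubin(traces) else NULL
  z_draws <- NULL
  if (control$keep_z) {
    z_draws <- array(0L, dim = c(data$M, ncol(data$Y_aug),
                                 msom_retained(control)))
    k <- 0L
    for (ch in chains) {
      nk <- dim(ch$z_draws)[3]
      z_draws[, , k + seq_len(nk)] <- ch$z_draws
      k <- k + nk
    }
  }
  structure(list(z_draws = z_draws, traces = traces, rhat = rhat,
                 converged = if (is.null(rhat)) NA else all(rhat < 1.05),
                 n_retained = msom_retained(control), control = control,
                 data = data, covariate = control$covariate,
                 covariate_values = x),
            class = "msom_fit")
}

#' @export
print.msom_fit <- function(x, ...) {
  cat(sprintf("MSOM fit: M = %d slots (%d detected), %d patches, V = %d\n",
              x$data$M, x$data$S_obs_total, ncol(x$data$Y_aug), x$data$V))
  cat(sprintf("  %d chains, %d retained draws; converged: %s\n",
              x$control$chains, x$n_retained,
              ifelse(is.na(x$converged), "NA (single chain)",
                     x$converged)))
  if (!is.null(x$rhat)) {
    cat("  R-hat: ",
        paste(sprintf("%s=%.3f", names(x$rhat), x$rhat), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Posterior per-patch richness from an MSOM fit
#'
#' Per retained draw, patch richness is the number of occupied slots
#' `S_p = sum_m z_pm`; the point estimate is the posterior mean.
#'
#' @param fit an [fit_msom()] result (with retained `z_draws`).
#' @return list with `mean`, `sd` (per-patch vectors) and `draws`
#'   (draws x patches matrix).
#' @export
derive_richness <- function(fit) {
  stopifnot(inherits(fit, "msom_fit"), !is.null(fit$z_draws))
  s_draws <- t(colSums(fit$z_draws))     # draws x patches
  list(mean = colMeans(s_draws), sd = apply(s_draws, 2, sd),
       draws = s_draws)
}

#' Posterior pairwise Sorensen similarity from an MSOM fit
#'
#' Per retained draw, `Sor(a, b) = 2 |z_a & z_b| / (S_a + S_b)` over the
#' occupancy vectors; draws in which both patches are empty are excluded
#' from the posterior mean (pairs empty in every draw are `NA`).
#'
#' @param fit an [fit_msom()] result (with retained `z_draws`).
#' @return list with `mean` (patches x patches posterior-mean similarity
#'   matrix, diagonal 1) and `n_draws_used` (per-pair counts).
#' @export
derive_sorensen <- function(fit) {
  stopifnot(inherits(fit, "msom_fit"), !is.null(fit$z_draws))
  p <- dim(fit$z_draws)[2]
  n_draws <- dim(fit$z_draws)[3]
  acc <- matrix(0, p, p)
  cnt <- matrix(0L, p, p)
  for (k in seq_len(n_draws)) {
    z <- fit$z_draws[, , k]
    inter <- crossprod(z)
    s <- colSums(z)
    denom <- outer(s, s, `+`)
    ok <- denom > 0
    acc[ok] <- acc[ok] + 2 * inter[ok] / denom[ok]
    cnt <- cnt + ok
  }
  mean_mat <- acc / cnt
  mean_mat[cnt == 0] <- NA_real_
  diag(mean_mat) <- ifelse(diag(cnt) > 0, 1, NA_real_)
  list(mean = mean_mat, n_draws_used = cnt)
}
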