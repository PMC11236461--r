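# Data-augmented hierarchical multi-species occupancy model (MSOM).
#
# Model, for each species slot m of the augmented list and patch p:
#   omega_m       ~ Bernoulli(Omega)            community membership
#   z_pm          ~ Bernoulli(omega_m * psi_pm) occupancy
#   y_pm          ~ Binomial(V, z_pm * theta_m) detections over V visits
#   logit(psi_pm) = delta0_m + delta1_m * x_p   occupancy linear predictor
#   logit(theta_m)= lambda0_m                   detection intercept
# with (delta0_m, lambda0_m) jointly bivariate normal across species,
# delta1_m normal, community-level hyperpriors on all means/SDs, and a
# scale-prior approximation Beta(a, 1) with small a on Omega.

#' Augment an incidence matrix with all-zero species slots
#'
#' Appends twice as many never-detected pseudo-species rows as there are
#' detected species, so slots for community members that escaped detection
#' entirely can be estimated: `M = 3 * S_obs_total`.
#'
#' @param y_detected detected-species x patches incidence count matrix
#'   (entries: number of visits with a detection, `0..V`).  Rows that are
#'   entirely zero are dropped before augmentation.
#' @param V number of visits per patch.
#' @return object of class `"augmented_incidence"`: list with `Y_aug`
#'   (`M` x patches), `M`, `S_obs_total`, `V`.
#' @export
augment <- function(y_detected, V) {
  y_detected <- as.matrix(y_detected)
  keep <- rowSums(y_detected) > 0
  y <- y_detected[keep, , drop = FALSE]
  s_obs <- nrow(y)
  if (s_obs < 1) stop("model unfittable: zero detected species")
  stopifnot(all(y >= 0), all(y <= V))
  n_aug <- 2L * s_obs
  y_aug <- rbind(y, matrix(0L, n_aug, ncol(y)))
  rownames(y_aug) <- NULL
  structure(list(Y_aug = y_aug, M = s_obs + n_aug, S_obs_total = s_obs,
                 V = as.integer(V)),
            class = "augmented_incidence")
}

#' Build augmented MSOM data from a survey
#'
#' @param survey a [survey()] / [sample_landscape()] result.
#' @return an [augment()]ed incidence object (species slots x patches).
#' @export
msom_data <- function(survey) {
  augment(t(survey$Y), survey$V)
}

#' Joint MSOM log-density of data and latent states
#'
#' Evaluates the log of
#' `p(omega | Omega) p(z | omega, psi) p(y | z, theta, V)` for a full
#' latent-state configuration.  Impossible states (a detection where
#' `z = 0`, or `z = 1` where `omega = 0`) return `-Inf`.
#'
#' @param params list with elements `omega` (length `M` 0/1), `Omega`
#'   (scalar), `z` (`M` x patches 0/1), `delta0`, `delta1`, `lambda0`
#'   (length `M`).
#' @param data an [augment()]ed incidence object.
#' @param x per-patch occupancy covariate (see [msom_control()]).
#' @return joint log-density (finite for admissible states).
#' @export
msom_loglik <- function(params, data, x) {
  y <- data$Y_aug
  v <- data$V
  m <- data$M
  stopifnot(length(params$omega) == m, nrow(params$z) == m,
            length(x) == ncol(y))
  om <- params$omega
  z <- params$z
  if (any(y > 0 & z == 0) || any(z == 1 & om == 0)) return(-Inf)
  lp_om <- sum(om * log(params$Omega) + (1 - om) * log1p(-params$Omega))
  psi <- plogis(params$delta0 + outer(params$delta1, x))
  pocc <- om * psi                       # z ~ Bern(omega * psi)
  lp_z <- sum(z * log(pocc + (pocc == 0)) + (1 - z) * log1p(-pocc))
  theta <- plogis(params$lambda0)
  pdet <- z * theta                      # y ~ Binom(V, z * theta)
  lp_y <- sum(dbinom(y, v, pdet, log = TRUE))
  lp_om + lp_z + lp_y
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) R-hat: with `m >= 2` chains of length `n`,
#' `W` the mean within-chain variance and `B/n` the variance of chain
#' means, `R-hat = sqrt(((n-1)/n * W + B/n) / W)`.  Values below 1.05 are
#' taken to indicate convergence.
#'
#' @param traces list of chains, each an iterations x parameters matrix
#'   (or a vector for a single parameter).
#' @return named numeric vector of R-hat per parameter.
#' @export
gelman_rubin <- function(traces) {
  traces <- lapply(traces, function(tr) {
    if (is.null(dim(tr))) matrix(tr, ncol = 1) else as.matrix(tr)
  })
  if (length(traces) < 2) stop("at least 2 chains are required")
  n <- nrow(traces[[1]])
  if (n < 2) stop("at least 2 retained draws per chain are required")
  stopifnot(all(vapply(traces, nrow, 0L) == n))
  means <- vapply(traces, colMeans, numeric(ncol(traces[[1]])))
  vars <- vapply(traces, function(tr) apply(tr, 2, var),
                 numeric(ncol(traces[[1]])))
  if (is.null(dim(means))) {  # single parameter
    means <- matrix(means, nrow = 1)
    vars <- matrix(vars, nrow = 1)
  }
  w <- rowMeans(vars)
  b_over_n <- apply(means, 1, var)          # = B/n
  var_plus <- (n - 1) / n * w + b_over_n
  rhat <- sqrt(var_plus / w)
  names(rhat) <- colnames(traces[[1]])
  rhat
}

#' MSOM sampler configuration
#'
#' MCMC and prior settings.  The published profile is 4 chains of 50,000
#' iterations, burn-in 10,000, thinning 20 (8,000 retained draws); the
#' desk profile ([msom_control_desk()]) is a reduced configuration for
#' interactive and test use.
#'
#' @param chains,iterations,burn_in,thin MCMC bookkeeping; retained draws
#'   per chain are `(iterations - burn_in) / thin`.
#' @param omega_a shape `a` of the `Beta(a, 1)` scale-prior approximation
#'   on the community inclusion probability Omega.
#' @param sd_max upper bound of the uniform priors on hyper-SDs.
#' @param covariate `"log_std"` (standardised ln(area); communities are
#'   generated on the log-area scale) or `"raw"` (area in ha).
#' @param adapt_batch batch length for acceptance-rate adaptation during
#'   burn-in (target 0.44).
#' @param keep_z store the retained occupancy draws (needed by
#'   [derive_richness()] / [derive_sorensen()]).
#' @return list of class `"msom_control"`.
#' @export
msom_control <- function(chains = 4, iterations = 50000, burn_in = 10000,
                         thin = 20, omega_a = 0.001, sd_max = 5,
                         covariate = c("log_std", "raw"),
                         adapt_batch = 50, keep_z = TRUE) {
  covariate <- match.arg(covariate)
  stopifnot(chains >= 1, iterations > burn_in, thin >= 1,
            (iterations - burn_in) %% thin == 0)
  structure(list(chains = chains, iterations = iterations,
                 burn_in = burn_in, thin = thin, omega_a = omega_a,
                 sd_max = sd_max, covariate = covariate,
                 adapt_batch = adapt_batch, keep_z = keep_z),
            class = "msom_control")
}

#' Reduced desk-scale MSOM profile
#'
#' 2 chains x 6,000 iterations, burn-in 2,000, thinning 10 (800 retained
#' draws).  Distinct from the published 4 x 50,000 profile, which remains
#' the [msom_control()] default for full replication.
#'
#' @param ... overrides passed to [msom_control()].
#' @return an `"msom_control"` object.
#' @export
msom_control_desk <- function(...) {
  args <- modifyList(list(chains = 2, iterations = 6000, burn_in = 2000,
                          thin = 10), list(...))
  do.call(msom_control, args)
}

#' Retained-draw accounting for an MSOM configuration
#'
#' @param control an `"msom_control"` object.
#' @return total retained draws, `chains * (iterations - burn_in) / thin`.
#' @export
msom_retained <- function(control) {
  control$chains * (control$iterations - control$burn_in) %/% control$thin
}
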