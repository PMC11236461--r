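# Imperfect, spatially incomplete sampling: species detection
# probabilities, transect-based availability, repeated binomial surveys,
# and the pooled/incidence summaries the estimators consume.

#' Nine-scenario detection grid
#'
#' The factorial detection design: mean detection probability
#' `mu` in \{0.005, 0.05, 0.2\} crossed with logit-scale standard deviation
#' `sigma` in \{0.25, 1.0, 3.0\}, labelled S1-S9 in order of increasing
#' `mu` (outer) and `sigma` (inner).
#'
#' @return data.frame with columns `scenario_id`, `mu`, `sigma`.
#' @export
detection_scenarios <- function() {
  grid <- expand.grid(sigma = c(0.25, 1.0, 3.0), mu = c(0.005, 0.05, 0.2))
  data.frame(scenario_id = paste0("S", seq_len(nrow(grid))),
             mu = grid$mu, sigma = grid$sigma)
}

#' Draw per-species detection probabilities
#'
#' Individual-level detection probabilities are logit-normal:
#' `logit(theta_i) ~ Normal(logit(mu), sigma)` independently per species.
#'
#' @param n_species number of species.
#' @param mu mean detection probability, in (0, 1).
#' @param sigma logit-scale standard deviation, >= 0.
#' @return numeric vector `theta` in (0, 1).
#' @export
draw_detection_probs <- function(n_species, mu, sigma) {
  if (!(mu > 0 && mu < 1)) stop("mu must lie strictly in (0, 1)")
  if (sigma < 0) stop("sigma must be >= 0")
  plogis(rnorm(n_species, qlogis(mu), sigma))
}

#' Transect schedule for a patch
#'
#' Field surveys cover a fixed-footprint set of 500-m transects per patch
#' (one transect with a 50-m search radius = 5.93 ha).  Under the default
#' capped-proportional schedule the transect count grows proportionally
#' with patch area (one transect per `area_per_transect` = 25 ha, so the
#' smallest patch gets exactly one) up to a logistical cap of `cap` = 16
#' transects.  Below the cap the sampled area tracks patch area and the
#' sampled proportion `pi_p` stays near its maximum; above it `pi_p`
#' declines as 1/area, so in the largest patches the sampled fraction
#' falls below 0.5 / 100 and a minimum viable population of 100
#' individuals rounds to zero available individuals -- the additional
#' spatial detection-failure mechanism that drives large-patch richness
#' underestimation.  (The default cap is the largest integer for which
#' that mechanism fires in a 20,000-ha patch:
#' `floor(0.005 * 20000 / 5.93) = 16`.)
#'
#' A sub-linear power law `max(1, round(scale * (area/25)^exponent))` is
#' available via `schedule = "power"`, and a lookup table
#' (`area` -> `transects`) overrides either analytic schedule.
#'
#' @param area patch area(s) in ha.
#' @param schedule `"capped_prop"` (default) or `"power"`.
#' @param area_per_transect ha of patch area per transect in the
#'   proportional regime.
#' @param cap maximum transects per patch.
#' @param scale,exponent power-law schedule parameters (used when
#'   `schedule = "power"`).
#' @param transect_area footprint of one transect in ha.
#' @param lookup optional data.frame with columns `area` and `transects`;
#'   matched by nearest area.
#' @return list with `transects` (integer vector) and `pi_p` (sampled
#'   proportion, clamped to `(0, 1]`).
#' @export
transect_schedule <- function(area, schedule = c("capped_prop", "power"),
                              area_per_transect = 25, cap = 16,
                              scale = 1, exponent = 0.75,
                              transect_area = 5.93, lookup = NULL) {
  stopifnot(all(area > 0))
  schedule <- match.arg(schedule)
  if (!is.null(lookup)) {
    idx <- vapply(area, function(a) which.min(abs(lookup$area - a)), 0L)
    tr <- as.integer(lookup$transects[idx])
  } else if (schedule == "capped_prop") {
    tr <- pmax(1L, pmin(as.integer(round_half_up(area / area_per_transect)),
                        as.integer(cap)))
  } else {
    tr <- pmax(1L, as.integer(round_half_up(scale * (area / 25)^exponent)))
  }
  list(transects = tr, pi_p = pmin(1, tr * transect_area / area))
}

#' Individuals available for sampling
#'
#' Assuming constant within-patch density, the number of individuals of
#' each species available within the sampled fraction `pi_p` of patch p is
#' `round(N[p,i] * pi_p)` (round-half-up).  Species whose in-patch
#' abundance times `pi_p` rounds to zero become unavailable: an extra
#' detection-failure mechanism on top of per-individual detectability.
#'
#' @param N patches x species true abundance matrix.
#' @param pi_p per-patch sampled proportion in (0, 1].
#' @return integer matrix of available counts, same shape as `N`.
#' @export
available_counts <- function(N, pi_p) {
  stopifnot(all(pi_p > 0), all(pi_p <= 1), length(pi_p) == nrow(N))
  matrix(as.integer(round_half_up(N * pi_p)), nrow(N), ncol(N),
         dimnames = dimnames(N))
}

#' Simulate repeated binomial surveys
#'
#' Each of `V` visits to each patch records
#' `X[p,i,v] ~ Binomial(n[p,i], theta_i)` independently: every available
#' individual is detected with its species' probability, individuals being
#' exchangeable within species (and recountable across visits).
#'
#' @param n_avail patches x species availability matrix.
#' @param theta per-species detection probabilities.
#' @param V number of visits per patch (>= 1).
#' @return object of class `"survey_data"`: list with `X` (patches x
#'   species x visits), `pooled` (counts summed over visits), `Y`
#'   (incidence: number of visits with >= 1 detection), and `V`.
#' @export
survey <- function(n_avail, theta, V) {
  stopifnot(V >= 1, length(theta) == ncol(n_avail),
            all(theta >= 0), all(theta <= 1))
  p <- nrow(n_avail)
  s <- ncol(n_avail)
  prob <- rep(theta, each = p)
  x <- array(0L, dim = c(p, s, V))
  for (v in seq_len(V)) {
    x[, , v] <- rbinom(p * s, size = as.vector(n_avail), prob = prob)
  }
  pooled <- matrix(as.integer(rowSums(x, dims = 2)), p, s)
  y <- matrix(as.integer(rowSums(x > 0, dims = 2)), p, s)
  structure(list(X = x, pooled = pooled, Y = y, V = as.integer(V)),
            class = "survey_data")
}

#' @export
print.survey_data <- function(x, ...) {
  cat(sprintf("Survey data: %d patches x %d species x %d visits; %d detections\n",
              dim(x$X)[1], dim(x$X)[2], x$V, sum(x$pooled)))
  invisible(x)
}

#' Observed per-patch species richness
#'
#' Number of species with at least one individual recorded in the counts
#' pooled across all visits.
#'
#' @param x a [survey()] result or a patches x species pooled-count matrix.
#' @return integer vector of per-patch richness.
#' @export
observed_richness <- function(x) {
  pooled <- if (inherits(x, "survey_data")) x$pooled else x
  as.integer(rowSums(pooled > 0))
}

#' Simulate one full sampling process over a landscape
#'
#' Convenience wrapper: draws detection probabilities for the scenario,
#' computes the transect schedule and availability, and runs the `V`-visit
#' binomial survey.
#'
#' @param landscape a [simulate_landscape()] result.
#' @param mu,sigma detection hyperparameters (see
#'   [draw_detection_probs()]).
#' @param V visits per patch.
#' @param seed optional integer seed.
#' @param perfect if `TRUE`, overrides to the perfect-detection control:
#'   `theta = 1` and `pi_p = 1` everywhere.
#' @param ... passed to [transect_schedule()].
#' @return a `"survey_data"` object with added elements `theta`, `pi_p`,
#'   `transects`, `mu`, `sigma`, `seed`.
#' @export
sample_landscape <- function(landscape, mu, sigma, V, seed = NULL,
                             perfect = FALSE, ...) {
  if (!is.null(seed)) set.seed(seed)
  s <- landscape$metacommunity$n_species
  if (perfect) {
    theta <- rep(1, s)
    sched <- list(transects = rep(NA_integer_, length(landscape$patch_areas)),
                  pi_p = rep(1, length(landscape$patch_areas)))
  } else {
    theta <- draw_detection_probs(s, mu, sigma)
    sched <- transect_schedule(landscape$patch_areas, ...)
  }
  n_avail <- available_counts(landscape$N, sched$pi_p)
  out <- survey(n_avail, theta, V)
  out$theta <- theta
  out$pi_p <- sched$pi_p
  out$transects <- sched$transects
  out$mu <- if (perfect) 1 else mu
  out$sigma <- if (perfect) 0 else sigma
  out$seed <- seed
  out
}
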