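# Factorial experiment orchestration and the three performance criteria
# (bias, accuracy, precision) per parameter x method x scenario.

#' Bias of point estimates
#'
#' Mean of the signed differences between point estimates and the true
#' value.  For patch-level richness the bias is divided by the true
#' richness (scaled mean error, a proportion).
#'
#' @param estimates vector of point estimates across replicate datasets.
#' @param truth true parameter value (scalar).
#' @param scale_by_truth divide by `truth` (richness convention).
#' @return signed mean error; `NA` if scaling by a zero truth.
#' @export
bias <- function(estimates, truth, scale_by_truth = FALSE) {
  stopifnot(length(estimates) >= 1, length(truth) == 1)
  b <- mean(estimates - truth)
  if (scale_by_truth) {
    if (truth == 0) return(NA_real_)
    b <- b / truth
  }
  b
}

#' Accuracy of point estimates
#'
#' Mean absolute difference between point estimates and the true value,
#' multiplied by -1 (0 is perfect; more negative is worse).  Scaled by the
#' true value for patch-level richness, as with [bias()].
#'
#' @inheritParams bias
#' @return negative mean absolute error.
#' @export
accuracy <- function(estimates, truth, scale_by_truth = FALSE) {
  stopifnot(length(estimates) >= 1, length(truth) == 1)
  a <- -mean(abs(estimates - truth))
  if (scale_by_truth) {
    if (truth == 0) return(NA_real_)
    a <- a / truth
  }
  a
}

#' Precision of point estimates
#'
#' Negative coefficient of variation: sample standard deviation (n - 1
#' denominator) of the point estimates divided by the absolute value of
#' their mean, multiplied by -1.
#'
#' @param estimates vector of point estimates (>= 2).
#' @return negative CV; `NA` when the mean is zero.
#' @export
precision <- function(estimates) {
  stopifnot(length(estimates) >= 2)
  m <- mean(estimates)
  if (m == 0) return(NA_real_)
  -sd(estimates) / abs(m)
}

#' Factorial experiment configuration
#'
#' The full profile crosses mean detection probability, detection-SD,
#' area-response ramp maximum and visit count (3 levels each: 81
#' combinations) with 35 landscape communities per combination and 10
#' sampled datasets per community (2,835 communities, 28,350 datasets).
#' The desk profile is a single-scenario reduction for interactive use.
#'
#' @param mu_grid,sigma_grid,alpha_max_grid,V_grid factor levels.
#' @param communities_per_combo landscape communities per combination.
#' @param sampling_reps_per_community sampled datasets per community.
#' @param master_seed hierarchical seeding root.
#' @param methods estimation routes to run.
#' @param msom_control MCMC profile for the MSOM route.
#' @param n_patches,n_species landscape dimensions.
#' @param profile label recorded in outputs (`"full"` or `"desk"`).
#' @return list of class `"experiment_config"`.
#' @export
experiment_config <- function(mu_grid = c(0.005, 0.05, 0.2),
                              sigma_grid = c(0.25, 1.0, 3.0),
                              alpha_max_grid = c(4, 8, 12),
                              V_grid = c(3, 6, 12),
                              communities_per_combo = 35,
                              sampling_reps_per_community = 10,
                              master_seed = 1,
                              methods = c("observed", "chao", "msom"),
                              msom_control = msom_control_desk(),
                              n_patches = 25, n_species = 200,
                              profile = "full") {
  methods <- match.arg(methods, c("observed", "chao", "msom"),
                       several.ok = TRUE)
  structure(list(mu_grid = mu_grid, sigma_grid = sigma_grid,
                 alpha_max_grid = alpha_max_grid, V_grid = V_grid,
                 communities_per_combo = communities_per_combo,
                 sampling_reps_per_community = sampling_reps_per_community,
                 master_seed = master_seed, methods = methods,
                 msom_control = msom_control, n_patches = n_patches,
                 n_species = n_species, profile = profile),
            class = "experiment_config")
}

#' Desk-scale experiment profile
#'
#' Single scenario (mu = 0.2, sigma = 1.0, alpha_max = 8, V = 6), two
#' communities, three sampling replicates: a complete end-to-end run in
#' minutes on one CPU.
#'
#' @param ... overrides passed to [experiment_config()].
#' @return an `"experiment_config"` object.
#' @export
experiment_config_desk <- function(...) {
  args <- modifyList(
    list(mu_grid = 0.2, sigma_grid = 1.0, alpha_max_grid = 8, V_grid = 6,
         communities_per_combo = 2, sampling_reps_per_community = 3,
         methods = c("observed", "chao"), profile = "desk"),
    list(...))
  do.call(experiment_config, args)
}

#' Enumerate the factorial design of a configuration
#'
#' @param config an [experiment_config()].
#' @return list with the scenario `grid` (data.frame), `n_combinations`,
#'   `n_communities`, `n_datasets`.
#' @export
enumerate_design <- function(config) {
  grid <- expand.grid(mu = config$mu_grid, sigma = config$sigma_grid,
                      alpha_max = config$alpha_max_grid, V = config$V_grid)
  scen <- detection_scenarios()
  grid$scenario_id <- scen$scenario_id[match(
    paste(grid$mu, grid$sigma), paste(scen$mu, scen$sigma))]
  n_comb <- nrow(grid)
  n_comm <- n_comb * config$communities_per_combo
  list(grid = grid, n_combinations = n_comb, n_communities = n_comm,
       n_datasets = n_comm * config$sampling_reps_per_community)
}

# Six-parameter estimates for one sampled dataset by one method.
# Returns list(richness, sorensen, c, z, g0, g1) or signals an error.
.estimate_method <- function(method, svy, landscape, msom_ctrl) {
  areas <- landscape$patch_areas
  if (method == "observed") {
    rich <- observed_richness(svy)
    sor <- sorensen_pairwise(svy$pooled)
  } else if (method == "chao") {
    rich <- chao_richness_by_patch(svy$pooled)
    sor <- chao_sorensen_matrix(svy$pooled)
  } else if (method == "msom") {
    fit <- fit_msom(msom_data(svy), areas, msom_ctrl)
    rich <- derive_richness(fit)$mean
    sor <- derive_sorensen(fit)$mean
  } else stop("unknown method: ", method)
  sar <- fit_sar(rich, areas)
  bg <- fit_beta_glm(sor, areas)
  list(richness = rich, sorensen = sor, c = sar$c_value, z = sar$z_value,
       g0 = bg$gamma0, g1 = bg$gamma1)
}

# Performance criteria for one landscape: estimates across sampling reps
# vs the landscape truth.  Patch-level (and pair-level) parameters are
# scored per patch/pair across replicates, then averaged.
.score_landscape <- function(est_reps, truth) {
  p <- length(truth$richness)
  rich_mat <- do.call(rbind, lapply(est_reps, `[[`, "richness"))
  per_patch <- function(f, ...) {
    vals <- vapply(seq_len(p), function(j) {
      f(rich_mat[, j], truth$richness[j], ...)
    }, 0)
    mean(vals, na.rm = TRUE)
  }
  rich_prec <- mean(vapply(seq_len(p), function(j) {
    if (nrow(rich_mat) < 2) return(NA_real_)
    precision(rich_mat[, j])
  }, 0), na.rm = TRUE)

  ut <- upper.tri(truth$sorensen)
  sor_mat <- do.call(rbind, lapply(est_reps, function(e) e$sorensen[ut]))
  true_sor <- truth$sorensen[ut]
  pair_score <- function(f, ...) {
    vals <- vapply(seq_along(true_sor), function(j) {
      est <- sor_mat[, j]
      est <- est[is.finite(est)]
      if (length(est) == 0 || !is.finite(true_sor[j])) return(NA_real_)
      f(est, true_sor[j], ...)
    }, 0)
    mean(vals, na.rm = TRUE)
  }
  sor_prec <- mean(vapply(seq_along(true_sor), function(j) {
    est <- sor_mat[, j]
    est <- est[is.finite(est)]
    if (length(est) < 2) return(NA_real_)
    precision(est)
  }, 0), na.rm = TRUE)

  scalar_rows <- lapply(
    c(c = "c", z = "z", gamma0 = "g0", gamma1 = "g1"),
    function(key) {
      tru <- switch(key, c = truth$c_value, z = truth$z_value,
                    g0 = truth$gamma0, g1 = truth$gamma1)
      est <- vapply(est_reps, `[[`, 0, key)
      data.frame(bias = bias(est, tru), accuracy = accuracy(est, tru),
                 precision = if (length(est) >= 2) precision(est) else NA_real_)
    })

  rbind(
    data.frame(parameter = "richness",
               bias = per_patch(bias, scale_by_truth = TRUE),
               accuracy = per_patch(accuracy, scale_by_truth = TRUE),
               precision = rich_prec),
    data.frame(parameter = "sorensen",
               bias = pair_score(bias), accuracy = pair_score(accuracy),
               precision = sor_prec),
    cbind(parameter = c("c_value", "z_value", "gamma0", "gamma1"),
          do.call(rbind, scalar_rows))
  )
}

#' Run the factorial estimator-performance experiment
#'
#' For each grid combination and community replicate: simulate a
#' landscape, derive the six true parameters once; for each sampling
#' replicate: sample under the scenario, estimate all six parameters by
#' each requested method, and fit the trend models.  Bias, accuracy and
#' precision are aggregated over sampling replicates per landscape, then
#' averaged across landscapes per scenario.  Fully deterministic given
#' `master_seed` (hierarchical seeding: master -> landscape -> replicate).
#'
#' @param config an [experiment_config()].
#' @param perfect if `TRUE`, overrides sampling to the perfect-detection
#'   control (theta = 1, pi = 1).
#' @param verbose print per-stage progress.
#' @return list of class `"experiment_result"`: `performance` (one row
#'   per scenario x method x parameter), `raw` (per-dataset scalar
#'   estimates), `failures` (count per cell), `config`.
#' @export
run_experiment <- function(config = experiment_config_desk(),
                           perfect = FALSE, verbose = FALSE) {
  design <- enumerate_design(config)
  grid <- design$grid
  combo_seeds <- derive_seeds(config$master_seed, nrow(grid))
  perf <- list()
  raw <- list()
  n_fail <- 0L
  for (g in seq_len(nrow(grid))) {
    t0 <- Sys.time()
    land_seeds <- derive_seeds(combo_seeds[g], config$communities_per_combo)
    combo_scores <- list()
    for (cc in seq_len(config$communities_per_combo)) {
      land <- simulate_landscape(n_patches = config$n_patches,
                                 n_species = config$n_species,
                                 alpha_max = grid$alpha_max[g],
                                 seed = land_seeds[cc])
      truth <- community_parameters(land$patch_areas, m = land$N)
      rep_seeds <- derive_seeds(land_seeds[cc] + 1L,
                                config$sampling_reps_per_community)
      est <- list()
      for (r in seq_len(config$sampling_reps_per_community)) {
        svy <- sample_landscape(land, mu = grid$mu[g], sigma = grid$sigma[g],
                                V = grid$V[g], seed = rep_seeds[r],
                                perfect = perfect)
        for (method in config$methods) {
          res <- tryCatch(
            .estimate_method(method, svy, land, config$msom_control),
            error = function(e) e)
          if (inherits(res, "error")) {
            n_fail <- n_fail + 1L
            next
          }
          est[[method]] <- c(est[[method]], list(res))
          raw[[length(raw) + 1L]] <- data.frame(
            scenario_id = grid$scenario_id[g], mu = grid$mu[g],
            sigma = grid$sigma[g], alpha_max = grid$alpha_max[g],
            V = grid$V[g], community = cc, rep = r, method = method,
            c_value = res$c, z_value = res$z, gamma0 = res$g0,
            gamma1 = res$g1, mean_richness = mean(res$richness),
            true_c = truth$c_value, true_z = truth$z_value,
            true_gamma0 = truth$gamma0, true_gamma1 = truth$gamma1,
            true_mean_richness = mean(truth$richness))
        }
      }
      for (method in names(est)) {
        sc <- .score_landscape(est[[method]], truth)
        sc$method <- method
        sc$community <- cc
        sc$n_replicates <- length(est[[method]])
        combo_scores[[length(combo_scores) + 1L]] <- sc
      }
    }
    if (length(combo_scores) > 0) {
      all_sc <- do.call(rbind, combo_scores)
      agg <- aggregate(all_sc[c("bias", "accuracy", "precision")],
                       by = all_sc[c("parameter", "method")],
                       FUN = mean, na.rm = TRUE)
      nrep <- aggregate(list(n_replicates = all_sc$n_replicates),
                        by = all_sc[c("parameter", "method")], FUN = sum)
      agg <- merge(agg, nrep)
      agg <- cbind(grid[rep(g, nrow(agg)), , drop = FALSE], agg,
                   row.names = NULL)
      perf[[length(perf) + 1L]] <- agg
    }
    if (verbose) {
      message(sprintf("combo %d/%d (%s, amax=%g, V=%d): %.1fs", g,
                      nrow(grid), grid$scenario_id[g], grid$alpha_max[g],
                      grid$V[g], as.numeric(Sys.time() - t0, units = "secs")))
    }
  }
  structure(list(performance = do.call(rbind, perf),
                 raw = do.call(rbind, raw), failures = n_fail,
                 config = config),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Experiment (%s profile): %d performance rows, %d raw rows, %d failures\n",
              x$config$profile, nrow(x$performance),
              if (is.null(x$raw)) 0L else nrow(x$raw), x$failures))
  invisible(x)
}
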