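test_that("augmentation triples the species list with zero rows", {
  y <- matrix(rbinom(50 * 6, 3, 0.4), 50, 6)
  y[y == 0] <- 1                             # ensure all 50 detected
  aug <- augment(y, V = 3)
  expect_equal(aug$M, 150)
  expect_equal(aug$S_obs_total, 50)
  expect_true(all(aug$Y_aug[51:150, ] == 0))
  expect_equal(nrow(aug$Y_aug), 150)

  aug1 <- augment(matrix(c(1, 0, 2), 1, 3), V = 2)
  expect_equal(aug1$M, 3)

  # all-zero input rows are dropped before augmentation
  y2 <- rbind(c(2, 0, 0), c(0, 0, 0), c(0, 1, 1))
  aug2 <- augment(y2, V = 2)
  expect_equal(aug2$S_obs_total, 2)
  expect_equal(aug2$M, 6)
  expect_equal(sum(rowSums(aug2$Y_aug) == 0), 4)

  expect_error(augment(matrix(0, 3, 4), V = 2), "unfittable")
})

test_that("joint log-likelihood matches closed forms and bans impossible states", {
  # one slot, two patches, V = 6
  data <- augment(matrix(c(3, 0), 1, 2), V = 6)   # detected slot + 2 aug
  x <- c(0, 0)
  base <- list(omega = c(1, 0, 0), Omega = 0.4,
               z = rbind(c(1, 0), c(0, 0), c(0, 0)),
               delta0 = rep(0, 3), delta1 = rep(0, 3),
               lambda0 = rep(0, 3))            # psi = theta = 0.5

  ll <- msom_loglik(base, data, x)
  # manual: omega terms log(.4) + 2*log(.6); z terms: slot1 log(.5)+log(.5),
  # slots 2-3 each 2*log(1); y terms: slot1 patch1 dbinom(3,6,.5),
  # patch2 z=0 -> dbinom(0,6,0)=1; aug slots dbinom(0,6,0)=1
  manual <- log(0.4) + 2 * log(0.6) + 2 * log(0.5) +
    dbinom(3, 6, 0.5, log = TRUE)
  expect_equal(ll, manual)
  # binomial term is log(choose(6,3) * 0.5^6)
  expect_equal(dbinom(3, 6, 0.5, log = TRUE), log(choose(6, 3) * 0.5^6))

  # absent augmented slot contributes log(1 - Omega) only
  drop_om <- base
  drop_om$Omega <- 0.25
  ll2 <- msom_loglik(drop_om, data, x)
  expect_equal(ll2, log(0.25) + 2 * log(0.75) + 2 * log(0.5) +
                 dbinom(3, 6, 0.5, log = TRUE))

  # detection with z = 0 is impossible
  bad <- base
  bad$z[1, 1] <- 0
  expect_identical(msom_loglik(bad, data, x), -Inf)
  # occupancy outside the community is impossible
  bad2 <- base
  bad2$z[2, 1] <- 1
  expect_identical(msom_loglik(bad2, data, x), -Inf)
})

test_that("Gelman-Rubin diagnostic matches the reference formula", {
  expect_error(gelman_rubin(list(matrix(1:10, 5))), "2 chains")

  # identical chains -> 1 up to the (n-1)/n finite-sample factor
  tr <- matrix(rnorm(1000), 500, 2)
  expect_equal(unname(gelman_rubin(list(tr, tr))), c(1, 1),
               tolerance = 2e-3)
  expect_equal(unname(gelman_rubin(list(tr, tr))),
               rep(sqrt(499 / 500), 2))

  # constant chains at different values -> enormous R-hat
  expect_gt(gelman_rubin(list(rep(0, 10) + 1e-9 * rnorm(10),
                              rep(5, 10) + 1e-9 * rnorm(10)))[1], 100)

  # fixed fixture vs independently coded PSRF
  set.seed(19)
  chains <- lapply(1:3, function(i) matrix(rnorm(60, i * 0.1), 30, 2))
  rh <- gelman_rubin(chains)
  for (j in 1:2) {
    draws <- sapply(chains, function(ch) ch[, j])   # n x m
    n <- nrow(draws)
    m <- ncol(draws)
    bb <- n * var(colMeans(draws))
    ww <- mean(apply(draws, 2, var))
    ref <- sqrt(((n - 1) / n * ww + bb / n) / ww)
    expect_equal(unname(rh[j]), ref, tolerance = 1e-6)
  }
})

test_that("MCMC bookkeeping matches the stated profiles", {
  expect_equal(msom_retained(msom_control()), 8000)
  expect_equal(msom_control()$chains, 4)
  expect_equal(msom_retained(msom_control_desk()), 800)
  expect_error(msom_control(iterations = 1000, burn_in = 2000), "iterations")
})

test_that("derived richness and Sorensen follow the per-draw formulas", {
  # two hand-built draws over 3 slots x 2 patches
  z1 <- rbind(c(1, 1), c(1, 0), c(1, 1))   # S = (3, 2), Sor = 2*2/5
  z2 <- rbind(c(1, 0), c(0, 1), c(0, 0))   # S = (1, 1), Sor = 0
  fit <- fake_msom_fit(array(c(z1, z2), dim = c(3, 2, 2)))

  rich <- derive_richness(fit)
  expect_equal(rich$mean, c(2, 1.5))
  expect_equal(rich$draws, rbind(c(3, 2), c(1, 1)))

  sor <- derive_sorensen(fit)
  expect_equal(sor$mean[1, 2], mean(c(4 / 5, 0)))
  expect_equal(diag(sor$mean), c(1, 1))

  # identical nonempty occupancy -> 1; disjoint -> 0
  z_same <- rbind(c(1, 1), c(1, 1), c(0, 0))
  expect_equal(derive_sorensen(
    fake_msom_fit(array(z_same, dim = c(3, 2, 1))))$mean[1, 2], 1)
  z_disj <- rbind(c(1, 0), c(0, 1), c(1, 0))
  expect_equal(derive_sorensen(
    fake_msom_fit(array(z_disj, dim = c(3, 2, 1))))$mean[1, 2], 0)
  # both-empty draws are excluded; all-empty pairs are NA
  z_empty <- matrix(0, 3, 2)
  expect_true(is.na(derive_sorensen(
    fake_msom_fit(array(z_empty, dim = c(3, 2, 1))))$mean[1, 2]))
})

test_that("a short fit respects forced occupancy and accounting", {
  set.seed(20)
  dat <- simulate_msom_dataset(n_species = 20, n_patches = 10, V = 4)
  aug <- augment(dat$y, V = dat$V)
  ctrl <- msom_control(chains = 2, iterations = 600, burn_in = 200,
                       thin = 4)
  fit <- fit_msom(aug, dat$areas, ctrl)

  expect_equal(fit$n_retained, 2 * (600 - 200) / 4)
  expect_equal(dim(fit$z_draws), c(aug$M, 10, fit$n_retained))
  expect_equal(nrow(fit$traces[[1]]), fit$n_retained / 2)

  # detections force occupancy in every retained draw
  det <- which(t(aug$Y_aug) > 0, arr.ind = TRUE)  # patch, slot
  for (k in seq_len(fit$n_retained)) {
    expect_true(all(fit$z_draws[cbind(det[, 2], det[, 1], k)] == 1))
  }
  # richness bounded by observed and M
  rich <- derive_richness(fit)
  obs <- colSums(aug$Y_aug > 0)
  expect_true(all(rich$draws >= matrix(obs, nrow = fit$n_retained,
                                       ncol = 10, byrow = TRUE)))
  expect_true(all(rich$draws <= aug$M))
  expect_true(!is.null(fit$rhat) && all(is.finite(fit$rhat)))
})

test_that("near-perfect detection pins posterior richness to observed", {
  set.seed(24)
  land <- tiny_landscape(seed = 25, n_patches = 10, n_species = 25)
  svy <- sample_landscape(land, mu = 0.9, sigma = 0.1, V = 8)
  aug <- msom_data(svy)
  fit <- fit_msom(aug, land$patch_areas,
                  msom_control(chains = 2, iterations = 1500,
                               burn_in = 500, thin = 5))
  rich <- derive_richness(fit)
  obs <- observed_richness(svy)
  expect_lt(max(abs(rich$mean - obs)), 1)
})
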