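test_that("detection probabilities are logit-normal around logit(mu)", {
  expect_identical(draw_detection_probs(10, 0.2, 0), rep(0.2, 10))
  expect_error(draw_detection_probs(10, 0, 1), "mu")
  expect_error(draw_detection_probs(10, 1.2, 1), "mu")
  expect_error(draw_detection_probs(10, 0.5, -1), "sigma")

  # scenario S5: mu = 0.05, sigma = 1.0
  set.seed(8)
  th <- draw_detection_probs(2e5, 0.05, 1.0)
  lt <- qlogis(th)
  expect_lt(abs(mean(lt) - qlogis(0.05)), 4 * sd(lt) / sqrt(length(lt)))
  expect_lt(abs(sd(lt) - 1), 0.02)

  # logit symmetry at mu = 0.5: median converges to 0.5
  set.seed(9)
  th <- draw_detection_probs(2e5, 0.5, 3)
  expect_lt(abs(median(th) - 0.5), 0.02)
})

test_that("transect schedules sample less of larger patches", {
  s <- transect_schedule(25)
  expect_equal(s$transects, 1L)
  expect_equal(s$pi_p, 5.93 / 25)

  # capped-proportional regime: proportional below the cap, flat above
  expect_equal(transect_schedule(100)$transects, 4L)
  expect_equal(transect_schedule(20000)$transects, 16L)
  # the largest patch samples so little that a 100-individual
  # population becomes unavailable
  expect_lt(transect_schedule(20000)$pi_p, 0.005)
  expect_identical(as.integer(available_counts(
    matrix(100), transect_schedule(20000)$pi_p)), 0L)

  # power-law alternative
  expect_equal(transect_schedule(25 * 2^(4 / 3),
                                 schedule = "power")$transects, 2L)
  expect_equal(transect_schedule(25, schedule = "power")$transects, 1L)

  areas <- exp(seq(log(25), log(20000), length.out = 40))
  s <- transect_schedule(areas)
  expect_true(all(s$pi_p <= 1))
  # sampled area non-decreasing in patch area
  sampled <- s$transects * 5.93
  expect_true(all(diff(sampled) >= 0))
  # sampled proportion decreasing above the cap, and small patches
  # sampled proportionally hardest
  above <- areas > 16 * 25
  expect_true(all(diff(s$pi_p[above]) < 0))
  expect_lt(min(s$pi_p), 0.005)
  expect_equal(which.min(s$pi_p), 40L)   # largest patch least covered
  expect_gt(max(s$pi_p), 0.2)            # small patches most covered

  # lookup override
  lk <- data.frame(area = c(25, 20000), transects = c(2, 7))
  s <- transect_schedule(c(30, 19000), lookup = lk)
  expect_identical(s$transects, c(2L, 7L))
})

test_that("availability rounds half-up and clamps through pi", {
  n <- available_counts(matrix(100), 0.2372)
  expect_identical(as.integer(n), 24L)  # round(23.72)
  expect_identical(as.integer(available_counts(matrix(1), 0.3)), 0L)
  m <- matrix(c(0L, 7L, 120L, 3L), 2, 2)
  expect_identical(available_counts(m, c(1, 1)), m)
  # half-up, not banker's
  expect_identical(as.integer(available_counts(matrix(5), 0.5)), 3L)
})

test_that("surveys are independent binomial visits", {
  n <- matrix(c(3L, 0L, 10L, 2L), 2, 2)

  sv <- survey(n, theta = c(1, 1), V = 4)
  expect_true(all(sv$X == array(n, dim = c(2, 2, 4))))
  expect_identical(sv$pooled, n * 4L)
  expect_identical(sv$Y, matrix(as.integer((n > 0) * 4), 2, 2))

  sv0 <- survey(n, theta = c(0, 0), V = 4)
  expect_true(all(sv0$X == 0))

  # binomial moments: mean count over many visits ~ n * theta
  set.seed(10)
  sv <- survey(matrix(50L), theta = 0.3, V = 1e4)
  xbar <- mean(sv$X)
  se <- sqrt(50 * 0.3 * 0.7) / sqrt(1e4)
  expect_lt(abs(xbar - 50 * 0.3), 3 * se)

  # incidence bounds
  set.seed(11)
  sv <- survey(matrix(c(5L, 1L, 0L, 8L), 2, 2), theta = c(0.4, 0.9), V = 6)
  expect_true(all(sv$Y >= 0 & sv$Y <= 6))
  expect_identical(sv$pooled, matrix(as.integer(rowSums(sv$X, dims = 2)), 2, 2))
})

test_that("observed richness counts positive pooled species", {
  expect_identical(observed_richness(matrix(c(0, 3, 1, 0), 1, 4)), 2L)
  expect_identical(observed_richness(matrix(0, 1, 4)), 0L)
})

test_that("sampling never invents species and pooling is monotone", {
  land <- tiny_landscape(seed = 21)
  true_rich <- richness_from_matrix(land$N)
  for (seed in 1:3) {
    svy <- sample_landscape(land, mu = 0.05, sigma = 1, V = 6, seed = seed)
    obs <- observed_richness(svy)
    expect_true(all(obs <= true_rich))
    expect_true(all(svy$pooled[land$N == 0] == 0))
    # pooling over more visits never loses species
    for (p in seq_len(dim(svy$X)[1])) {
      xs <- matrix(svy$X[p, , ], ncol = svy$V)   # species x visits
      rich_k <- vapply(seq_len(svy$V), function(k) {
        sum(rowSums(xs[, seq_len(k), drop = FALSE]) > 0)
      }, 0L)
      expect_true(all(diff(rich_k) >= 0))
    }
  }
})

test_that("perfect detection recovers availability and true richness", {
  land <- tiny_landscape(seed = 22)
  svy <- sample_landscape(land, mu = 0.2, sigma = 1, V = 3, perfect = TRUE)
  expect_identical(svy$pooled, land$N * 3L)
  expect_identical(observed_richness(svy), richness_from_matrix(land$N))
})
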