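# Shared fixtures built in code.

# Small landscape for fast end-to-end tests (still uses the default
# area bounds so endpoint invariants hold).
tiny_landscape <- function(seed = 42, n_patches = 8, n_species = 30,
                           alpha_max = 8) {
  simulate_landscape(n_patches = n_patches, n_species = n_species,
                     alpha_max = alpha_max, seed = seed)
}

# Generative MSOM dataset: species coefficients drawn from known
# community hyperparameters, detections from the model itself.
simulate_msom_dataset <- function(n_species = 50, n_patches = 25, V = 6,
                                  mu_d0 = 0, mu_l0 = 0, mu_d1 = 0.5,
                                  s_d0 = 1, s_l0 = 1, s_d1 = 0.5,
                                  rho = 0) {
  areas <- draw_patch_areas(n_patches)
  x <- as.numeric(scale(log(areas)))
  l0 <- rnorm(n_species, mu_l0, s_l0)
  d0 <- mu_d0 + rho * s_d0 / s_l0 * (l0 - mu_l0) +
    rnorm(n_species, 0, s_d0 * sqrt(1 - rho^2))
  d1 <- rnorm(n_species, mu_d1, s_d1)
  psi <- plogis(d0 + outer(d1, x))
  z <- matrix(rbinom(n_species * n_patches, 1, psi), n_species, n_patches)
  theta <- plogis(l0)
  y <- matrix(rbinom(n_species * n_patches, V, z * theta),
              n_species, n_patches)
  list(y = y, areas = areas, x = x, V = V, z = z,
       truth = list(mu_d0 = mu_d0, mu_l0 = mu_l0, mu_d1 = mu_d1))
}

# Construct a minimal msom_fit-like object from a hand-built z array,
# for testing the derived-quantity functions in isolation.
fake_msom_fit <- function(z_draws) {
  structure(list(z_draws = z_draws), class = "msom_fit")
}
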