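# The six community parameters computed from any occurrence/abundance
# source (true or estimated): per-patch richness, SAR power-model
# coefficients (c, z), pairwise Sorensen similarity, and logit-link
# beta-diversity regression coefficients (gamma0, gamma1).

#' Per-patch species richness from a matrix
#'
#' Counts species with positive entries per patch; for a binary occurrence
#' matrix this is the row sum.
#'
#' @param m patches x species abundance or occurrence matrix.
#' @return integer vector of per-patch richness.
#' @export
richness_from_matrix <- function(m) {
  as.integer(rowSums(m > 0))
}

#' Pairwise plug-in Sorensen similarity
#'
#' `Sor(a, b) = 2 |A intersect B| / (|A| + |B|)` over the occurrence sets
#' of each pair of patches.  The diagonal is 1 for non-empty patches;
#' entries where both patches are empty are `NA`.
#'
#' @param m patches x species abundance or occurrence matrix (positive
#'   entries mark occurrence).
#' @return symmetric patches x patches similarity matrix in `[0, 1]`.
#' @export
sorensen_pairwise <- function(m) {
  occ <- (m > 0) * 1
  inter <- tcrossprod(occ)            # |A intersect B|
  rich <- rowSums(occ)
  denom <- outer(rich, rich, `+`)
  out <- 2 * inter / denom
  out[denom == 0] <- NA_real_
  diag(out) <- ifelse(rich > 0, 1, NA_real_)
  unname(out)
}

#' Fit a power-law species-area relationship
#'
#' Ordinary least squares of `ln(S_p)` on `ln(Area_p)` — the maximum
#' likelihood fit of the power model `S = c * Area^z` under log-normal
#' errors.  Patches with zero richness are dropped (with a warning), since
#' `ln(0)` is undefined and the power model has no zero-richness rule.
#'
#' @param richness per-patch richness (must align with `areas`).
#' @param areas per-patch areas (ha).
#' @return object of class `"sar_fit"`: list with `c_value` (intercept on
#'   the ln scale), `z_value` (slope), `n_patches_used`, and the `lm` fit.
#' @export
fit_sar <- function(richness, areas) {
  stopifnot(length(richness) == length(areas))
  use <- is.finite(richness) & richness > 0 & is.finite(areas) & areas > 0
  n_zero <- sum(is.finite(richness) & richness <= 0)
  if (n_zero > 0)
    warning(sprintf("dropping %d zero-richness patch(es) from SAR fit", n_zero))
  if (sum(use) < 3) stop("fewer than 3 usable patches for SAR fit")
  fit <- lm(log(richness[use]) ~ log(areas[use]))
  structure(list(c_value = unname(coef(fit)[1]),
                 z_value = unname(coef(fit)[2]),
                 n_patches_used = sum(use), fit = fit),
            class = "sar_fit")
}

#' @export
print.sar_fit <- function(x, ...) {
  cat(sprintf("SAR power model (ln-ln OLS): c = %.4f, z = %.4f (%d patches)\n",
              x$c_value, x$z_value, x$n_patches_used))
  invisible(x)
}

#' Fit the logit-link beta-diversity regression
#'
#' Models pairwise Sorensen similarity as a function of the log-transformed
#' pairwise absolute difference in patch area:
#' `logit(Sor_ab) = gamma0 + gamma1 * ln(|Area_a - Area_b| + 1)`, fitted as
#' a quasi-binomial GLM (Bernoulli-form quasi-likelihood on continuous
#' proportions, iteratively reweighted least squares) over all unordered
#' patch pairs.  Pairs with missing similarity are excluded and reflected
#' in `n_pairs`.
#'
#' @param similarity symmetric patches x patches similarity matrix.
#' @param areas per-patch areas (ha).
#' @return object of class `"beta_glm_fit"`: list with `gamma0`, `gamma1`,
#'   `n_pairs`, and the `glm` fit.
#' @export
fit_beta_glm <- function(similarity, areas) {
  p <- length(areas)
  stopifnot(nrow(similarity) == p, ncol(similarity) == p)
  idx <- which(upper.tri(similarity), arr.ind = TRUE)
  sim <- similarity[idx]
  d_area <- abs(areas[idx[, 1]] - areas[idx[, 2]])
  keep <- is.finite(sim)
  sim <- sim[keep]
  d_area <- d_area[keep]
  if (length(sim) < 3) stop("fewer than 3 usable patch pairs for beta GLM")
  if (all(sim == 0) || all(sim == 1))
    stop("degenerate similarity values: all 0 or all 1")
  x <- log(d_area + 1)
  fit <- suppressWarnings(glm(sim ~ x, family = quasibinomial(link = "logit")))
  if (!fit$converged) stop("beta GLM failed to converge")
  structure(list(gamma0 = unname(coef(fit)[1]), gamma1 = unname(coef(fit)[2]),
                 n_pairs = length(sim), fit = fit),
            class = "beta_glm_fit")
}

#' @export
print.beta_glm_fit <- function(x, ...) {
  cat(sprintf("Beta-diversity logit GLM: gamma0 = %.4f, gamma1 = %.4f (%d pairs)\n",
              x$gamma0, x$gamma1, x$n_pairs))
  invisible(x)
}

#' Compute all six community parameters from one source
#'
#' Parameter 1: per-patch richness; 2-3: SAR intercept (c) and slope (z);
#' 4: pairwise Sorensen matrix; 5-6: beta-GLM intercept (gamma0) and slope
#' (gamma1).  The source may be a true abundance matrix, a pooled-count
#' matrix, or precomputed richness/similarity (for estimator routes that
#' produce them directly).
#'
#' @param areas per-patch areas (ha).
#' @param m optional patches x species matrix from which richness and
#'   similarity are derived.
#' @param richness,similarity optional precomputed per-patch richness and
#'   pairwise similarity matrix, overriding `m`.
#' @return list with `richness`, `sorensen`, `c_value`, `z_value`,
#'   `gamma0`, `gamma1`, `sar_n`, `glm_n`.
#' @export
community_parameters <- function(areas, m = NULL, richness = NULL,
                                 similarity = NULL) {
  if (is.null(richness)) {
    stopifnot(!is.null(m))
    richness <- richness_from_matrix(m)
  }
  if (is.null(similarity)) {
    stopifnot(!is.null(m))
    similarity <- sorensen_pairwise(m)
  }
  sar <- fit_sar(richness, areas)
  bg <- fit_beta_glm(similarity, areas)
  list(richness = richness, sorensen = similarity,
       c_value = sar$c_value, z_value = sar$z_value,
       gamma0 = bg$gamma0, gamma1 = bg$gamma1,
       sar_n = sar$n_patches_used, glm_n = bg$n_pairs)
}
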