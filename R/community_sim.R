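# Fragmented-landscape community simulator: patch areas, metacommunity
# abundances, species-specific area responses, and capacity-constrained
# assignment of individuals to patches.

#' Four-parameter beta distribution specification
#'
#' Shape/bound container for the scaled beta distributions used to draw
#' patch areas and species area-response coefficients.
#'
#' @param alpha,beta shape parameters, both > 0.
#' @param min,max lower and upper bound of the support (`max > min`).
#' @return an object of class `"beta4"`.
#' @export
beta4 <- function(alpha, beta, min, max) {
  stopifnot(alpha > 0, beta > 0, max > min)
  structure(list(alpha = alpha, beta = beta, min = min, max = max),
            class = "beta4")
}

#' @export
print.beta4 <- function(x, ...) {
  cat(sprintf("Beta4(alpha = %g, beta = %g, min = %g, max = %g)\n",
              x$alpha, x$beta, x$min, x$max))
  invisible(x)
}

#' Draw from a four-parameter beta distribution
#'
#' @param n number of draws.
#' @param params a [beta4()] specification.
#' @return numeric vector in `[params$min, params$max]`.
#' @export
rbeta4 <- function(n, params) {
  stopifnot(inherits(params, "beta4"))
  params$min + (params$max - params$min) * rbeta(n, params$alpha, params$beta)
}

#' Draw patch areas for a fragmented landscape
#'
#' The smallest and largest patches are pre-assigned the distribution
#' bounds (25 and 20,000 ha under defaults, spanning the area range typical
#' of fragmented tropical-forest landscapes); the remaining `n_patches - 2`
#' areas are drawn from the four-parameter beta distribution, whose default
#' shapes (1, 4) give the negative power-law frequency-area profile seen in
#' real fragment size distributions.
#'
#' @param n_patches number of patches (>= 2).
#' @param params a [beta4()] specification; default
#'   `beta4(1, 4, 25, 20000)`.
#' @return numeric vector of areas (ha), sorted ascending.
#' @export
draw_patch_areas <- function(n_patches, params = beta4(1, 4, 25, 20000)) {
  if (n_patches < 2) stop("n_patches must be at least 2")
  free <- if (n_patches > 2) rbeta4(n_patches - 2, params) else numeric(0)
  sort(c(params$min, params$max, free))
}

#' Simulate a metacommunity species abundance distribution
#'
#' Draws relative abundances from a log-normal species abundance
#' distribution (SAD), allocates `round(total_area)` individuals to
#' species proportionally (largest-remainder rounding with a floor of one
#' individual per species), and inflates every abundance by `inflation`.
#' With the default inflation of 500 this guarantees a minimum viable
#' landscape-level population of 500 individuals per species and an overall
#' density of 500 individuals per hectare.
#'
#' The SAD is parameterised on the log scale (`meanlog`, `sdlog`); only its
#' shape matters because abundances are rescaled to a fixed total.
#'
#' @param n_species number of species.
#' @param total_area total landscape area in ha; sets the pre-inflation
#'   individual count.
#' @param meanlog,sdlog log-scale location and scale of the SAD.
#' @param inflation abundance multiplier applied after allocation.
#' @return object of class `"metacommunity"`: list with `abundances`
#'   (integer vector) and `n_species`.
#' @export
simulate_metacommunity <- function(n_species = 200, total_area,
                                   meanlog = log(650), sdlog = log(3),
                                   inflation = 500) {
  stopifnot(n_species >= 1, total_area > 0)
  n_ind <- round(total_area)
  if (n_ind < n_species)
    stop("round(total_area) must be >= n_species to allocate >=1 individual each")
  rel <- if (sdlog > 0) rlnorm(n_species, meanlog, sdlog) else
    rep(exp(meanlog), n_species)
  alloc <- allocate_largest_remainder(n_ind, rel, floor_each = 1L)
  structure(list(abundances = alloc * as.integer(inflation),
                 n_species = n_species,
                 inflation = inflation, n_individuals = n_ind),
            class = "metacommunity")
}

# Largest-remainder apportionment of `total` units proportional to `weights`,
# with a minimum of `floor_each` units per class.
allocate_largest_remainder <- function(total, weights, floor_each = 1L) {
  k <- length(weights)
  quota <- total * weights / sum(weights)
  alloc <- pmax(as.integer(floor_each), as.integer(floor(quota)))
  frac <- quota - floor(quota)
  d <- total - sum(alloc)
  if (d > 0) {
    idx <- order(frac, decreasing = TRUE)[seq_len(d)]
    alloc[idx] <- alloc[idx] + 1L
  } else if (d < 0) {
    # floors pushed the total over: take back from classes with spare units,
    # smallest fractional remainder first
    idx <- order(frac)
    for (i in idx) {
      if (d == 0) break
      take <- min(alloc[i] - as.integer(floor_each), -d)
      if (take > 0) {
        alloc[i] <- alloc[i] - take
        d <- d + take
      }
    }
    if (d != 0) stop("cannot satisfy per-class floor with given total")
  }
  alloc
}

#' @export
print.metacommunity <- function(x, ...) {
  cat(sprintf("Metacommunity: %d species, %d individuals (min %d, max %d)\n",
              x$n_species, sum(x$abundances), min(x$abundances),
              max(x$abundances)))
  invisible(x)
}

#' Draw species-specific area-response coefficients
#'
#' Each species i receives an area-response coefficient
#' `beta_area_i = 5 * Beta(alpha_i, beta_shape)`, where the first shape
#' parameter `alpha_i` ramps linearly over `[0.1, alpha_max]` in inverse
#' proportion to abundance rank: the most abundant species gets
#' `alpha_i = 0.1` (weak, near-zero expected response) and the rarest gets
#' `alpha_max` (strong expected response).  A uniformly random eighth of
#' the species has its coefficient negated, yielding negative area
#' responses.
#'
#' @param metacommunity a [simulate_metacommunity()] result (or a bare
#'   abundance vector).
#' @param alpha_max upper end of the `alpha_i` ramp (> 0.1); larger values
#'   steepen the realised species-area relationship.
#' @param beta_shape second shape parameter, shared across species.
#' @param b_max upper bound of the coefficient magnitude.
#' @param neg_fraction fraction of species with negated response.
#' @return object of class `"area_responses"`: list with `beta_area`,
#'   `alpha_i`, `sign_flipped` (indices).
#' @export
draw_area_responses <- function(metacommunity, alpha_max, beta_shape = 5,
                                b_max = 5, neg_fraction = 1 / 8) {
  ab <- if (inherits(metacommunity, "metacommunity"))
    metacommunity$abundances else metacommunity
  if (alpha_max <= 0.1) stop("alpha_max must exceed 0.1")
  s <- length(ab)
  # rank 1 = most abundant; ties broken by species index
  ord <- order(-ab, seq_len(s))
  rank_pos <- integer(s)
  rank_pos[ord] <- seq_len(s)
  alpha_i <- if (s > 1) 0.1 + (rank_pos - 1) / (s - 1) * (alpha_max - 0.1)
             else rep(0.1, s)
  beta_area <- b_max * rbeta(s, alpha_i, beta_shape)
  n_neg <- round(s * neg_fraction)
  flipped <- if (n_neg > 0) sort(sample.int(s, n_neg)) else integer(0)
  beta_area[flipped] <- -beta_area[flipped]
  structure(list(beta_area = beta_area, alpha_i = alpha_i,
                 sign_flipped = flipped),
            class = "area_responses")
}

#' Patch-assignment probabilities for one species
#'
#' Assignment weight `W_p = Area_p ^ beta_i` (equivalently
#' `exp(beta_i * ln(Area_p))`), normalised to the probability vector
#' `phi_p = W_p / sum(W)`.
#'
#' @param patch_areas vector of patch areas (> 0).
#' @param beta_i the species' area-response coefficient.
#' @return probability vector summing to one.
#' @export
assignment_probs <- function(patch_areas, beta_i) {
  stopifnot(all(patch_areas > 0))
  w <- patch_areas^beta_i
  tot <- sum(w)
  if (!is.finite(tot) || tot <= 0)
    stop("assignment weights have empty or non-finite support")
  w / tot
}

#' Assign metacommunity individuals to patches under carrying capacities
#'
#' Individuals are placed in groups of `group_size` (the final group of a
#' species may be smaller), guaranteeing minimum viable patch-level
#' populations.  All (species, group) units are shuffled globally, then
#' each group's patch is drawn by weighted sampling with the species'
#' assignment probabilities restricted to non-full patches.  A patch is
#' declared full once its assigned total reaches its (rounded) carrying
#' capacity, so each patch may overshoot its capacity by at most one group.
#'
#' @param metacommunity a [simulate_metacommunity()] result.
#' @param patch_areas vector of patch areas (ha).
#' @param responses a [draw_area_responses()] result.
#' @param density individuals per ha; sets capacity `K_p = density * Area_p`.
#' @param group_size individuals per assignment group.
#' @return integer matrix `N` (patches x species) of true abundances.
#' @export
assign_individuals <- function(metacommunity, patch_areas, responses,
                               density = 500, group_size = 100) {
  ab <- metacommunity$abundances
  s <- length(ab)
  stopifnot(length(responses$beta_area) == s, all(patch_areas > 0))
  cap <- round(density * patch_areas)
  if (sum(ab) > sum(cap) + group_size * length(cap))
    stop("total individuals exceed total carrying capacity beyond tolerance")
  # per-species group sizes: full groups then a (possibly smaller) remainder
  n_full <- ab %/% group_size
  remn <- ab %% group_size
  unit_species <- c(rep.int(seq_len(s), n_full), which(remn > 0))
  unit_size <- c(rep.int(as.integer(group_size), sum(n_full)),
                 as.integer(remn[remn > 0]))
  perm <- sample.int(length(unit_species))
  w <- exp(responses$beta_area %o% log(patch_areas))  # species x patches
  n <- assign_groups_cpp(unit_species[perm] - 1L, unit_size[perm], w,
                         as.numeric(cap))
  stopifnot(all(as.integer(colSums(n)) == as.integer(ab)))
  n
}

#' Simulate one fragmented-landscape community
#'
#' End-to-end generator: patch areas, metacommunity, area responses and the
#' patch-by-species true abundance matrix, under the default stated world
#' (25 patches spanning 25-20,000 ha, 200 species, log-normal SAD, density
#' 500 individuals per ha).
#'
#' @param n_patches,n_species landscape dimensions.
#' @param alpha_max area-response ramp maximum (4, 8 or 12 in the factorial
#'   design).
#' @param area_params [beta4()] spec for patch areas.
#' @param meanlog,sdlog SAD parameters on the log scale.
#' @param density individuals per ha (also the abundance inflation factor).
#' @param group_size assignment group size.
#' @param seed optional integer seed (recorded in the result).
#' @return object of class `"landscape"`: list with `patch_areas`,
#'   `capacities`, `total_area`, `metacommunity`, `responses`, `N`
#'   (patches x species abundance matrix) and `seed`.
#' @export
simulate_landscape <- function(n_patches = 25, n_species = 200,
                               alpha_max = 8,
                               area_params = beta4(1, 4, 25, 20000),
                               meanlog = log(650), sdlog = log(3),
                               density = 500, group_size = 100,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  areas <- draw_patch_areas(n_patches, area_params)
  meta <- simulate_metacommunity(n_species, total_area = sum(areas),
                                 meanlog = meanlog, sdlog = sdlog,
                                 inflation = density)
  resp <- draw_area_responses(meta, alpha_max = alpha_max)
  n <- assign_individuals(meta, areas, resp, density = density,
                          group_size = group_size)
  structure(list(patch_areas = areas, capacities = round(density * areas),
                 total_area = sum(areas), metacommunity = meta,
                 responses = resp, N = n, alpha_max = alpha_max,
                 density = density, seed = seed),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf(
    "Fragmented landscape: %d patches (%.0f-%.0f ha), %d species, %d individuals\n",
    length(x$patch_areas), min(x$patch_areas), max(x$patch_areas),
    x$metacommunity$n_species, sum(x$N)))
  cat(sprintf("  alpha_max = %g, density = %g individuals/ha\n",
              x$alpha_max, x$density))
  invisible(x)
}
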