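# Delimited-text readers/writers for the intermediate artifacts:
# landscape tables, abundance matrices, survey long tables, and metadata
# sidecars.

#' Write a simulated landscape to delimited text
#'
#' Emits `landscape.tsv` (patch_id, area_ha, capacity), `species.tsv`
#' (species_id, abundance, alpha_i, beta_area), `abundance.tsv`
#' (patches x species matrix with header) and `metadata.json` (seed and
#' parameters).
#'
#' @param landscape a [simulate_landscape()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, f) write.table(d, file.path(dir, f), sep = "\t",
                                    row.names = FALSE, quote = FALSE)
  tsv(data.frame(patch_id = seq_along(landscape$patch_areas),
                 area_ha = landscape$patch_areas,
                 capacity = landscape$capacities), "landscape.tsv")
  tsv(data.frame(species_id = seq_len(landscape$metacommunity$n_species),
                 abundance = landscape$metacommunity$abundances,
                 alpha_i = landscape$responses$alpha_i,
                 beta_area = landscape$responses$beta_area), "species.tsv")
  ab <- as.data.frame(landscape$N)
  names(ab) <- paste0("sp", seq_len(ncol(ab)))
  tsv(ab, "abundance.tsv")
  jsonlite::write_json(
    list(seed = landscape$seed, alpha_max = landscape$alpha_max,
         density = landscape$density, total_area = landscape$total_area,
         n_patches = length(landscape$patch_areas),
         n_species = landscape$metacommunity$n_species),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a landscape written by [write_landscape()]
#'
#' @param dir directory holding the landscape tables.
#' @return a `"landscape"`-like list with `patch_areas`, `capacities`,
#'   `N`, `metacommunity`, `responses`, plus metadata.
#' @export
read_landscape <- function(dir) {
  land <- read.table(file.path(dir, "landscape.tsv"), header = TRUE)
  spp <- read.table(file.path(dir, "species.tsv"), header = TRUE)
  ab <- as.matrix(read.table(file.path(dir, "abundance.tsv"), header = TRUE))
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  structure(list(patch_areas = land$area_ha, capacities = land$capacity,
                 total_area = sum(land$area_ha),
                 metacommunity = structure(
                   list(abundances = spp$abundance, n_species = nrow(spp)),
                   class = "metacommunity"),
                 responses = structure(
                   list(beta_area = spp$beta_area, alpha_i = spp$alpha_i,
                        sign_flipped = which(spp$beta_area < 0)),
                   class = "area_responses"),
                 N = unname(ab), alpha_max = meta$alpha_max,
                 density = meta$density, seed = meta$seed),
            class = "landscape")
}

#' Write survey data to delimited text
#'
#' Emits `counts_long.tsv` (patch_id, species_id, visit, count),
#' `pooled.tsv`, `incidence.tsv` and `metadata.json` (mu, sigma, V, seed).
#'
#' @param svy a [survey()] / [sample_landscape()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(svy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(svy$X)
  long <- data.frame(patch_id = rep(seq_len(d[1]), times = d[2] * d[3]),
                     species_id = rep(rep(seq_len(d[2]), each = d[1]),
                                      times = d[3]),
                     visit = rep(seq_len(d[3]), each = d[1] * d[2]),
                     count = as.vector(svy$X))
  long <- long[long$count > 0, ]  # sparse long format
  tsv <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                    row.names = FALSE, quote = FALSE)
  tsv(long, "counts_long.tsv")
  pooled <- as.data.frame(svy$pooled)
  names(pooled) <- paste0("sp", seq_len(ncol(pooled)))
  tsv(pooled, "pooled.tsv")
  inc <- as.data.frame(svy$Y)
  names(inc) <- paste0("sp", seq_len(ncol(inc)))
  tsv(inc, "incidence.tsv")
  jsonlite::write_json(
    list(V = svy$V, mu = svy$mu, sigma = svy$sigma, seed = svy$seed,
         n_patches = d[1], n_species = d[2]),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read survey data written by [write_survey()]
#'
#' @param dir directory holding the survey tables.
#' @return a `"survey_data"` object.
#' @export
read_survey <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  long <- read.table(file.path(dir, "counts_long.tsv"), header = TRUE)
  x <- array(0L, dim = c(meta$n_patches, meta$n_species, meta$V))
  x[cbind(long$patch_id, long$species_id, long$visit)] <- long$count
  pooled <- matrix(as.integer(rowSums(x, dims = 2)),
                   meta$n_patches, meta$n_species)
  y <- matrix(as.integer(rowSums(x > 0, dims = 2)),
              meta$n_patches, meta$n_species)
  structure(list(X = x, pooled = pooled, Y = y, V = as.integer(meta$V),
                 mu = meta$mu, sigma = meta$sigma, seed = meta$seed),
            class = "survey_data")
}

#' Write an experiment performance table
#'
#' @param result an [run_experiment()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_performance <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(result$performance, file.path(dir, "performance.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(result$raw))
    write.table(result$raw, file.path(dir, "raw_estimates.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- result$config
  jsonlite::write_json(
    list(profile = cfg$profile, master_seed = cfg$master_seed,
         mu_grid = cfg$mu_grid, sigma_grid = cfg$sigma_grid,
         alpha_max_grid = cfg$alpha_max_grid, V_grid = cfg$V_grid,
         communities_per_combo = cfg$communities_per_combo,
         sampling_reps_per_community = cfg$sampling_reps_per_community,
         methods = cfg$methods, failures = result$failures,
         package_version = as.character(utils::packageVersion("fragsar"))),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
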