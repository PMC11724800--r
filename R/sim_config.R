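#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator: population design
#' (heterotic pools, founders, biparental families, line derivation), the
#' marker map, the sparse factorial, trait variance components, and the
#' spectral emulation profiles.
#'
#' @param pools labels of the two heterotic pools.
#' @param founders_per_pool number of founder lines per pool.
#' @param families_per_pool number of biparental families per pool; families
#'   are distinct founder pairs, so at most `choose(founders_per_pool, 2)`.
#' @param lines_per_family inbred lines derived per family.
#' @param derivation `"DH"` (doubled haploids: one meiosis then doubling) or
#'   `"SSD"` (single-seed descent selfing from the F1).
#' @param n_selfing_generations selfing generations for `"SSD"`.
#' @param n_chromosomes,markers_per_chromosome marker map dimensions.
#' @param map_length genetic length of each chromosome in centimorgans.
#' @param founder_freq_range range from which per-marker founder allele
#'   frequencies are drawn.
#' @param hybrids_per_parent target number of crosses each parent enters.
#' @param n_traits number of hybrid traits.
#' @param var_gca_dent,var_gca_flint,var_sca,var_error per-trait variance
#'   components of the hybrid phenotypes.
#' @param wavelength_grid ordered wavelengths (nm) of the simulated spectra.
#' @param h2_profile per-wavelength genetic proportion of spectral variance,
#'   in `[0, 1]`, recycled to the grid length if scalar.
#' @param gxe_profile per-wavelength genotype-by-trial proportion, same rules;
#'   `h2_profile + gxe_profile` must not exceed 1 anywhere.
#' @param n_trials number of spectra trials (environments).
#' @param smooth_width moving-average width (wavelength points) used to make
#'   marker loadings and residual noise smooth along the grid.
#' @param seed master seed; all generator stages derive child seeds from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [sim_config_maize()] for the default maize emulation preset.
#' @export
sim_config <- function(pools = c("dent", "flint"),
                       founders_per_pool = 4L,
                       families_per_pool = 6L,
                       lines_per_family = 15L,
                       derivation = c("DH", "SSD"),
                       n_selfing_generations = 5L,
                       n_chromosomes = 5L,
                       markers_per_chromosome = 60L,
                       map_length = 120,
                       founder_freq_range = c(0.2, 0.8),
                       hybrids_per_parent = 4L,
                       n_traits = 1L,
                       var_gca_dent = 1,
                       var_gca_flint = 1,
                       var_sca = 0.25,
                       var_error = 1,
                       wavelength_grid = seq(400, 2490, by = 14),
                       h2_profile = 0.5,
                       gxe_profile = 0.2,
                       n_trials = 2L,
                       smooth_width = 11L,
                       seed = 1L) {
  derivation <- match.arg(derivation)
  cfg <- list(
    pools = as.character(pools),
    founders_per_pool = as.integer(founders_per_pool),
    families_per_pool = as.integer(families_per_pool),
    lines_per_family = as.integer(lines_per_family),
    derivation = derivation,
    n_selfing_generations = as.integer(n_selfing_generations),
    n_chromosomes = as.integer(n_chromosomes),
    markers_per_chromosome = as.integer(markers_per_chromosome),
    map_length = as.numeric(map_length),
    founder_freq_range = as.numeric(founder_freq_range),
    hybrids_per_parent = as.integer(hybrids_per_parent),
    n_traits = as.integer(n_traits),
    var_gca_dent = as.numeric(var_gca_dent),
    var_gca_flint = as.numeric(var_gca_flint),
    var_sca = as.numeric(var_sca),
    var_error = as.numeric(var_error),
    wavelength_grid = as.numeric(wavelength_grid),
    h2_profile = as.numeric(h2_profile),
    gxe_profile = as.numeric(gxe_profile),
    n_trials = as.integer(n_trials),
    smooth_width = as.integer(smooth_width),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (length(cfg$pools) != 2L || anyDuplicated(cfg$pools)) {
    cfg_stop("exactly two distinct pool labels are required")
  }
  counts <- c(founders_per_pool = cfg$founders_per_pool,
              families_per_pool = cfg$families_per_pool,
              lines_per_family = cfg$lines_per_family,
              n_chromosomes = cfg$n_chromosomes,
              markers_per_chromosome = cfg$markers_per_chromosome,
              hybrids_per_parent = cfg$hybrids_per_parent,
              n_traits = cfg$n_traits,
              n_trials = cfg$n_trials)
  bad <- counts <= 0L | is.na(counts)
  if (any(bad)) {
    cfg_stop("counts must be positive: ", paste(names(counts)[bad], collapse = ", "))
  }
  if (cfg$families_per_pool > choose(cfg$founders_per_pool, 2)) {
    cfg_stop("families_per_pool exceeds the number of distinct founder pairs")
  }
  if (!is.finite(cfg$map_length) || cfg$map_length <= 0) {
    cfg_stop("map_length must be > 0")
  }
  if (length(cfg$founder_freq_range) != 2L ||
      any(cfg$founder_freq_range <= 0) || any(cfg$founder_freq_range >= 1) ||
      diff(cfg$founder_freq_range) < 0) {
    cfg_stop("founder_freq_range must be an increasing pair inside (0, 1)")
  }
  vars <- c(cfg$var_gca_dent, cfg$var_gca_flint, cfg$var_sca, cfg$var_error)
  if (any(vars < 0) || any(is.na(vars))) cfg_stop("variances must be >= 0")
  L <- length(cfg$wavelength_grid)
  if (L < 2L || is.unsorted(cfg$wavelength_grid, strictly = TRUE)) {
    cfg_stop("wavelength_grid must be strictly increasing, length >= 2")
  }
  for (nm in c("h2_profile", "gxe_profile")) {
    p <- cfg[[nm]]
    if (length(p) == 1L) cfg[[nm]] <- p <- rep(p, L)
    if (length(p) != L) cfg_stop(nm, " must have length 1 or length(wavelength_grid)")
    if (any(p < 0) || any(p > 1)) cfg_stop(nm, " must lie in [0, 1]")
  }
  if (any(cfg$h2_profile + cfg$gxe_profile > 1 + 1e-12)) {
    cfg_stop("h2_profile + gxe_profile must be <= 1 at every wavelength")
  }
  if (cfg$derivation == "SSD" && cfg$n_selfing_generations < 1L) {
    cfg_stop("SSD derivation needs n_selfing_generations >= 1")
  }
  cfg
}

#' Maize hybrid study emulation preset
#'
#' Default configuration mirroring the structure of a dent x flint maize
#' factorial: two heterotic pools, each with six biparental families derived
#' from four founders (doubled haploids on the dent side, five selfing
#' generations on the flint side are emulated with DH for both by default),
#' 90 lines per pool, and a sparse factorial in which each parent enters
#' about four crosses, giving roughly 360 hybrids.
#'
#' @param seed master seed.
#' @param ... overrides passed on to [sim_config()].
#' @return a `sim_config`.
#' @export
sim_config_maize <- function(seed = 1L, ...) {
  sim_config(
    pools = c("dent", "flint"),
    founders_per_pool = 4L,
    families_per_pool = 6L,
    lines_per_family = 15L,
    derivation = "DH",
    n_chromosomes = 10L,
    markers_per_chromosome = 40L,
    map_length = 150,
    hybrids_per_parent = 4L,
    var_gca_dent = 1,
    var_gca_flint = 1,
    var_sca = 0.25,
    var_error = 1,
    seed = seed,
    ...
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  pools: %s | %d founders -> %d families x %d lines (%s)\n",
              paste(x$pools, collapse = "/"), x$founders_per_pool,
              x$families_per_pool, x$lines_per_family, x$derivation))
  cat(sprintf("  map: %d chrom x %d markers, %.0f cM\n",
              x$n_chromosomes, x$markers_per_chromosome, x$map_length))
  cat(sprintf("  factorial: ~%d hybrids/parent; traits: %d; trials: %d; seed %d\n",
              x$hybrids_per_parent, x$n_traits, x$n_trials, x$seed))
  invisible(x)
}
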