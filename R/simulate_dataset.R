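#' Simulate a complete hybrid prediction dataset
#'
#' Orchestrates the generator end to end: founder genomes, two heterotic
#' pools of biparental families, a sparse factorial, hybrid phenotypes with
#' GCA/SCA structure, and (optionally) multi-trial spectra for each pool.
#' Every stage is seeded from `cfg$seed`, so the whole bundle is a pure
#' function of the configuration.
#'
#' @param cfg a [sim_config()] (see [sim_config_maize()] for the default
#'   maize-like preset).
#' @param spectra also simulate parental spectra for both pools?
#' @param layout simulate plot-level spectra with a field layout (see
#'   [simulate_spectra()]).
#' @return list with `founders`, `dent`, `flint` ([geno_matrix()]),
#'   `design` ([factorial_design()]), `phenotypes` (long data.frame) and,
#'   if requested, `spectra` (list by pool).
#' @export
simulate_dataset <- function(cfg = sim_config_maize(), spectra = FALSE,
                             layout = FALSE) {
  cfg <- validate_sim_config(cfg)
  founders <- simulate_founder_genomes(cfg)
  dent <- simulate_pool(founders, cfg$pools[1L], cfg, seed = child_seed(cfg$seed, 2L))
  flint <- simulate_pool(founders, cfg$pools[2L], cfg, seed = child_seed(cfg$seed, 102L))
  design <- simulate_factorial(dent, flint, cfg)
  phenotypes <- simulate_hybrid_phenotypes(design, dent, flint, cfg)
  out <- list(cfg = cfg, founders = founders, dent = dent, flint = flint,
              design = design, phenotypes = phenotypes)
  if (spectra) {
    out$spectra <- list(
      dent = simulate_spectra(dent, cfg, seed = child_seed(cfg$seed, 5L), layout = layout),
      flint = simulate_spectra(flint, cfg, seed = child_seed(cfg$seed, 105L), layout = layout)
    )
  }
  out
}

#' Build the standard kernel bundle from a simulated dataset
#'
#' Convenience wrapper used by the analysis drivers: VanRaden GCA kinships
#' per pool, the SCA product kernel, unit-variance scaling and PSD repair.
#'
#' @param dat a [simulate_dataset()] result (or a list with `dent`,
#'   `flint`, `design`).
#' @param scale scale all kernels to unit entry variance?
#' @param min_maf per-pool minor-allele-frequency filter applied before the
#'   kinship (markers monomorphic within a pool carry no GCA information).
#' @return list with `dent`, `flint`, `sca` [kernel_matrix()] objects.
#' @export
genomic_kernel_bundle <- function(dat, scale = TRUE, min_maf = 0.05) {
  kd <- vanraden_gca_kinship(impute_missing(filter_markers(dat$dent, min_maf = min_maf)))
  kf <- vanraden_gca_kinship(impute_missing(filter_markers(dat$flint, min_maf = min_maf)))
  ks <- sca_kernel(kd, kf, dat$design)
  finish <- function(k) ensure_psd(if (scale) scale_unit_variance(k) else k)
  list(dent = finish(kd), flint = finish(kf), sca = finish(ks))
}

#' Spectral kernel bundle from parental spectra
#'
#' Runs the pretreatment chain (normalize, Savitzky-Golay first derivative)
#' on each pool's adjusted spectra for one trial, builds the H matrices and
#' the spectral SCA kernel, then scales and repairs them.
#'
#' @param spectra_dent,spectra_flint [spectra_set()] objects in state
#'   `"adjusted"`; `spectra_flint` may be `NULL` (origin without flint
#'   spectra: only the dent GCA kernel is returned).
#' @param design a [factorial_design()].
#' @param trial which trial's spectra to use.
#' @param window,polyorder Savitzky-Golay parameters.
#' @param scale scale kernels to unit entry variance?
#' @return list with `dent` and, when flint spectra are given, `flint` and
#'   `sca` kernels.
#' @export
spectral_kernel_bundle <- function(spectra_dent, spectra_flint, design,
                                   trial = NULL, window = 37L, polyorder = 2L,
                                   scale = TRUE) {
  pretreat <- function(s, role) {
    if (!is.null(trial)) {
      keep <- s$meta$trial_id == trial
      s <- spectra_set(s$values[keep, , drop = FALSE], s$wavelengths,
                       s$meta[keep, , drop = FALSE], state = s$state)
    }
    d <- savitzky_golay_first_derivative(normalize_spectra(s), window, polyorder)
    spectral_relationship(d, role = role)
  }
  finish <- function(k) ensure_psd(if (scale) scale_unit_variance(k) else k)
  hd <- pretreat(spectra_dent, "GCA_dent")
  if (is.null(spectra_flint)) return(list(dent = finish(hd)))
  hf <- pretreat(spectra_flint, "GCA_flint")
  hs <- sca_kernel(hd, hf, design)
  list(dent = finish(hd), flint = finish(hf), sca = finish(hs))
}
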