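#!/usr/bin/env Rscript

# Stage 1: simulate the study population.
#
# Two heterotic pools (dent, flint), each bred as six biparental families
# from four founders (90 inbred lines per pool), crossed in a sparse
# factorial where every parent enters about four hybrids (~360 hybrids).
# Hybrid adjusted means carry GCA + SCA + error structure
# (1 : 1 : 0.25 : 1 variance ratio), and both pools get two-trial parental
# NIR spectra with wavelength-varying heritability and GxE.

suppressMessages(library(hybridps))

seed <- 2026L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config_maize(
  seed = seed,
  # stepped genetic profile and moderate GxE along the grid, emulating the
  # strong wavelength dependence of spectral heritability
  wavelength_grid = seq(400, 2490, by = 14),
  h2_profile = rep(c(0.05, 0.45, 0.85), length.out = 150),
  gxe_profile = 0.1,
  n_trials = 2L
)

dat <- simulate_dataset(cfg, spectra = TRUE)

audit <- attr(dat$design, "degree_audit")
message(sprintf("simulated %d hybrids from %d x %d parents (degrees %d-%d)",
                nrow(dat$design$hybrids), nrow(dat$dent$geno),
                nrow(dat$flint$geno), audit$dent_range[1], audit$dent_range[2]))
comp <- attr(dat$phenotypes, "components")
message(sprintf("realized variance parts: GCAd %.2f, GCAf %.2f, SCA %.2f, error %.2f",
                comp[1, "gca_d"], comp[1, "gca_f"], comp[1, "sca"], comp[1, "error"]))

write_genotypes(dat$dent, file.path(out, "genotypes_dent.csv"))
write_genotypes(dat$flint, file.path(out, "genotypes_flint.csv"))
write_design(dat$design, file.path(out, "design.csv"))
write_phenotypes(dat$phenotypes, file.path(out, "phenotypes.csv"))
write_spectra(dat$spectra$dent, file.path(out, "spectra_dent.csv"))
write_spectra(dat$spectra$flint, file.path(out, "spectra_flint.csv"))

message("wrote simulated bundle to ", out)
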