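#!/usr/bin/env Rscript

# Stage 2: spectra preprocessing.
#
# Demonstrates the full pretreatment chain on plot-level spectra with a
# field layout (technical-spot averaging, per-wavelength spatial adjustment
# with row/column random effects, broad-sense heritability), then runs the
# chemometric pretreatment (SNV normalization + Savitzky-Golay first
# derivative, window 37, order 2) on the genotype-level spectra of stage 1.

suppressMessages(library(hybridps))

data_dir <- "results/data"
out <- "results"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## plot-level demonstration on a reduced grid (the spatial model is fitted
## per wavelength; 40 wavelengths keep this stage quick)
cfg_plot <- sim_config_maize(seed = 4097L, n_trials = 1L,
                             wavelength_grid = seq(1000, 1390, by = 10),
                             h2_profile = 0.6, gxe_profile = 0)
founders <- simulate_founder_genomes(cfg_plot)
dent <- simulate_pool(founders, "dent", cfg_plot)
raw <- simulate_spectra(dent, cfg_plot, seed = 4098L, layout = TRUE, n_tech = 2)
message(sprintf("raw spectra: %d technical spectra on %d plots",
                nrow(raw$values), length(unique(raw$meta$plot_id))))

plots <- average_technical_replicates(raw)
adj <- adjust_wavelength_means(plots)
h2_tab <- data.frame(wavelength = adj$spectra$wavelengths, H2 = adj$h2)
utils::write.table(h2_tab, file.path(out, "broad_sense_h2_plotlevel.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
message(sprintf("spatially adjusted means for %d genotypes; mean plot-level H2 = %.2f",
                nrow(adj$spectra$values), mean(adj$h2, na.rm = TRUE)))

## pretreat the stage-1 genotype-level spectra (both pools, both trials)
for (pool in c("dent", "flint")) {
  sp <- read_spectra(file.path(data_dir, sprintf("spectra_%s.csv", pool)))
  for (trial in unique(sp$meta$trial_id)) {
    keep <- sp$meta$trial_id == trial
    s <- spectra_set(sp$values[keep, , drop = FALSE], sp$wavelengths,
                     sp$meta[keep, , drop = FALSE], state = sp$state)
    d <- savitzky_golay_first_derivative(normalize_spectra(s))
    write_spectra(d, file.path(data_dir,
                               sprintf("pretreated_%s_%s.csv", pool, trial)))
  }
}
message("pretreated spectra written (first derivative of SNV-normalized means)")
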