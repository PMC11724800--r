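#!/usr/bin/env Rscript

# Stage 4: genomic heritability of the spectra.
#
# Decomposes the per-wavelength variance of the parental spectra into
# genetic, genotype-by-trial and residual parts with the bivariate
# polygenic model (both trials), separately per pool, and contrasts it
# with the univariate scan on a single trial (where GxE is not estimable).

suppressMessages(library(hybridps))

data_dir <- "results/data"
out <- "results"

split_trial <- function(s, tr) {
  keep <- s$meta$trial_id == tr
  spectra_set(s$values[keep, , drop = FALSE], s$wavelengths,
              s$meta[keep, , drop = FALSE], state = s$state)
}

for (pool in c("dent", "flint")) {
  g <- read_genotypes(file.path(data_dir, sprintf("genotypes_%s.csv", pool)))
  K <- vanraden_gca_kinship(impute_missing(filter_markers(g)))
  sp <- read_spectra(file.path(data_dir, sprintf("spectra_%s.csv", pool)))
  scan <- scan_bivariate(split_trial(sp, "trial1"), split_trial(sp, "trial2"),
                         K, pool = pool, tissue = "leaf")
  utils::write.table(scan, file.path(out, sprintf("heritability_scan_%s.tsv", pool)),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  s <- summarize_scan(scan)
  message(sprintf(
    "%s: mean genetic %.1f%%, GxE %.1f%%, residual %.1f%% over %d/%d wavelengths (genetic range %.2f-%.2f)",
    pool, 100 * s$mean_proportions["G"], 100 * s$mean_proportions["GxE"],
    100 * s$mean_proportions["e"], s$n_converged, s$n_wavelengths,
    s$range_prop_G[1], s$range_prop_G[2]))
}

## univariate comparison on the dent pool, trial 1 only
g <- read_genotypes(file.path(data_dir, "genotypes_dent.csv"))
K <- vanraden_gca_kinship(impute_missing(filter_markers(g)))
sp <- read_spectra(file.path(data_dir, "spectra_dent.csv"))
scan_u <- scan_univariate(split_trial(sp, "trial1"), K, pool = "dent",
                          tissue = "leaf")
utils::write.table(scan_u, file.path(out, "heritability_scan_dent_univariate.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
su <- summarize_scan(scan_u)
message(sprintf("dent univariate (trial 1): mean genomic heritability %.1f%% (GxE confounded into it)",
                100 * su$mean_proportions["G"]))
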