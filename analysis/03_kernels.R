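#!/usr/bin/env Rscript

# Stage 3: relationship kernels.
#
# Builds the three kernel families the prediction models use:
#   - genomic: VanRaden GCA kinships per pool (after marker QC and mean
#     imputation) and their SCA product kernel;
#   - pedigree: the two-level family relationship (equal cross-family
#     coefficients), plus its SCA product;
#   - spectral: H = S*S*'/L per pool, trial and pretreated spectra set,
#     plus spectral SCA products.
# All kernels are scaled to unit entry variance and PSD-repaired.

suppressMessages(library(hybridps))

data_dir <- "results/data"
kern_dir <- "results/kernels"
dir.create(kern_dir, recursive = TRUE, showWarnings = FALSE)

dent <- read_genotypes(file.path(data_dir, "genotypes_dent.csv"))
flint <- read_genotypes(file.path(data_dir, "genotypes_flint.csv"))
design <- read_design(file.path(data_dir, "design.csv"))

## genomic
dent_q <- impute_missing(filter_markers(dent))
flint_q <- impute_missing(filter_markers(flint))
message(sprintf("marker QC: dent %d -> %d, flint %d -> %d markers",
                ncol(dent$geno), ncol(dent_q$geno),
                ncol(flint$geno), ncol(flint_q$geno)))
kb <- genomic_kernel_bundle(list(dent = dent, flint = flint, design = design))
for (nm in names(kb)) {
  write_kernel(kb[[nm]], file.path(kern_dir, sprintf("genomic_%s.csv", nm)))
}

## pedigree
ped <- list(
  dent = pedigree_kernel(setNames(dent$family, rownames(dent$geno)),
                         role = "GCA_dent"),
  flint = pedigree_kernel(setNames(flint$family, rownames(flint$geno)),
                          role = "GCA_flint"))
ped$sca <- sca_kernel(ped$dent, ped$flint, design)
for (nm in names(ped)) {
  write_kernel(ped[[nm]], file.path(kern_dir, sprintf("pedigree_%s.csv", nm)))
}

## spectral, one bundle per trial (two "origins")
for (trial in c("trial1", "trial2")) {
  hd <- spectral_relationship(
    read_spectra(file.path(data_dir, sprintf("pretreated_dent_%s.csv", trial))),
    role = "GCA_dent")
  hf <- spectral_relationship(
    read_spectra(file.path(data_dir, sprintf("pretreated_flint_%s.csv", trial))),
    role = "GCA_flint")
  hs <- sca_kernel(hd, hf, design)
  for (k in list(hd, hf, hs)) {
    k2 <- ensure_psd(scale_unit_variance(k))
    write_kernel(k2, file.path(kern_dir, sprintf("spectral_%s_%s.csv", trial,
                                                 tolower(attr(k2, "role")))))
  }
}

message("kernels written to ", kern_dir)
## quick alignment diagnostic: spectral vs genomic similarity
off <- function(m) m[lower.tri(m)]
hd1 <- read_kernel(file.path(kern_dir, "spectral_trial1_gca_dent.csv"))
kd <- read_kernel(file.path(kern_dir, "genomic_dent.csv"))
message(sprintf("cor(off-diagonal H, K) for dent, trial 1: %.3f",
                cor(off(as.matrix(hd1)), off(as.matrix(kd)))))
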