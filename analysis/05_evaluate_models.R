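#!/usr/bin/env Rscript

# Stage 5: predictive ability of the model set under both CV scenarios.
#
# Loads the kernel bundles of stage 3, assembles the named model catalog
# (P-BLUP, G-BLUP, per-origin H-BLUP, combined H models), and evaluates
# every model on byte-identical partitions under:
#   CV_SparseTesting - random fivefold CV, five repetitions;
#   CV_newDentFlint  - (dent family x flint family) holdouts with two-sided
#                      family exclusion and at least 10 predicted hybrids.

suppressMessages(library(hybridps))

data_dir <- "results/data"
kern_dir <- "results/kernels"
out <- "results"
seed <- 313L

design <- read_design(file.path(data_dir, "design.csv"))
phenotypes <- read_phenotypes(file.path(data_dir, "phenotypes.csv"), design)

rk <- function(...) read_kernel(file.path(kern_dir, sprintf(...)))
genomic <- list(dent = rk("genomic_dent.csv"), flint = rk("genomic_flint.csv"),
                sca = rk("genomic_sca.csv"))
pedigree <- list(dent = rk("pedigree_dent.csv"), flint = rk("pedigree_flint.csv"),
                 sca = rk("pedigree_sca.csv"))
spectral <- list(
  T1.LEAF = list(dent = rk("spectral_trial1_gca_dent.csv"),
                 flint = rk("spectral_trial1_gca_flint.csv"),
                 sca = rk("spectral_trial1_sca.csv")),
  T2.LEAF = list(dent = rk("spectral_trial2_gca_dent.csv"),
                 flint = rk("spectral_trial2_gca_flint.csv"),
                 sca = rk("spectral_trial2_sca.csv")))

models <- standard_model_catalog(pedigree = pedigree, genomic = genomic,
                                 spectral = spectral)
message("model catalog: ", paste(names(models), collapse = ", "))

partitions <- c(make_cv_sparse(design, k = 5, reps = 5, seed = seed),
                make_cv_new_dent_flint(design, min_predicted = 10))
message(sprintf("%d sparse folds + %d family-holdout partitions",
                sum(vapply(partitions, function(p) p$scenario, "") == "CV_SparseTesting"),
                sum(vapply(partitions, function(p) p$scenario, "") == "CV_newDentFlint")))

res <- run_scenario(models, partitions, phenotypes, design)
utils::write.table(res, file.path(out, "cv_results.tsv"), sep = "\t",
                   row.names = FALSE, quote = FALSE)
summ <- summarize_results(res)
utils::write.table(summ, file.path(out, "cv_summary.tsv"), sep = "\t",
                   row.names = FALSE, quote = FALSE)

for (sc in unique(summ$scenario)) {
  message("\n== ", sc, " ==")
  s <- summ[summ$scenario == sc, ]
  for (i in seq_len(nrow(s))) {
    message(sprintf("  %-12s mean ability %s (defined %d/%d folds)",
                    s$model[i],
                    ifelse(is.na(s$mean_ability[i]), "   NA",
                           sprintf("%+.3f", s$mean_ability[i])),
                    s$n_defined[i], s$n_folds[i]))
  }
}
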