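#' Define a BLUP model as a named set of kernel effects
#'
#' A model is an ordered list of random effects, each tied to a kernel and
#' a level key: `GCA_dent` effects take the hybrid's dent parent as level,
#' `GCA_flint` the flint parent, and `SCA` the hybrid id. Models with
#' several kernels of the same role (e.g. the combined-spectra models) are
#' expressed by repeating the role with different kernels.
#'
#' @param name model name (e.g. `"G-BLUP"`, `"H.PLOU.LEAF"`).
#' @param ... [kernel_matrix()] objects; each contributes one random effect
#'   whose role is read from the kernel's `role` attribute.
#' @return object of class `blup_model`.
#' @export
blup_model <- function(name, ...) {
  kernels <- list(...)
  if (!length(kernels)) stop("a model needs at least one kernel", call. = FALSE)
  for (k in kernels) stopifnot(inherits(k, "kernel_matrix"))
  roles <- unname(vapply(kernels, attr, character(1), "role"))
  ef_names <- make.unique(paste0(tolower(roles), "_", substr(
    vapply(kernels, attr, character(1), "source"), 1L, 4L)), sep = "_")
  structure(list(name = name, kernels = kernels, roles = roles,
                 effect_names = ef_names),
            class = "blup_model")
}

#' @export
print.blup_model <- function(x, ...) {
  cat(sprintf("<blup_model> %s: %s\n", x$name,
              paste(sprintf("%s(%s)", x$roles,
                            vapply(x$kernels, attr, character(1), "source")),
                    collapse = " + ")))
  invisible(x)
}

#' The standard model catalog of the hybrid prediction study
#'
#' Builds the named model set compared in the analysis: `P-BLUP`, `G-BLUP`,
#' the four single-origin spectral models (`H.PLOU.LEAF`, `H.MONS.LEAF`,
#' `H.PLOU.SIL`, `H.MONS.SIL`), the combined-tissue models (`H.COMB.LEAF`,
#' `H.COMB.SIL`) and `H.ALL`. Each spectral origin is a list with elements
#' `dent` (GCA kernel), optionally `flint`, and optionally `sca`; origins
#' missing the flint side (as for Mons silage) contribute only the dent GCA
#' effect, and no SCA effect.
#'
#' @param pedigree,genomic lists with elements `dent`, `flint`, `sca`
#'   ([kernel_matrix()] objects), or `NULL` to omit the model.
#' @param spectral named list of origins (`PLOU.LEAF`, `MONS.LEAF`,
#'   `PLOU.SIL`, `MONS.SIL`), each itself a list (`dent`, `flint`, `sca`).
#' @return list of [blup_model()] objects.
#' @export
standard_model_catalog <- function(pedigree = NULL, genomic = NULL, spectral = list()) {
  models <- list()
  add <- function(models, m) c(models, stats::setNames(list(m), m$name))
  bundle_kernels <- function(b) Filter(Negate(is.null), b[c("dent", "flint", "sca")])
  if (!is.null(pedigree)) {
    models <- add(models, do.call(blup_model, c(list("P-BLUP"), bundle_kernels(pedigree))))
  }
  if (!is.null(genomic)) {
    models <- add(models, do.call(blup_model, c(list("G-BLUP"), bundle_kernels(genomic))))
  }
  for (org in names(spectral)) {
    models <- add(models, do.call(blup_model, c(list(paste0("H.", org)),
                                                bundle_kernels(spectral[[org]]))))
  }
  leaf <- spectral[grep("LEAF$", names(spectral))]
  sil <- spectral[grep("SIL$", names(spectral))]
  if (length(leaf) > 1L) {
    models <- add(models, do.call(blup_model, c(list("H.COMB.LEAF"),
                                                unlist(lapply(leaf, bundle_kernels),
                                                       recursive = FALSE, use.names = FALSE))))
  }
  if (length(sil) > 1L) {
    models <- add(models, do.call(blup_model, c(list("H.COMB.SIL"),
                                                unlist(lapply(sil, bundle_kernels),
                                                      recursive = FALSE, use.names = FALSE))))
  }
  if (length(leaf) && length(sil) && length(c(leaf, sil)) > 1L) {
    models <- add(models, do.call(blup_model, c(list("H.ALL"),
                                                unlist(lapply(c(leaf, sil), bundle_kernels),
                                                       recursive = FALSE, use.names = FALSE))))
  }
  models
}

new_partition <- function(scenario, rep_id, fold_id, train, predict) {
  structure(list(scenario = scenario, rep = rep_id, fold = fold_id,
                 train = train, predict = predict),
            class = "cv_partition")
}

#' Random k-fold partitions over hybrids (sparse-testing scenario)
#'
#' Per repetition, a seeded random partition of all hybrids into `k` folds
#' of near-equal size (sizes differ by at most one; remainders go to the
#' lowest-index folds after the shuffle). Each fold serves once as the
#' predicted set, the remaining hybrids as calibration.
#'
#' @param design a [factorial_design()].
#' @param k folds per repetition.
#' @param reps repetitions.
#' @param seed RNG seed.
#' @return list of partitions (`scenario = "CV_SparseTesting"`), each with
#'   `train` and `predict` hybrid-id vectors.
#' @export
make_cv_sparse <- function(design, k = 5L, reps = 5L, seed = 1L) {
  stopifnot(inherits(design, "factorial_design"))
  ids <- design$hybrids$hybrid_id
  n <- length(ids)
  if (k > n) stop("k exceeds the number of hybrids", call. = FALSE)
  with_seed(seed, {
    parts <- list()
    for (r in seq_len(reps)) {
      shuffled <- sample(ids)
      fold_of <- rep(seq_len(k), length.out = n)  # remainder to lowest folds
      for (f in seq_len(k)) {
        pred <- shuffled[fold_of == f]
        parts[[length(parts) + 1L]] <-
          new_partition("CV_SparseTesting", r, f, setdiff(ids, pred), pred)
      }
    }
    parts
  })
}

#' Family-holdout partitions (new dent x new flint scenario)
#'
#' For every (dent family, flint family) pair, the predicted set holds the
#' hybrids whose dent parent belongs to the dent family and whose flint
#' parent belongs to the flint family; the calibration set holds the
#' hybrids with a dent parent outside that dent family AND a flint parent
#' outside that flint family (two-sided family exclusion). Only partitions
#' with at least `min_predicted` predicted hybrids are kept.
#'
#' @param design a [factorial_design()] with family labels.
#' @param min_predicted minimum size of the predicted set.
#' @return list of partitions (`scenario = "CV_newDentFlint"`); empty, with
#'   a warning, when no pair qualifies.
#' @export
make_cv_new_dent_flint <- function(design, min_predicted = 10L) {
  stopifnot(inherits(design, "factorial_design"))
  hyb <- design$hybrids
  dfam <- design$dent_family[hyb$dent_parent]
  ffam <- design$flint_family[hyb$flint_parent]
  d_levels <- unique(design$dent_family)
  f_levels <- unique(design$flint_family)
  if (length(d_levels) < 2L || length(f_levels) < 2L) {
    warning("need at least two families per pool; no partitions generated")
    return(list())
  }
  parts <- list()
  fold <- 0L
  for (D in d_levels) {
    for (F_ in f_levels) {
      pred <- hyb$hybrid_id[dfam == D & ffam == F_]
      if (length(pred) < min_predicted) next
      train <- hyb$hybrid_id[dfam != D & ffam != F_]
      if (!length(train)) next
      fold <- fold + 1L
      p <- new_partition("CV_newDentFlint", 1L, fold, train, pred)
      p$held_out <- c(dent = D, flint = F_)
      parts[[fold]] <- p
    }
  }
  if (!length(parts)) warning("no family pair reaches min_predicted = ", min_predicted)
  parts
}

#' Predictive ability (Pearson correlation)
#'
#' Pearson correlation between predictions and observed adjusted means of
#' the predicted set. Undefined when either vector is (numerically)
#' constant — e.g. pedigree predictions under family holdout — and then
#' reported as `NA` with a `reason` attribute, never coerced to 0.
#'
#' @param pred,obs numeric vectors of equal length (at least 3).
#' @return correlation in `[-1, 1]`, or `NA` with attribute `reason`.
#' @export
predictive_ability <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("pred and obs lengths differ", call. = FALSE)
  if (length(pred) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (is_near_constant(pred)) {
    return(structure(NA_real_, reason = "constant predictions"))
  }
  if (is_near_constant(obs)) {
    return(structure(NA_real_, reason = "constant observations"))
  }
  stats::cor(pred, obs)
}

# fit one model on the training hybrids and predict the held-out ones
fit_and_predict <- function(model, train_ids, pred_ids, y_all, design) {
  hyb <- design$hybrids
  lev_for <- function(role, ids) {
    rows <- match(ids, hyb$hybrid_id)
    switch(role,
           GCA_dent = hyb$dent_parent[rows],
           GCA_flint = hyb$flint_parent[rows],
           SCA = hyb$hybrid_id[rows])
  }
  y <- y_all[train_ids]
  effects <- vector("list", length(model$kernels))
  newlevels <- list()
  for (i in seq_along(model$kernels)) {
    role <- model$roles[i]
    effects[[i]] <- random_effect(model$effect_names[i], lev_for(role, train_ids),
                                  kernel = model$kernels[[i]])
    newlevels[[model$effect_names[i]]] <- lev_for(role, pred_ids)
  }
  fm <- fit_reml(y, effects)
  list(fit = fm,
       pred = predict_hybrids(fm, as.data.frame(newlevels, stringsAsFactors = FALSE)))
}

#' Run a cross-validation scenario for a set of models
#'
#' Applies every model to byte-identical train/predict partitions (shared
#' partition objects, enforced by construction), for every trait in the
#' phenotype table, and records the per-fold predictive ability, training
#' sizes and convergence. A model failure in one cell is recorded and the
#' run continues.
#'
#' @param models list of [blup_model()] (e.g. [standard_model_catalog()]).
#' @param partitions list of partitions from [make_cv_sparse()] and/or
#'   [make_cv_new_dent_flint()].
#' @param phenotypes long data.frame (`hybrid_id`, `trait`, `value`).
#' @param design the [factorial_design()] the partitions refer to.
#' @return data.frame with one row per (trait, model, partition):
#'   `trait`, `model`, `scenario`, `rep`, `fold`, `n_train`, `n_pred`,
#'   `ability`, `converged`, `note`.
#' @export
run_scenario <- function(models, partitions, phenotypes, design) {
  stopifnot(inherits(design, "factorial_design"))
  traits <- unique(phenotypes$trait)
  rows <- list()
  for (tr in traits) {
    ph <- phenotypes[phenotypes$trait == tr, ]
    y_all <- stats::setNames(ph$value, ph$hybrid_id)
    for (p in partitions) {
      train_ids <- intersect(p$train, names(y_all))
      pred_ids <- intersect(p$predict, names(y_all))
      for (m in models) {
        res <- tryCatch(fit_and_predict(m, train_ids, pred_ids, y_all, design),
                        error = function(e) e)
        if (inherits(res, "error")) {
          rows[[length(rows) + 1L]] <- data.frame(
            trait = tr, model = m$name, scenario = p$scenario, rep = p$rep,
            fold = p$fold, n_train = length(train_ids), n_pred = length(pred_ids),
            ability = NA_real_, converged = FALSE,
            note = paste("fit failed:", conditionMessage(res)),
            stringsAsFactors = FALSE)
          next
        }
        ab <- predictive_ability(res$pred, unname(y_all[pred_ids]))
        rows[[length(rows) + 1L]] <- data.frame(
          trait = tr, model = m$name, scenario = p$scenario, rep = p$rep,
          fold = p$fold, n_train = length(train_ids), n_pred = length(pred_ids),
          ability = as.numeric(ab), converged = res$fit$converged,
          note = if (is.na(ab)) attr(ab, "reason") %||% "undefined" else "",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize scenario results per (trait, model, scenario)
#'
#' Means and medians are taken over folds with a defined ability; the count
#' of defined folds is reported alongside.
#'
#' @param results data.frame from [run_scenario()].
#' @return summary data.frame with `mean_ability`, `median_ability`,
#'   `n_folds`, `n_defined`.
#' @export
summarize_results <- function(results) {
  key <- interaction(results$trait, results$model, results$scenario, drop = TRUE)
  pieces <- lapply(split(results, key), function(d) {
    ok <- !is.na(d$ability)
    data.frame(trait = d$trait[1L], model = d$model[1L], scenario = d$scenario[1L],
               mean_ability = if (any(ok)) mean(d$ability[ok]) else NA_real_,
               median_ability = if (any(ok)) stats::median(d$ability[ok]) else NA_real_,
               n_folds = nrow(d), n_defined = sum(ok),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$trait, out$scenario, out$model), ]
}
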