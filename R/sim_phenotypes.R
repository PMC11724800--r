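#' Simulate hybrid phenotypes with GCA/SCA structure
#'
#' Hybrid adjusted means are generated as
#' `Y_ij = mu + GCA_d(i) + GCA_f(j) + SCA(i, j) + e`.
#' Each pool's GCA values are sums of i.i.d. normal per-marker effects on the
#' frequency-centered genotypes, rescaled so the realized variance over the
#' pool's lines equals the configured target exactly. SCA deviations are
#' drawn from `N(0, K_SCA * var_sca)` where `K_SCA` is the product kernel of
#' the two pools' VanRaden kinships (the covariance the prediction model
#' assumes). Errors are i.i.d. `N(0, var_error)`.
#'
#' @param design a [factorial_design()].
#' @param dent_geno,flint_geno imputed [geno_matrix()] objects covering all
#'   parents in `design`.
#' @param cfg a [sim_config()] (variance targets, number of traits).
#' @param mu grand mean.
#' @param seed RNG seed.
#' @return long data.frame (`hybrid_id`, `trait`, `value`) with attributes
#'   `components` (realized variance bookkeeping per trait: the four part
#'   variances plus the cross-covariance term, summing exactly to `var(Y)`)
#'   and `true_values` (the underlying GCA/SCA/error draws).
#' @export
simulate_hybrid_phenotypes <- function(design, dent_geno, flint_geno, cfg,
                                       mu = 0, seed = child_seed(cfg$seed, 4L)) {
  stopifnot(inherits(design, "factorial_design"))
  hyb <- design$hybrids
  miss <- c(setdiff(hyb$dent_parent, rownames(dent_geno$geno)),
            setdiff(hyb$flint_parent, rownames(flint_geno$geno)))
  if (length(miss)) stop("design references unknown lines: ",
                         paste(miss, collapse = ", "), call. = FALSE)

  gca_from_markers <- function(g, target_var) {
    C <- sweep(g$geno, 2L, allele_freq(g))
    alpha <- stats::rnorm(ncol(C))
    u <- drop(C %*% alpha)
    if (target_var <= 0) return(stats::setNames(rep(0, nrow(C)), rownames(C)))
    s <- stats::sd(u)
    if (s < 1e-12) stop("degenerate genotypes: no marker variation for GCA", call. = FALSE)
    stats::setNames(u / s * sqrt(target_var), rownames(C))
  }

  sca_draw <- function(var_sca) {
    n_h <- nrow(hyb)
    if (var_sca <= 0) return(stats::setNames(rep(0, n_h), hyb$hybrid_id))
    Kd <- vanraden_gca_kinship(drop_monomorphic(dent_geno))
    Kf <- vanraden_gca_kinship(drop_monomorphic(flint_geno))
    Ks <- sca_kernel(Kd, Kf, design)
    Ks <- ensure_psd(Ks)
    U <- chol(unclass(Ks) + diag(1e-8, n_h))
    stats::setNames(drop(crossprod(U, stats::rnorm(n_h))) * sqrt(var_sca), hyb$hybrid_id)
  }

  with_seed(seed, {
    out <- vector("list", cfg$n_traits)
    comps <- vector("list", cfg$n_traits)
    truth <- vector("list", cfg$n_traits)
    for (t in seq_len(cfg$n_traits)) {
      gd <- gca_from_markers(dent_geno, cfg$var_gca_dent)
      gf <- gca_from_markers(flint_geno, cfg$var_gca_flint)
      sc <- sca_draw(cfg$var_sca)
      e <- stats::rnorm(nrow(hyb), 0, sqrt(cfg$var_error))
      parts <- cbind(gca_d = gd[hyb$dent_parent], gca_f = gf[hyb$flint_parent],
                     sca = sc, error = e)
      y <- mu + rowSums(parts)
      trait <- sprintf("trait%d", t)
      out[[t]] <- data.frame(hybrid_id = hyb$hybrid_id, trait = trait,
                             value = y, stringsAsFactors = FALSE)
      part_vars <- apply(parts, 2L, stats::var)
      comps[[t]] <- c(part_vars, cross_cov = stats::var(y) - sum(part_vars),
                      total = stats::var(y))
      truth[[t]] <- list(gca_d = gd, gca_f = gf, sca = sc, error = e)
    }
    res <- do.call(rbind, out)
    attr(res, "components") <- do.call(rbind, comps)
    attr(res, "true_values") <- truth
    attr(res, "mu") <- mu
    res
  })
}
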