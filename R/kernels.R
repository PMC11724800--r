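#' Relationship kernel container
#'
#' A square symmetric relationship matrix over parent lines or hybrid
#' crosses, tagged with its source (`pedigree`, `genomic`, `spectral`) and
#' role (`GCA_dent`, `GCA_flint`, `SCA`).
#'
#' @param m square numeric matrix with identical row/column names.
#' @param source one of `"pedigree"`, `"genomic"`, `"spectral"`.
#' @param role one of `"GCA_dent"`, `"GCA_flint"`, `"SCA"`.
#' @param scaled has the matrix been scaled to unit entry variance?
#' @param jitter diagonal jitter added by PSD repair (0 if none).
#' @return object of class `kernel_matrix` (the matrix, with attributes).
#' @export
kernel_matrix <- function(m, source = c("genomic", "spectral", "pedigree"),
                          role = c("GCA_dent", "GCA_flint", "SCA"),
                          scaled = FALSE, jitter = 0) {
  source <- match.arg(source)
  role <- match.arg(role)
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("kernel must be square", call. = FALSE)
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m))) {
    stop("kernel needs identical row and column names", call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) stop("kernel ids must be unique", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-10 * max(1, max(abs(m)))) {
    stop("kernel is not symmetric", call. = FALSE)
  }
  m <- (m + t(m)) / 2
  structure(m, class = c("kernel_matrix", "matrix"),
            source = source, role = role, scaled = scaled, jitter = jitter)
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("<kernel_matrix> %d x %d; source=%s role=%s scaled=%s jitter=%g\n",
              nrow(x), ncol(x), attr(x, "source"), attr(x, "role"),
              attr(x, "scaled"), attr(x, "jitter")))
  invisible(x)
}

#' @export
as.matrix.kernel_matrix <- function(x, ...) {
  structure(unclass(x), source = NULL, role = NULL, scaled = NULL, jitter = NULL)
}

kernel_attrs <- function(k) attributes(k)[c("source", "role", "scaled", "jitter")]

with_kernel_attrs <- function(m, template, ...) {
  a <- utils::modifyList(kernel_attrs(template), list(...))
  kernel_matrix(m, source = a$source, role = a$role, scaled = a$scaled,
                jitter = a$jitter)
}

#' Marker quality control
#'
#' Drops markers that exceed a missingness threshold (within any pool), a
#' pool-specific heterozygosity-rate threshold (fraction of 0.5 calls among
#' observed, dent and flint thresholds separately), or whose minor allele
#' frequency is below `min_maf` in every pool present. An audit of counts
#' removed per rule is attached as attribute `filter_audit`.
#'
#' @param g a [geno_matrix()] (one pool or both).
#' @param max_missing maximum missing fraction per pool.
#' @param max_het_dent,max_het_flint maximum heterozygosity rate in the dent
#'   (first configured pool) and flint (second) lines.
#' @param min_maf minimum minor allele frequency (marker kept if it passes
#'   in at least one pool).
#' @param pools the two pool labels, in (dent, flint) order.
#' @return the filtered `geno_matrix`.
#' @export
filter_markers <- function(g, max_missing = 0.20, max_het_dent = 0.05,
                           max_het_flint = 0.10, min_maf = 0.05,
                           pools = c("dent", "flint")) {
  stopifnot(inherits(g, "geno_matrix"))
  het_limits <- stats::setNames(c(max_het_dent, max_het_flint), pools)
  present <- intersect(pools, unique(g$pool))
  n_mrk <- ncol(g$geno)
  fail_miss <- fail_het <- rep(FALSE, n_mrk)
  maf_pass <- rep(FALSE, n_mrk)
  for (p in present) {
    sub <- g$geno[g$pool == p, , drop = FALSE]
    miss <- colMeans(is.na(sub))
    het <- colMeans(sub == 0.5, na.rm = TRUE)
    het[is.nan(het)] <- 1  # entirely missing within pool
    f <- colMeans(sub, na.rm = TRUE)
    maf <- pmin(f, 1 - f)
    maf[is.nan(maf)] <- 0
    fail_miss <- fail_miss | miss > max_missing
    fail_het <- fail_het | het > het_limits[[p]]
    maf_pass <- maf_pass | maf >= min_maf
  }
  keep <- !fail_miss & !fail_het & maf_pass
  audit <- c(n_input = n_mrk,
             removed_missing = sum(fail_miss),
             removed_het = sum(fail_het & !fail_miss),
             removed_maf = sum(!maf_pass & !fail_miss & !fail_het),
             n_kept = sum(keep))
  if (!any(keep)) {
    stop("all markers removed by QC filters (",
         paste(sprintf("%s=%d", names(audit), audit), collapse = ", "), ")",
         call. = FALSE)
  }
  out <- geno_matrix(g$geno[, keep, drop = FALSE], g$pool, g$map[keep, , drop = FALSE],
                     family = g$family)
  attr(out, "filter_audit") <- audit
  out
}

#' Impute missing genotype calls
#'
#' Each missing entry is replaced by the reference-allele frequency of its
#' marker, estimated within the line's pool.
#'
#' @param g a filtered [geno_matrix()].
#' @return a `geno_matrix` with no missing values. Imputed values are
#'   generally not in \{0, 0.5, 1\}; they are stored as-is for kinship
#'   computation.
#' @export
impute_missing <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  geno <- g$geno
  for (p in unique(g$pool)) {
    rows <- g$pool == p
    sub <- geno[rows, , drop = FALSE]
    if (!anyNA(sub)) next
    f <- colMeans(sub, na.rm = TRUE)
    if (anyNA(f) || any(is.nan(f))) {
      stop("marker entirely missing within pool '", p,
           "'; it should have been filtered out", call. = FALSE)
    }
    idx <- which(is.na(sub), arr.ind = TRUE)
    sub[idx] <- f[idx[, 2L]]
    geno[rows, ] <- sub
  }
  out <- g
  out$geno <- geno
  # bypass the {0, 0.5, 1} check: imputed dosages are fractional by design
  structure(out, class = "geno_matrix")
}

# internal: drop markers with f in {0,1} within this (single-pool) matrix
drop_monomorphic <- function(g) {
  f <- allele_freq(g)
  keep <- f > 0 & f < 1
  if (all(keep)) return(g)
  out <- g
  out$geno <- g$geno[, keep, drop = FALSE]
  out$map <- g$map[keep, , drop = FALSE]
  structure(out, class = "geno_matrix")
}

#' VanRaden GCA kinship for inbred lines
#'
#' Method-1 VanRaden kinship adapted to inbreds coded as allele shares
#' 0/0.5/1:
#' `K(i, i') = sum_m (G_im - f_m) (G_i'm - f_m) / sum_m f_m (1 - f_m)`,
#' with `f_m` the reference-allele frequency estimated on the same pool's
#' lines.
#'
#' @param g an imputed, filtered [geno_matrix()] containing a single pool.
#' @param role kernel role; defaults to `GCA_dent`/`GCA_flint` based on the
#'   pool label when it is one of `dent`/`flint`.
#' @return a [kernel_matrix()] with `source = "genomic"`.
#' @export
vanraden_gca_kinship <- function(g, role = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  if (length(unique(g$pool)) != 1L) {
    stop("kinship is computed within one pool; subset first", call. = FALSE)
  }
  if (anyNA(g$geno)) stop("impute missing genotypes first", call. = FALSE)
  f <- allele_freq(g)
  if (any(f <= 0) || any(f >= 1)) {
    stop("monomorphic markers present (f in {0,1}); filtering violated", call. = FALSE)
  }
  Cg <- sweep(g$geno, 2L, f)
  K <- tcrossprod(Cg) / sum(f * (1 - f))
  if (is.null(role)) {
    role <- switch(g$pool[1L], dent = "GCA_dent", flint = "GCA_flint", "GCA_dent")
  }
  kernel_matrix(K, source = "genomic", role = role)
}

#' Spectral relationship matrix (H)
#'
#' `H = S* S*' / L`: the pretreated spectra (first derivative of the
#' normalized spectra), with every wavelength column centered and scaled to
#' unit variance across genotypes, cross-multiplied and divided by the
#' number of wavelengths `L`. Zero-variance columns are dropped with a
#' warning (`L` decremented).
#'
#' @param pretreated a [spectra_set()] in state `"derivative"` with one
#'   spectrum per genotype, or a plain genotype x wavelength matrix.
#' @param role kernel role for the result.
#' @return a [kernel_matrix()] with `source = "spectral"`.
#' @export
spectral_relationship <- function(pretreated, role = c("GCA_dent", "GCA_flint", "SCA")) {
  role <- match.arg(role)
  m <- if (inherits(pretreated, "spectra_set")) {
    require_state(pretreated, "derivative")
    spectra_matrix(pretreated)
  } else as.matrix(pretreated)
  sds <- apply(m, 2L, stats::sd)
  zero <- sds < 1e-12
  if (any(zero)) {
    warning(sum(zero), " zero-variance wavelength column(s) dropped from H")
    m <- m[, !zero, drop = FALSE]
    sds <- sds[!zero]
  }
  if (!ncol(m)) stop("no informative wavelengths left", call. = FALSE)
  S <- scale(m, center = TRUE, scale = sds)
  H <- tcrossprod(S) / ncol(S)
  kernel_matrix(H, source = "spectral", role = role)
}

#' SCA kernel as the product of parental GCA kernels
#'
#' For hybrids (i x j) and (i' x j'):
#' `K_SCA((ij), (i'j')) = K_GCA_d(i, i') * K_GCA_f(j, j')`.
#'
#' @param kd,kf parental [kernel_matrix()] objects (dent, flint), of the
#'   same source, covering every parent in `design`.
#' @param design a [factorial_design()]; the result is indexed by its
#'   hybrid ids, in order.
#' @return a hybrid-level [kernel_matrix()] with `role = "SCA"`.
#' @export
sca_kernel <- function(kd, kf, design) {
  stopifnot(inherits(design, "factorial_design"))
  if (!identical(attr(kd, "source"), attr(kf, "source"))) {
    stop("parental kernels must share a source (both genomic, both spectral, or both pedigree)",
         call. = FALSE)
  }
  hyb <- design$hybrids
  miss_d <- setdiff(hyb$dent_parent, rownames(kd))
  miss_f <- setdiff(hyb$flint_parent, rownames(kf))
  if (length(miss_d) || length(miss_f)) {
    stop("kernel missing parents referenced by the design: ",
         paste(c(miss_d, miss_f), collapse = ", "), call. = FALSE)
  }
  Kd <- unclass(kd)[hyb$dent_parent, hyb$dent_parent, drop = FALSE]
  Kf <- unclass(kf)[hyb$flint_parent, hyb$flint_parent, drop = FALSE]
  Ks <- Kd * Kf
  rownames(Ks) <- colnames(Ks) <- hyb$hybrid_id
  kernel_matrix(Ks, source = attr(kd, "source"), role = "SCA")
}

#' Scale a kernel to unit entry variance
#'
#' Divides the matrix by the sample standard deviation of all its `n^2`
#' entries so their sample variance becomes 1 (guards REML component
#' estimates against arbitrary kernel scaling).
#'
#' @param k an unscaled [kernel_matrix()].
#' @return the scaled `kernel_matrix` (`scaled` flag set).
#' @export
scale_unit_variance <- function(k) {
  stopifnot(inherits(k, "kernel_matrix"))
  if (isTRUE(attr(k, "scaled"))) return(k)
  s <- stats::sd(as.vector(unclass(k)))
  if (!is.finite(s) || s < 1e-14) stop("kernel entries are constant; cannot scale", call. = FALSE)
  with_kernel_attrs(unclass(k) / s, k, scaled = TRUE)
}

#' Repair near-PSD kernels
#'
#' If the smallest eigenvalue is below `-tol`, adds `|min eigenvalue| + 1e-6`
#' to the diagonal and records the jitter; REML needs invertible covariances.
#'
#' @param k a [kernel_matrix()].
#' @param tol negative-eigenvalue tolerance.
#' @return the (possibly jittered) `kernel_matrix`.
#' @export
ensure_psd <- function(k, tol = 1e-8) {
  stopifnot(inherits(k, "kernel_matrix"))
  ev <- eigen(unclass(k), symmetric = TRUE, only.values = TRUE)$values
  mn <- min(ev)
  if (mn >= -tol) return(k)
  jit <- abs(mn) + 1e-6
  with_kernel_attrs(unclass(k) + diag(jit, nrow(k)), k,
                    jitter = attr(k, "jitter") + jit)
}

#' Family-structured pedigree relationship matrix
#'
#' Builds the two-level expected relationship implied by a set of biparental
#' families: `diag_value` on the diagonal, `within` between lines of the
#' same family, and `between` for every cross-family pair. This is the
#' structural pedigree kernel of a balanced family design, in which all
#' cross-family coefficients are equal; under family-holdout
#' cross-validation it carries no information about held-out families.
#'
#' @param family named character vector mapping line id to family.
#' @param diag_value self-relationship of an inbred line.
#' @param within relationship between two lines of the same family.
#' @param between relationship between lines of different families.
#' @param role kernel role.
#' @return a [kernel_matrix()] with `source = "pedigree"`.
#' @export
pedigree_kernel <- function(family, diag_value = 1, within = 0.5, between = 0.25,
                            role = c("GCA_dent", "GCA_flint", "SCA")) {
  role <- match.arg(role)
  ids <- names(family)
  if (is.null(ids)) stop("`family` must be a named vector", call. = FALSE)
  same <- outer(family, family, `==`)
  P <- ifelse(same, within, between)
  diag(P) <- diag_value
  rownames(P) <- colnames(P) <- ids
  kernel_matrix(P, source = "pedigree", role = role)
}
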