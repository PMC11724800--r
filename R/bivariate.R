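#' Bivariate polygenic model across two trials
#'
#' Fits, by REML, the model `y = X beta + Z u + e` on the stacked
#' observations of two trials, where `beta` holds fixed trial effects,
#' `var(u) = [[s2_u1, s_u12], [s_u12, s2_u2]] (x) K` is the across-trial
#' polygenic covariance (Kronecker with the kinship `K`), and
#' `var(e) = diag(s2_e1, s2_e2) (x) I`. The 2x2 genetic matrix is
#' parameterized by its Cholesky factor, which keeps it positive
#' semidefinite throughout the optimization (Nelder-Mead, then BFGS
#' polish, on the restricted likelihood).
#'
#' @param y1,y2 named numeric vectors of per-genotype values in trial 1 and
#'   trial 2 (names = genotype ids present in `K`).
#' @param K a [kernel_matrix()] (or plain matrix) over the genotypes.
#' @param tol relative convergence tolerance passed to the optimizer.
#' @return object of class `bivariate_components`: `sigma2_u1`, `sigma2_u2`,
#'   `sigma_u12`, `sigma2_e1`, `sigma2_e2`, the restricted log-likelihood,
#'   and a convergence flag.
#' @export
fit_bivariate <- function(y1, y2, K, tol = 1e-8) {
  if (!length(y1) || !length(y2)) {
    stop("one trial has no observations; use the univariate path (scan_univariate)",
         call. = FALSE)
  }
  Km <- unclass(K)
  ids1 <- names(y1); ids2 <- names(y2)
  if (is.null(ids1) || is.null(ids2)) stop("y1/y2 must be named by genotype", call. = FALSE)
  missing_ids <- setdiff(c(ids1, ids2), rownames(Km))
  if (length(missing_ids)) {
    stop("kernel lacks genotype(s): ", paste(utils::head(missing_ids, 5L), collapse = ", "),
         call. = FALSE)
  }
  n1 <- length(y1); n2 <- length(y2)
  y <- c(y1, y2)
  X <- cbind(trial1 = rep(c(1, 0), c(n1, n2)), trial2 = rep(c(0, 1), c(n1, n2)))
  K11 <- Km[ids1, ids1, drop = FALSE]
  K22 <- Km[ids2, ids2, drop = FALSE]
  K12 <- Km[ids1, ids2, drop = FALSE]

  build_V <- function(g11, g12, g22, e1, e2) {
    rbind(cbind(g11 * K11 + diag(e1, n1), g12 * K12),
          cbind(g12 * t(K12), g22 * K22 + diag(e2, n2)))
  }
  negll <- function(p) {
    l11 <- exp(p[1L]); l21 <- p[2L]; l22 <- exp(p[3L])
    e1 <- exp(p[4L]); e2 <- exp(p[5L])
    V <- build_V(l11^2, l11 * l21, l21^2 + l22^2, e1, e2)
    ll <- reml_loglik_V(y, X, V)
    if (!is.finite(ll)) 1e10 else -ll
  }

  # start from univariate single-kernel fits of each trial
  start_uni <- function(yt, ids) {
    fm <- try(fit_reml(yt, list(random_effect("g", ids,
                kernel_matrix(Km, source = "genomic", role = "GCA_dent")))),
              silent = TRUE)
    if (inherits(fm, "try-error")) c(g = stats::var(yt) / 2, e = stats::var(yt) / 2)
    else c(g = unname(fm$sigma2[1L]), e = unname(fm$sigma2[2L]))
  }
  s1 <- start_uni(y1, ids1); s2 <- start_uni(y2, ids2)
  g1 <- max(s1["g"], 1e-6 * stats::var(y)); g2 <- max(s2["g"], 1e-6 * stats::var(y))
  l11 <- sqrt(g1); l21 <- 0.5 * sqrt(g2); l22 <- sqrt(max(g2 - l21^2, 1e-8))
  p0 <- c(log(l11), l21, log(l22),
          log(max(s1["e"], 1e-6 * stats::var(y))),
          log(max(s2["e"], 1e-6 * stats::var(y))))

  opt <- stats::optim(p0, negll, method = "Nelder-Mead",
                      control = list(maxit = 800, reltol = tol))
  opt2 <- try(stats::optim(opt$par, negll, method = "BFGS",
                           control = list(maxit = 200, reltol = tol)),
              silent = TRUE)
  if (!inherits(opt2, "try-error") && opt2$value <= opt$value) opt <- opt2

  p <- opt$par
  l11 <- exp(p[1L]); l21 <- p[2L]; l22 <- exp(p[3L])
  structure(list(
    sigma2_u1 = l11^2,
    sigma2_u2 = l21^2 + l22^2,
    sigma_u12 = l11 * l21,
    sigma2_e1 = exp(p[4L]),
    sigma2_e2 = exp(p[5L]),
    loglik = -opt$value,
    converged = opt$convergence == 0L,
    n = c(n1 = n1, n2 = n2)
  ), class = "bivariate_components")
}

#' @export
print.bivariate_components <- function(x, ...) {
  cat(sprintf("<bivariate_components> u1=%.4g u2=%.4g u12=%.4g | e1=%.4g e2=%.4g | logREML=%.4f\n",
              x$sigma2_u1, x$sigma2_u2, x$sigma_u12, x$sigma2_e1, x$sigma2_e2,
              x$loglik))
  invisible(x)
}

#' Decompose bivariate components into genetic, GxE and residual variance
#'
#' Across-site decomposition of a two-trial polygenic fit:
#' the genetic variance is the across-trial genetic covariance,
#' `sigma2_G = sigma_u12`; the genotype-by-environment variance is
#' `sigma2_GxE = (sigma2_u1 + sigma2_u2) / 2 - sigma_u12`; and the residual
#' is the average `sigma2_e = (sigma2_e1 + sigma2_e2) / 2`.
#'
#' @param b a [fit_bivariate()] result.
#' @return named list with the three components and `proportions` (shares of
#'   their sum, after flooring the genetic and GxE parts at zero; a negative
#'   estimated covariance means no detectable genetic signal).
#' @export
yamada_decomposition <- function(b) {
  stopifnot(inherits(b, "bivariate_components"))
  s_g <- b$sigma_u12
  s_gxe <- 0.5 * (b$sigma2_u1 + b$sigma2_u2) - b$sigma_u12
  s_e <- 0.5 * (b$sigma2_e1 + b$sigma2_e2)
  parts <- pmax(c(G = s_g, GxE = s_gxe, e = s_e), 0)
  tot <- sum(parts)
  list(sigma2_G = s_g, sigma2_GxE = s_gxe, sigma2_e = s_e,
       proportions = if (tot > 0) parts / tot else parts * NA_real_)
}
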