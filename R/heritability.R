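#' Per-wavelength genomic variance decomposition across two trials
#'
#' Fits the bivariate polygenic model ([fit_bivariate()]) at every
#' wavelength of two trials' adjusted spectra and decomposes the components
#' into genetic, genotype-by-environment and residual variance
#' ([yamada_decomposition()]). The kinship is normalized to mean diagonal 1
#' so the genomic variance is on the phenotypic scale and the proportions
#' are comparable across wavelengths. Wavelengths where the fit fails are
#' flagged, not fabricated.
#'
#' @param s1,s2 [spectra_set()] objects from the two trials, state
#'   `"adjusted"` (or `"normalized"`), one spectrum per genotype, sharing
#'   the wavelength grid.
#' @param K [kernel_matrix()] (or matrix) covering the genotypes of both
#'   trials.
#' @param pool,tissue labels recorded in the scan (bookkeeping only).
#' @return a `heritability_scan` data.frame: `wavelength`, `sigma2_G`,
#'   `sigma2_GxE`, `sigma2_e`, `prop_G`, `prop_GxE`, `prop_e`, `converged`.
#' @export
scan_bivariate <- function(s1, s2, K, pool = NA_character_, tissue = NA_character_) {
  require_state(s1, c("adjusted", "normalized"))
  require_state(s2, c("adjusted", "normalized"))
  if (!isTRUE(all.equal(s1$wavelengths, s2$wavelengths))) {
    stop("the two trials must share a wavelength grid", call. = FALSE)
  }
  m1 <- spectra_matrix(s1)
  m2 <- spectra_matrix(s2)
  common <- intersect(rownames(m1), rownames(m2))
  if (!length(common)) stop("disjoint genotype sets between trials", call. = FALSE)
  Kn <- normalize_kinship(K)
  L <- length(s1$wavelengths)
  out <- empty_scan(s1$wavelengths)
  for (l in seq_len(L)) {
    b <- tryCatch(fit_bivariate(m1[, l], m2[, l], Kn), error = function(e) NULL)
    if (is.null(b) || !b$converged) {
      out$converged[l] <- FALSE
      next
    }
    yd <- yamada_decomposition(b)
    out$sigma2_G[l] <- yd$sigma2_G
    out$sigma2_GxE[l] <- yd$sigma2_GxE
    out$sigma2_e[l] <- yd$sigma2_e
    out$prop_G[l] <- yd$proportions[["G"]]
    out$prop_GxE[l] <- yd$proportions[["GxE"]]
    out$prop_e[l] <- yd$proportions[["e"]]
    out$converged[l] <- TRUE
  }
  scan_result(out, model = "bivariate", pool = pool, tissue = tissue)
}

#' Per-wavelength genomic heritability from a single trial
#'
#' Univariate single-kernel REML per wavelength; genomic heritability is
#' `s2_g / (s2_g + s2_e)`. Genotype-by-environment variance is not
#' estimable from one trial and is reported absent (`NA`).
#'
#' @param s a [spectra_set()] (state `"adjusted"` or `"normalized"`), one
#'   spectrum per genotype, single trial.
#' @param K kinship over the genotypes.
#' @param pool,tissue labels recorded in the scan.
#' @return a `heritability_scan` data.frame (GxE columns `NA`).
#' @export
scan_univariate <- function(s, K, pool = NA_character_, tissue = NA_character_) {
  require_state(s, c("adjusted", "normalized"))
  m <- spectra_matrix(s)
  if (nrow(m) < 10L) {
    stop("fewer than 10 genotypes: univariate heritability is too unstable",
         call. = FALSE)
  }
  Kn <- normalize_kinship(K)
  kk <- kernel_matrix(Kn, source = "genomic", role = "GCA_dent")
  out <- empty_scan(s$wavelengths)
  for (l in seq_len(ncol(m))) {
    fm <- tryCatch(
      fit_reml(m[, l], list(random_effect("g", rownames(m), kk))),
      error = function(e) NULL)
    if (is.null(fm) || !fm$converged) {
      out$converged[l] <- FALSE
      next
    }
    s2g <- fm$sigma2[["g"]]; s2e <- fm$sigma2[["residual"]]
    out$sigma2_G[l] <- s2g
    out$sigma2_e[l] <- s2e
    out$prop_G[l] <- s2g / (s2g + s2e)
    out$prop_e[l] <- s2e / (s2g + s2e)
    out$converged[l] <- TRUE
  }
  scan_result(out, model = "univariate", pool = pool, tissue = tissue)
}

normalize_kinship <- function(K) {
  Km <- unclass(K)
  Km / mean(diag(Km))
}

empty_scan <- function(wl) {
  data.frame(wavelength = wl, sigma2_G = NA_real_, sigma2_GxE = NA_real_,
             sigma2_e = NA_real_, prop_G = NA_real_, prop_GxE = NA_real_,
             prop_e = NA_real_, converged = NA)
}

scan_result <- function(df, model, pool, tissue) {
  structure(df, class = c("heritability_scan", "data.frame"),
            model = model, pool = pool, tissue = tissue)
}

#' Summarize a heritability scan
#'
#' Average proportions over converged wavelengths, optional per-band means,
#' and the range across wavelengths.
#'
#' @param h a `heritability_scan` from [scan_bivariate()] or
#'   [scan_univariate()].
#' @param bands optional numeric vector of band boundaries (nm); band means
#'   are reported for each interval.
#' @return list with `mean_proportions`, `range_prop_G`, `n_converged`,
#'   and (if `bands` given) a `band_means` data.frame.
#' @export
summarize_scan <- function(h, bands = NULL) {
  stopifnot(inherits(h, "heritability_scan"))
  ok <- which(h$converged %in% TRUE)
  if (!length(ok)) stop("empty scan: no converged wavelengths", call. = FALSE)
  mp <- c(G = mean(h$prop_G[ok]), GxE = mean(h$prop_GxE[ok]),
          e = mean(h$prop_e[ok]))
  out <- list(mean_proportions = mp,
              range_prop_G = range(h$prop_G[ok]),
              n_converged = length(ok),
              n_wavelengths = nrow(h))
  if (!is.null(bands)) {
    cut_id <- cut(h$wavelength, bands, include.lowest = TRUE)
    bm <- stats::aggregate(
      h[ok, c("prop_G", "prop_GxE", "prop_e"), drop = FALSE],
      by = list(band = cut_id[ok]), FUN = mean)
    out$band_means <- bm
  }
  out
}

#' Stacked-proportion plot of a heritability scan
#'
#' Draws the per-wavelength genetic / GxE / residual shares as a stacked
#' area chart (ggplot2 when available, base graphics otherwise).
#'
#' @param h a `heritability_scan`.
#' @return a ggplot object, or `NULL` (base plot drawn as a side effect).
#' @export
plot_scan <- function(h) {
  stopifnot(inherits(h, "heritability_scan"))
  ok <- h$converged %in% TRUE
  df <- h[ok, , drop = FALSE]
  gxe <- ifelse(is.na(df$prop_GxE), 0, df$prop_GxE)
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    long <- data.frame(
      wavelength = rep(df$wavelength, 3L),
      component = factor(rep(c("genetic", "GxE", "residual"), each = nrow(df)),
                         levels = c("residual", "GxE", "genetic")),
      proportion = c(df$prop_G, gxe, df$prop_e))
    ggplot2::ggplot(long, ggplot2::aes(x = .data$wavelength, y = .data$proportion,
                                       fill = .data$component)) +
      ggplot2::geom_area() +
      ggplot2::scale_fill_manual(values = c(genetic = "#d73027", GxE = "#1a9850",
                                            residual = "#4575b4")) +
      ggplot2::labs(x = "wavelength (nm)", y = "proportion of variance") +
      ggplot2::theme_minimal()
  } else {
    graphics::plot(df$wavelength, df$prop_G, type = "l", col = "red",
                   ylim = c(0, 1), xlab = "wavelength (nm)",
                   ylab = "proportion of variance")
    graphics::lines(df$wavelength, gxe, col = "darkgreen")
    graphics::lines(df$wavelength, df$prop_e, col = "blue")
    invisible(NULL)
  }
}
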