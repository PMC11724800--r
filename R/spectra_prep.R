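#' Average technical spectra within each microplot
#'
#' Collapses the within-plot technical spectra (e.g. one spot on each side
#' of the leaf midrib) to their arithmetic mean, leaving one spectrum per
#' microplot.
#'
#' @param s a [spectra_set()] in state `"raw"` with a `plot_id` column.
#' @return a `spectra_set` (still `"raw"`) with one row per plot.
#' @export
average_technical_replicates <- function(s) {
  require_state(s, "raw")
  if (all(is.na(s$meta$plot_id))) stop("meta has no plot_id; nothing to aggregate",
                                       call. = FALSE)
  if (anyNA(s$meta$plot_id)) stop("plot_id missing for some samples", call. = FALSE)
  plots <- unique(s$meta$plot_id)
  vals <- matrix(NA_real_, length(plots), ncol(s$values))
  meta <- s$meta[match(plots, s$meta$plot_id), , drop = FALSE]
  for (i in seq_along(plots)) {
    rows <- which(s$meta$plot_id == plots[i])
    if (!length(rows)) stop("plot with zero spectra: ", plots[i], call. = FALSE)
    vals[i, ] <- colMeans(s$values[rows, , drop = FALSE])
  }
  meta$sample_id <- plots
  rownames(meta) <- NULL
  spectra_set(vals, s$wavelengths, meta, state = "raw")
}

#' Spatially adjusted genotype means and heritability, per wavelength
#'
#' For every wavelength, fits the mixed model
#' `absorbance = mean + genotype + row + column + error`, with row and
#' column coordinates as random intercepts, twice: once with genotype fixed
#' (cell-means coding) to obtain adjusted genotype means, and once with
#' genotype random (identity covariance) to obtain the broad-sense
#' heritability `H2 = s2_g / (s2_g + s2_e / n_rep)`, where `n_rep` is the
#' mean number of plots per genotype. This row+column random-effects model
#' is the package's approximation of a smooth spatial surface fit.
#'
#' @param s a [spectra_set()] in state `"raw"`, one spectrum per plot, with
#'   `row` and `column` coordinates; a single trial.
#' @param genotype_as fit reported means with genotype `"fixed"` (default);
#'   heritability always comes from the genotype-`"random"` fit.
#' @return list with `spectra` (a genotype x wavelength `spectra_set` in
#'   state `"adjusted"`) and `h2` (per-wavelength broad-sense heritability;
#'   `NA` where the fit failed or the design is unreplicated).
#' @export
adjust_wavelength_means <- function(s, genotype_as = c("fixed", "random")) {
  genotype_as <- match.arg(genotype_as)
  require_state(s, "raw")
  meta <- s$meta
  if (anyNA(meta$row) || anyNA(meta$column)) {
    stop("row/column coordinates are required for spatial adjustment", call. = FALSE)
  }
  if (length(unique(meta$trial_id)) != 1L) {
    stop("adjust one trial at a time", call. = FALSE)
  }
  genos <- sort(unique(meta$genotype_id))
  n_rep <- nrow(meta) / length(genos)
  replicated <- n_rep > 1 + 1e-9
  if (!replicated) {
    warning("unreplicated design: heritability is not identifiable and is reported as NA")
  }
  Xg <- incidence_matrix(meta$genotype_id, genos)
  row_f <- as.character(meta$row)
  col_f <- as.character(meta$column)
  L <- ncol(s$values)
  adj <- matrix(NA_real_, length(genos), L, dimnames = list(genos, NULL))
  h2 <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    yl <- s$values[, l]
    fm_fix <- tryCatch(
      fit_reml(yl, list(random_effect("row", row_f), random_effect("col", col_f)),
               X = Xg),
      error = function(e) NULL)
    if (!is.null(fm_fix)) {
      adj[, l] <- fm_fix$beta
    } else {
      # spatial fit failed (e.g. no spatial variance): fall back to raw means
      adj[, l] <- drop(crossprod(Xg, yl) / colSums(Xg))
    }
    if (replicated) {
      fm_ran <- tryCatch(
        fit_reml(yl, list(random_effect("genotype", meta$genotype_id),
                          random_effect("row", row_f),
                          random_effect("col", col_f))),
        error = function(e) NULL)
      if (!is.null(fm_ran)) {
        s2g <- fm_ran$sigma2[["genotype"]]
        s2e <- fm_ran$sigma2[["residual"]]
        h2[l] <- s2g / (s2g + s2e / n_rep)
      }
    }
  }
  trial <- meta$trial_id[1L]
  out_meta <- data.frame(sample_id = paste(genos, trial, sep = "."),
                         genotype_id = genos,
                         pool = meta$pool[match(genos, meta$genotype_id)],
                         trial_id = trial, stringsAsFactors = FALSE)
  list(spectra = spectra_set(adj, s$wavelengths, out_meta, state = "adjusted"),
       h2 = h2)
}

#' Normalize spectra (standard normal variate)
#'
#' Centers and scales each spectrum (row) to mean 0 and standard deviation
#' 1 — the chemometrics SNV convention.
#'
#' @param s a [spectra_set()] in state `"adjusted"`.
#' @return a `spectra_set` in state `"normalized"`.
#' @export
normalize_spectra <- function(s) {
  require_state(s, "adjusted")
  m <- s$values
  mu <- rowMeans(m)
  sd_r <- apply(m, 1L, stats::sd)
  flat <- sd_r < 1e-12
  if (any(flat)) {
    stop("constant spectrum cannot be scaled; genotype(s): ",
         paste(s$meta$genotype_id[flat], collapse = ", "), call. = FALSE)
  }
  spectra_set((m - mu) / sd_r, s$wavelengths, s$meta, state = "normalized")
}

# central Savitzky-Golay first-derivative coefficients (signal::sgolay is in
# sample-step units; divide by the grid spacing to get d/d(wavelength))
sg_deriv_coefs <- function(window, polyorder, spacing) {
  F <- signal::sgolay(p = polyorder, n = window, m = 1)
  as.numeric(F[(window + 1L) %/% 2L, ]) / spacing
}

#' Savitzky-Golay first derivative of the spectra
#'
#' Per-row first derivative via a local least-squares polynomial of order
#' `polyorder` over a centered window. Edge points where the full window
#' does not fit are dropped, so the wavelength grid shrinks by
#' `window - 1` points. Requires a uniform wavelength grid.
#'
#' @param s a [spectra_set()] in state `"normalized"`.
#' @param window odd window size in data points (default 37).
#' @param polyorder polynomial order (default 2).
#' @return a `spectra_set` in state `"derivative"` on the retained grid,
#'   in absorbance per nm.
#' @export
savitzky_golay_first_derivative <- function(s, window = 37L, polyorder = 2L) {
  require_state(s, "normalized")
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L || window <= polyorder) {
    stop("window must be odd and greater than polyorder", call. = FALSE)
  }
  L <- ncol(s$values)
  if (window >= L) stop("window (", window, ") must be smaller than the number of wavelengths (",
                        L, ")", call. = FALSE)
  d <- diff(s$wavelengths)
  if (max(abs(d - d[1L])) > 1e-6 * d[1L]) {
    stop("non-uniform wavelength grid; resample to a uniform grid first (see resample_uniform)",
         call. = FALSE)
  }
  w <- sg_deriv_coefs(window, polyorder, d[1L])
  half <- (window - 1L) %/% 2L
  keep <- (half + 1L):(L - half)
  out <- matrix(NA_real_, nrow(s$values), length(keep))
  for (j in seq_along(keep)) {
    idx <- (keep[j] - half):(keep[j] + half)
    out[, j] <- s$values[, idx, drop = FALSE] %*% w
  }
  spectra_set(out, s$wavelengths[keep], s$meta, state = "derivative")
}

#' Resample spectra onto a uniform wavelength grid
#'
#' Linear interpolation onto `n_out` equally spaced wavelengths; used for
#' instruments whose sampling interval changes along the range, since the
#' Savitzky-Golay derivative assumes uniform spacing.
#'
#' @param s a [spectra_set()] (any state; the state is preserved).
#' @param n_out number of output wavelengths (default: the input count).
#' @return a `spectra_set` on the uniform grid.
#' @export
resample_uniform <- function(s, n_out = length(s$wavelengths)) {
  stopifnot(inherits(s, "spectra_set"))
  grid <- seq(min(s$wavelengths), max(s$wavelengths), length.out = n_out)
  out <- t(apply(s$values, 1L, function(r) {
    stats::approx(s$wavelengths, r, xout = grid)$y
  }))
  spectra_set(out, grid, s$meta, state = s$state)
}
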