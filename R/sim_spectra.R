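# moving-average smoothing along the rows' second dimension, edge-padded by
# replication so output length equals input length
smooth_along <- function(m, width) {
  if (width <= 1L) return(m)
  if (width %% 2L == 0L) width <- width + 1L
  half <- width %/% 2L
  L <- ncol(m)
  idx <- c(rep(1L, half), seq_len(L), rep(L, half))
  padded <- m[, idx, drop = FALSE]
  t(apply(padded, 1L, function(r) stats::filter(r, rep(1 / width, width), sides = 2)))[, half + seq_len(L), drop = FALSE]
}

std_cols <- function(m) {
  s <- apply(m, 2L, stats::sd)
  s[s < 1e-12] <- 1
  scale(m, center = TRUE, scale = s)
}

# residualize each column of m against the same column of every basis matrix
# (then re-standardize), so the variance parts are sample-orthogonal: with few
# founders the pool's polygenic scores are dominated by family contrasts and
# independent draws would otherwise be strongly correlated
orth_cols <- function(m, basis) {
  for (b in basis) {
    num <- colSums(m * b)
    den <- colSums(b * b)
    den[den < 1e-12] <- Inf
    m <- m - sweep(b, 2L, num / den, `*`)
  }
  std_cols(m)
}

#' Simulate multi-environment NIR spectra with genetic structure
#'
#' Per wavelength `l` and trial `t`, a genotype's absorbance is
#' `baseline_l + sqrt(h2_l) * g + sqrt(gxe_l) * d_t + sqrt(1 - h2_l - gxe_l) * e`,
#' where `g` is a polygenic score (frequency-centered genotypes times marker
#' loadings that vary smoothly along the wavelength grid), `d_t` is an
#' independent trial-specific polygenic deviation, and `e` is smooth
#' correlated residual noise. All three parts are standardized per
#' wavelength, so the genetic / GxE / residual variance shares equal the
#' configured `h2_profile` and `gxe_profile` by construction.
#'
#' With `layout = TRUE` each trial gets a field layout: a fraction of the
#' genotypes is grown in two plots, plots are arranged on a grid, and
#' additive random row and column effects plus per-plot noise are added
#' (state `"raw"`, for testing the spatial adjustment). With
#' `layout = FALSE` one genotype-level spectrum per trial is emitted
#' directly (state `"adjusted"`).
#'
#' @param geno a [geno_matrix()] of a single pool.
#' @param cfg a [sim_config()] supplying the wavelength grid and profiles.
#' @param seed RNG seed.
#' @param layout simulate plot-level spectra with spatial trend?
#' @param prop_replicated fraction of genotypes grown in two plots
#'   (`layout = TRUE`).
#' @param spatial_sd standard deviation of the row and column effects.
#' @param plot_sd standard deviation of per-plot, per-wavelength noise.
#' @param n_tech technical spectra per plot (>1 adds small technical noise;
#'   only with `layout = TRUE`).
#' @param tech_sd technical noise standard deviation.
#' @return a [spectra_set()]; attribute `true_genetic` holds the genotype x
#'   wavelength matrix of true genetic values `sqrt(h2_l) * g`.
#' @export
simulate_spectra <- function(geno, cfg, seed = child_seed(cfg$seed, 5L),
                             layout = FALSE, prop_replicated = 0.5,
                             spatial_sd = 0.5, plot_sd = 0.3,
                             n_tech = 1L, tech_sd = 0.05) {
  cfg <- validate_sim_config(cfg)
  stopifnot(inherits(geno, "geno_matrix"))
  wl <- cfg$wavelength_grid
  L <- length(wl)
  h2 <- rep(cfg$h2_profile, length.out = L)
  gxe <- rep(cfg$gxe_profile, length.out = L)
  n <- nrow(geno$geno)
  ids <- rownames(geno$geno)
  pool <- geno$pool[1L]
  C <- sweep(geno$geno, 2L, allele_freq(geno))

  with_seed(seed, {
    poly_score <- function() {
      W <- smooth_along(matrix(stats::rnorm(ncol(C) * L), ncol(C), L), cfg$smooth_width)
      std_cols(C %*% W)
    }
    baseline <- 1 + drop(smooth_along(matrix(stats::rnorm(L), 1L, L),
                                      max(cfg$smooth_width, 15L))) * 0.2
    g <- poly_score()
    true_gen <- sweep(g, 2L, sqrt(h2), `*`)
    rownames(true_gen) <- ids

    g_std <- std_cols(g)
    sets <- vector("list", cfg$n_trials)
    for (t in seq_len(cfg$n_trials)) {
      d_t <- if (any(gxe > 0)) orth_cols(poly_score(), list(g_std)) else matrix(0, n, L)
      geno_level <- sweep(true_gen, 2L, baseline, `+`) +
        sweep(d_t, 2L, sqrt(gxe), `*`)
      trial <- sprintf("trial%d", t)
      if (!layout) {
        e_t <- orth_cols(smooth_along(matrix(stats::rnorm(n * L), n, L), cfg$smooth_width),
                         list(g_std, d_t))
        vals <- geno_level + sweep(e_t, 2L, sqrt(pmax(1 - h2 - gxe, 0)), `*`)
        meta <- data.frame(sample_id = paste(ids, trial, sep = "."),
                           genotype_id = ids, pool = pool, trial_id = trial,
                           stringsAsFactors = FALSE)
        sets[[t]] <- spectra_set(vals, wl, meta, state = "adjusted")
      } else {
        n_rep2 <- round(prop_replicated * n)
        rep2 <- sample(ids, n_rep2)
        plot_geno <- c(ids, rep2)
        replicate <- c(rep(1L, n), rep(2L, n_rep2))
        n_plots <- length(plot_geno)
        ord <- sample.int(n_plots)
        plot_geno <- plot_geno[ord]; replicate <- replicate[ord]
        n_col <- ceiling(sqrt(n_plots))
        row_i <- ((seq_len(n_plots) - 1L) %/% n_col) + 1L
        col_i <- ((seq_len(n_plots) - 1L) %% n_col) + 1L
        row_eff <- stats::rnorm(max(row_i), 0, spatial_sd)
        col_eff <- stats::rnorm(max(col_i), 0, spatial_sd)
        base_vals <- geno_level[plot_geno, , drop = FALSE] +
          row_eff[row_i] + col_eff[col_i] +
          matrix(stats::rnorm(n_plots * L, 0, plot_sd), n_plots, L)
        e_res <- std_cols(smooth_along(matrix(stats::rnorm(n_plots * L), n_plots, L),
                                       cfg$smooth_width))
        base_vals <- base_vals + sweep(e_res, 2L, sqrt(pmax(1 - h2 - gxe, 0)), `*`)
        plot_id <- sprintf("%s_p%03d", trial, seq_len(n_plots))
        reps <- max(1L, as.integer(n_tech))
        vals <- base_vals[rep(seq_len(n_plots), each = reps), , drop = FALSE]
        if (reps > 1L) {
          vals <- vals + matrix(stats::rnorm(length(vals), 0, tech_sd), nrow(vals))
        }
        meta <- data.frame(
          sample_id = paste0(rep(plot_id, each = reps), "_t", rep(seq_len(reps), n_plots)),
          genotype_id = rep(plot_geno, each = reps), pool = pool,
          trial_id = trial, row = rep(row_i, each = reps),
          column = rep(col_i, each = reps), replicate = rep(replicate, each = reps),
          plot_id = rep(plot_id, each = reps), stringsAsFactors = FALSE)
        sets[[t]] <- spectra_set(vals, wl, meta, state = "raw")
      }
    }
    out <- if (cfg$n_trials == 1L) sets[[1L]] else {
      spectra_set(do.call(rbind, lapply(sets, `[[`, "values")), wl,
                  do.call(rbind, lapply(sets, `[[`, "meta")),
                  state = sets[[1L]]$state)
    }
    attr(out, "true_genetic") <- true_gen
    out
  })
}
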