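make_raw <- function(vals, geno = paste0("g", seq_len(nrow(vals))),
                     plot = geno, row = NA, column = NA, trial = "t1") {
  meta <- data.frame(sample_id = paste0("s", seq_len(nrow(vals))),
                     genotype_id = geno, trial_id = trial, plot_id = plot,
                     row = row, column = column, stringsAsFactors = FALSE)
  spectra_set(vals, seq_len(ncol(vals)) * 10 + 990, meta, state = "raw")
}

test_that("technical replicate averaging equals per-wavelength column means", {
  v <- matrix(rnorm(5 * 8), 5, 8)
  s <- make_raw(v, geno = c("g1", "g1", "g1", "g2", "g2"),
                plot = c("p1", "p1", "p1", "p2", "p2"))
  avg <- average_technical_replicates(s)
  expect_equal(avg$values[1, ], colMeans(v[1:3, ]))
  expect_equal(avg$values[2, ], colMeans(v[4:5, ]))
  # idempotent on identical spectra; mean symmetry v / -v
  dup <- make_raw(rbind(v[1, ], v[1, ]), geno = c("g1", "g1"), plot = c("p", "p"))
  expect_equal(average_technical_replicates(dup)$values[1, ], v[1, ])
  sym <- make_raw(rbind(v[1, ], -v[1, ]), geno = c("g1", "g1"), plot = c("p", "p"))
  expect_equal(average_technical_replicates(sym)$values[1, ], rep(0, 8))
})

test_that("pipeline state tags enforce the preprocessing order", {
  v <- matrix(rnorm(3 * 50), 3, 50)
  s_adj <- spectra_set(v, seq(1000, 1490, by = 10),
                       data.frame(sample_id = paste0("s", 1:3),
                                  genotype_id = paste0("g", 1:3), trial_id = "t1"),
                       state = "adjusted")
  expect_error(average_technical_replicates(s_adj), "state")
  expect_error(savitzky_golay_first_derivative(s_adj, window = 5), "state")
  norm <- normalize_spectra(s_adj)
  expect_error(normalize_spectra(norm), "state")
  expect_s3_class(savitzky_golay_first_derivative(norm, window = 5), "spectra_set")
})

test_that("normalization is SNV: per-row mean 0, sd 1, affine invariant", {
  v <- matrix(rnorm(4 * 30, mean = 3, sd = 2), 4, 30)
  s <- spectra_set(v, seq_len(30),
                   data.frame(sample_id = paste0("s", 1:4),
                              genotype_id = paste0("g", 1:4), trial_id = "t1"),
                   state = "adjusted")
  n1 <- normalize_spectra(s)
  expect_equal(unname(rowMeans(n1$values)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(n1$values, 1, sd)), rep(1, 4), tolerance = 1e-12)
  s_aff <- s; s_aff$values <- 1.7 * v - 4
  expect_equal(normalize_spectra(s_aff)$values, n1$values, tolerance = 1e-12)
  # worked 5-point row against the direct formula
  r <- c(1, 2, 3, 4, 10)
  s5 <- spectra_set(matrix(r, 1), 1:5,
                    data.frame(sample_id = "s", genotype_id = "g", trial_id = "t"),
                    state = "adjusted")
  expect_equal(drop(normalize_spectra(s5)$values), (r - mean(r)) / sd(r))
  s_flat <- s; s_flat$values[2, ] <- 7
  expect_error(normalize_spectra(s_flat), "g2")
})

test_that("SG first derivative is exact on quadratics and drops edges", {
  L <- 101
  wl <- seq(1000, 2000, length.out = L)
  a <- 0.3; b <- -0.002; cc <- 1e-6
  v <- a + b * wl + cc * wl^2
  s <- spectra_set(rbind(v, v), wl,
                   data.frame(sample_id = c("s1", "s2"),
                              genotype_id = c("g1", "g2"), trial_id = "t"),
                   state = "normalized")
  d <- savitzky_golay_first_derivative(s, window = 37, polyorder = 2)
  expect_equal(length(d$wavelengths), L - 36)
  expect_equal(d$wavelengths, wl[19:(L - 18)])
  expect_equal(unname(d$values[1, ]), b + 2 * cc * d$wavelengths, tolerance = 1e-9)
  # constant row -> zero derivative
  s0 <- s; s0$values <- matrix(5, 2, L)
  expect_equal(max(abs(savitzky_golay_first_derivative(s0, 37, 2)$values)), 0,
               tolerance = 1e-12)
})

test_that("SG derivative matches a per-point local polynomial fit oracle", {
  set.seed(14)
  L <- 40
  wl <- seq(1, L) * 2
  v <- rnorm(L)
  s <- spectra_set(matrix(v, 1), wl,
                   data.frame(sample_id = "s", genotype_id = "g", trial_id = "t"),
                   state = "normalized")
  d <- savitzky_golay_first_derivative(s, window = 5, polyorder = 2)
  # oracle: weighted least squares quadratic at each retained point
  oracle <- sapply(3:(L - 2), function(i) {
    idx <- (i - 2):(i + 2)
    x <- wl[idx] - wl[i]
    fit <- lm(v[idx] ~ x + I(x^2))
    unname(coef(fit)[2])
  })
  expect_equal(unname(drop(d$values)), oracle, tolerance = 1e-9)
})

test_that("SG derivative is a linear operator", {
  set.seed(2)
  L <- 60
  wl <- seq_len(L)
  u <- rnorm(L); v <- rnorm(L)
  mk <- function(m) spectra_set(m, wl,
    data.frame(sample_id = paste0("s", seq_len(nrow(m))),
               genotype_id = paste0("g", seq_len(nrow(m))), trial_id = "t"),
    state = "normalized")
  D <- function(m) savitzky_golay_first_derivative(mk(m), window = 7, polyorder = 2)$values
  expect_equal(D(rbind(2.5 * u - 1.3 * v)), 2.5 * D(rbind(u)) - 1.3 * D(rbind(v)),
               tolerance = 1e-9)
})

test_that("SG derivative refuses non-uniform grids and oversized windows", {
  wl <- c(seq(1, 30), seq(32, 60, by = 2))
  v <- matrix(rnorm(length(wl)), 1)
  s <- spectra_set(v, wl, data.frame(sample_id = "s", genotype_id = "g",
                                     trial_id = "t"), state = "normalized")
  expect_error(savitzky_golay_first_derivative(s, window = 5), "uniform")
  u <- resample_uniform(s)
  expect_silent(savitzky_golay_first_derivative(u, window = 5))
  s2 <- spectra_set(matrix(rnorm(11), 1), 1:11,
                    data.frame(sample_id = "s", genotype_id = "g", trial_id = "t"),
                    state = "normalized")
  expect_error(savitzky_golay_first_derivative(s2, window = 37), "smaller")
  expect_error(savitzky_golay_first_derivative(s2, window = 4), "odd")
})

test_that("spatial adjustment recovers genotype means in the balanced no-trend case", {
  set.seed(7)
  n_g <- 12
  geno <- rep(paste0("g", seq_len(n_g)), each = 2)
  mu_g <- rnorm(n_g, sd = 2)
  v <- matrix(mu_g[rep(seq_len(n_g), each = 2)] + rnorm(2 * n_g, sd = 0.3), ncol = 1)
  v <- cbind(v, v + 1)  # two wavelengths
  s <- make_raw(v, geno = geno, plot = paste0("p", seq_along(geno)),
                row = rep(1:6, each = 4), column = rep(1:4, 6))
  res <- adjust_wavelength_means(s)
  adj <- spectra_matrix(res$spectra)
  raw_means <- tapply(v[, 1], geno, mean)
  expect_equal(unname(adj[names(raw_means), 1]),
               as.numeric(raw_means), tolerance = 1e-6)
  expect_equal(res$spectra$state, "adjusted")
})

test_that("spatial adjustment removes an additive row trend", {
  set.seed(19)
  n_g <- 30
  genos <- paste0("g", seq_len(n_g))
  true_g <- rnorm(n_g)
  geno <- rep(genos, each = 2)
  n <- length(geno)
  ord <- sample(n)
  geno <- geno[ord]
  n_col <- 10
  row_i <- (seq_len(n) - 1) %/% n_col + 1
  col_i <- (seq_len(n) - 1) %% n_col + 1
  row_eff <- (seq_len(max(row_i)) - mean(seq_len(max(row_i)))) * 1.5
  y <- true_g[match(geno, genos)] + row_eff[row_i] + rnorm(n, sd = 0.2)
  s <- make_raw(matrix(y, ncol = 1), geno = geno, plot = paste0("p", seq_len(n)),
                row = row_i, column = col_i)
  res <- adjust_wavelength_means(s)
  adj <- spectra_matrix(res$spectra)[genos, 1]
  raw <- tapply(y, geno, mean)[genos]
  expect_gt(cor(adj, true_g), cor(raw, true_g))
  # heritability from the genotype-random fit is defined and in [0, 1]
  expect_true(res$h2[1] >= 0 && res$h2[1] <= 1)
})

test_that("adjusted means are invariant to sample order and match lme4", {
  skip_if_not_installed("lme4")
  set.seed(3)
  n_g <- 15
  genos <- paste0("g", seq_len(n_g))
  geno <- rep(genos, each = 2)
  n <- length(geno)
  row_i <- (seq_len(n) - 1) %/% 5 + 1
  col_i <- (seq_len(n) - 1) %% 5 + 1
  y <- rnorm(n_g)[match(geno, genos)] + 0.8 * rnorm(max(row_i))[row_i] + rnorm(n, sd = 0.3)
  s <- make_raw(matrix(y, ncol = 1), geno = geno, plot = paste0("p", seq_len(n)),
                row = row_i, column = col_i)
  res <- adjust_wavelength_means(s)
  perm <- sample(n)
  s2 <- make_raw(matrix(y[perm], ncol = 1), geno = geno[perm],
                 plot = paste0("p", seq_len(n))[perm], row = row_i[perm],
                 column = col_i[perm])
  res2 <- adjust_wavelength_means(s2)
  expect_equal(res$spectra$values, res2$spectra$values, tolerance = 1e-6)
  # independent oracle: lme4 genotype-random fit gives the same components
  fm_pkg <- fit_reml(y, list(random_effect("genotype", geno),
                             random_effect("row", as.character(row_i)),
                             random_effect("col", as.character(col_i))))
  lmer_fit <- lme4::lmer(y ~ (1 | g) + (1 | r) + (1 | cl),
                         data = data.frame(y = y, g = geno, r = factor(row_i),
                                           cl = factor(col_i)), REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lmer_fit))
  lmer_s2 <- setNames(vc$vcov, vc$grp)
  expect_equal(unname(fm_pkg$sigma2["genotype"]), unname(lmer_s2["g"]), tolerance = 1e-3)
  expect_equal(unname(fm_pkg$sigma2["residual"]), unname(lmer_s2["Residual"]), tolerance = 1e-3)
})

test_that("null genotype variance yields near-zero heritability", {
  # the REML genotype variance is floored at zero, so single-wavelength null
  # estimates have a positive truncation tail; the bulk of the distribution
  # must still sit at (numerical) zero
  set.seed(77)
  n_g <- 100
  genos <- paste0("g", seq_len(n_g))
  geno <- rep(genos, each = 2)
  n <- length(geno)
  row_i <- (seq_len(n) - 1) %/% 20 + 1
  col_i <- (seq_len(n) - 1) %% 20 + 1
  y <- matrix(rnorm(n * 12), n, 12)  # 12 null wavelengths, no genotype signal
  s <- make_raw(y, geno = geno, plot = paste0("p", seq_len(n)),
                row = row_i, column = col_i)
  res <- adjust_wavelength_means(s)
  expect_lt(median(res$h2), 0.05)
  expect_lt(mean(res$h2), 0.15)
})

test_that("unreplicated designs warn and report heritability as missing", {
  set.seed(5)
  n <- 20
  s <- make_raw(matrix(rnorm(n), ncol = 1), geno = paste0("g", 1:n),
                plot = paste0("p", 1:n), row = rep(1:4, each = 5),
                column = rep(1:5, 4))
  expect_warning(res <- adjust_wavelength_means(s), "unreplicated")
  expect_true(is.na(res$h2[1]))
})
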