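# simulate a small single-kernel dataset with known components
sim_single <- function(n, s2g, s2e, seed) {
  set.seed(seed)
  ids <- paste0("g", seq_len(n))
  K <- unclass(random_kernel(ids, seed = seed + 1))
  u <- drop(crossprod(chol(K + diag(1e-8, n)), rnorm(n))) * sqrt(s2g)
  y <- 2 + u + rnorm(n, sd = sqrt(s2e))
  list(y = y, ids = ids, K = kernel_matrix(K, source = "genomic", role = "GCA_dent"))
}

test_that("fit_reml matches an exhaustive grid search (one kernel)", {
  d <- sim_single(25, s2g = 1, s2e = 0.5, seed = 100)
  fm <- fit_reml(d$y, list(random_effect("g", d$ids, d$K)))
  vy <- var(d$y)
  grid <- seq(vy / 200, 3 * vy, length.out = 200)
  ll <- outer(grid, grid, Vectorize(function(a, b) {
    reml_loglik(c(a, b), d$y, list(random_effect("g", d$ids, d$K)))
  }))
  best <- arrayInd(which.max(ll), dim(ll))
  step <- diff(grid[1:2])
  expect_lt(abs(fm$sigma2[["g"]] - grid[best[1]]), step)
  expect_lt(abs(fm$sigma2[["residual"]] - grid[best[2]]), step)
  expect_gte(fm$loglik, max(ll) - 1e-6)
})

test_that("fit_reml matches a grid search with two kernels", {
  set.seed(200)
  n <- 24
  ids <- paste0("g", seq_len(n))
  K1 <- random_kernel(ids, seed = 7)
  K2 <- random_kernel(ids, seed = 8, role = "GCA_flint")
  u1 <- drop(crossprod(chol(unclass(K1) + diag(1e-8, n)), rnorm(n)))
  u2 <- drop(crossprod(chol(unclass(K2) + diag(1e-8, n)), rnorm(n))) * sqrt(0.5)
  y <- u1 + u2 + rnorm(n, sd = 0.8)
  effects <- list(random_effect("a", ids, K1), random_effect("b", ids, K2))
  fm <- fit_reml(y, effects)
  vy <- var(y)
  grid <- seq(vy / 60, 2.5 * vy, length.out = 60)
  best_ll <- -Inf; best <- NULL
  for (a in grid) for (b in grid) for (e in grid) {
    l <- reml_loglik(c(a, b, e), y, effects)
    if (l > best_ll) { best_ll <- l; best <- c(a, b, e) }
  }
  step <- diff(grid[1:2])
  expect_true(all(abs(unname(fm$sigma2) - best) < 2 * step))
  expect_gte(fm$loglik, best_ll - 1e-6)
})

test_that("constant response collapses to the zero-variance solution", {
  ids <- paste0("g", 1:12)
  K <- random_kernel(ids, seed = 5)
  fm <- fit_reml(rep(3.7, 12), list(random_effect("g", ids, K)))
  expect_equal(fm$mu, 3.7)
  expect_equal(unname(fm$sigma2), c(0, 0))
  expect_true(fm$converged)
})

test_that("the REML solution dominates random admissible parameter vectors", {
  d <- sim_single(20, s2g = 0.8, s2e = 1.2, seed = 300)
  effects <- list(random_effect("g", d$ids, d$K))
  fm <- fit_reml(d$y, effects)
  set.seed(301)
  vy <- var(d$y)
  for (i in 1:50) {
    theta <- runif(2, 1e-4, 3 * vy)
    expect_gte(fm$loglik + 1e-7, reml_loglik(theta, d$y, effects))
  }
})

test_that("restricted likelihood is non-decreasing over accepted iterations", {
  d <- sim_single(30, s2g = 1, s2e = 1, seed = 400)
  fm <- fit_reml(d$y, list(random_effect("g", d$ids, d$K)))
  lls <- fm$trace[, "logREML"]
  expect_true(all(diff(lls) > -1e-8))
  expect_true(all(fm$sigma2 >= 0))
})

test_that("an effect estimated at the zero floor leaves the fit unchanged", {
  d <- sim_single(40, s2g = 1.5, s2e = 0.5, seed = 500)
  fm1 <- fit_reml(d$y, list(random_effect("g", d$ids, d$K)))
  # add an unrelated second kernel carrying no signal
  K0 <- random_kernel(d$ids, seed = 999, role = "GCA_flint")
  fm2 <- fit_reml(d$y, list(random_effect("g", d$ids, d$K),
                            random_effect("noise", d$ids, K0)))
  if (fm2$sigma2[["noise"]] < 1e-6 * var(d$y)) {
    expect_equal(fm2$mu, fm1$mu, tolerance = 1e-4)
    expect_equal(fm2$sigma2[["g"]], fm1$sigma2[["g"]], tolerance = 2e-2)
    p1 <- predict_hybrids(fm1, data.frame(g = d$ids))
    p2 <- predict_hybrids(fm2, data.frame(g = d$ids, noise = d$ids))
    expect_equal(p1, p2, tolerance = 1e-2)
  } else {
    succeed("noise variance not floored on this draw; nesting not applicable")
  }
})

test_that("predictions equal the mixed-model-equations solution", {
  d <- sim_single(18, s2g = 1, s2e = 0.7, seed = 600)
  ids_train <- d$ids[1:14]
  ids_new <- d$ids[15:18]
  y <- d$y[1:14]
  fm <- fit_reml(y, list(random_effect("g", ids_train, d$K)))
  pred <- predict_hybrids(fm, data.frame(g = ids_new))
  # MME oracle at the estimated components:
  # [1'R^-1 1, 1'R^-1 Z; Z'R^-1 1, Z'R^-1 Z + (K sigma_g^2)^-1] [mu; u] = [1'R^-1 y; Z'R^-1 y]
  s2g <- fm$sigma2[["g"]]; s2e <- fm$sigma2[["residual"]]
  Kfull <- unclass(d$K)
  Z <- diag(1, 14)  # one obs per training level
  Ktr <- Kfull[ids_train, ids_train]
  lhs <- rbind(cbind(14 / s2e, t(rep(1, 14)) %*% Z / s2e),
               cbind(Z %*% rep(1, 14) / s2e, crossprod(Z) / s2e + solve(Ktr * s2g)))
  rhs <- c(sum(y) / s2e, crossprod(Z, y) / s2e)
  sol <- solve(lhs, rhs)
  mu_mme <- unname(sol[1]); u_mme <- unname(sol[-1])
  expect_equal(unname(fm$mu), mu_mme, tolerance = 1e-5)
  expect_equal(unname(fm$blups$g[ids_train]), u_mme, tolerance = 1e-5)
  # new-level BLUPs extend via the kernel: u_new = K[new, train] Ktr^-1 u_train
  u_new <- Kfull[ids_new, ids_train] %*% solve(Ktr, u_mme)
  expect_equal(pred, unname(drop(mu_mme + u_new)), tolerance = 1e-5)
})

test_that("prediction falls back to the intercept with zero kernel covariance", {
  ids <- paste0("g", 1:10)
  K <- matrix(0, 12, 12, dimnames = list(c(ids, "n1", "n2"), c(ids, "n1", "n2")))
  diag(K) <- 1
  K[1:10, 1:10] <- unclass(random_kernel(ids, seed = 9))
  K <- (K + t(K)) / 2
  kk <- kernel_matrix(K, source = "genomic", role = "GCA_dent")
  set.seed(10)
  y <- rnorm(10) + 5
  fm <- fit_reml(y, list(random_effect("g", ids, kk)))
  pred <- predict_hybrids(fm, data.frame(g = c("n1", "n2")))
  expect_equal(pred, rep(fm$mu, 2), tolerance = 1e-10)
  expect_error(predict_hybrids(fm, data.frame(g = "unknown_level")), "unknown_level")
})

test_that("with vanishing error variance training predictions approach the data", {
  # noise-free response drawn from the kernel: REML drives s2e to the floor
  set.seed(700)
  n <- 20
  ids <- paste0("g", seq_len(n))
  K <- random_kernel(ids, seed = 701)
  u <- drop(crossprod(chol(unclass(K) + diag(1e-8, n)), rnorm(n)))
  y <- 1 + u
  fm <- fit_reml(y, list(random_effect("g", ids, K)))
  pred <- predict_hybrids(fm, data.frame(g = ids))
  expect_gt(cor(pred, y), 0.999)
  expect_lt(fm$sigma2[["residual"]], 0.05 * var(y))
  # BLUP consistency: training predictions equal the stored combination
  expect_equal(pred, unname(fm$mu + fm$blups$g[ids]), tolerance = 1e-12)
})

test_that("parameter recovery is approximately unbiased on factorial data", {
  # moderate-size check: full conditions are exercised in the acceptance suite
  est <- sapply(1:3, function(s) {
    dat <- simulate_dataset(sim_config_maize(seed = s + 40))
    kb <- genomic_kernel_bundle(dat, scale = FALSE)
    hyb <- dat$design$hybrids
    y <- setNames(dat$phenotypes$value, dat$phenotypes$hybrid_id)
    fit_reml(y[hyb$hybrid_id], list(
      random_effect("gca_d", hyb$dent_parent, kb$dent),
      random_effect("gca_f", hyb$flint_parent, kb$flint),
      random_effect("sca", hyb$hybrid_id, kb$sca)))$sigma2
  })
  m <- rowMeans(est)
  expect_lt(abs(m[["gca_d"]] - 1), 0.45)
  expect_lt(abs(m[["residual"]] - 1), 0.45)
})
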