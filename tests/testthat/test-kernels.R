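test_that("marker QC matches a hand-enumerated rule set", {
  # 10 markers with constructed violations, one pool of 20 dent lines
  set.seed(8)
  n <- 20
  geno <- matrix(rep(c(0, 1), length.out = n * 10), n, 10)  # MAF 0.5 baseline
  colnames(geno) <- paste0("m", 1:10)
  rownames(geno) <- paste0("l", 1:n)
  geno[1:6, 1] <- NA               # m1: 30% missing -> drop
  geno[, 2] <- c(1, rep(0, n - 1)) # m2: MAF 0.05 -> keep (boundary)
  geno[, 3] <- rep(0, n)           # m3: MAF 0 -> drop
  geno[1:2, 4] <- 0.5              # m4: 10% het > 5% dent limit -> drop
  geno[1, 5] <- 0.5                # m5: 5% het -> keep
  geno[1:3, 6] <- NA               # m6: 15% missing -> keep
  map <- data.frame(marker = colnames(geno), chrom = 1, pos_cM = 1:10)
  g <- geno_matrix(geno, rep("dent", n), map)
  out <- filter_markers(g)
  expect_setequal(colnames(out$geno), c("m2", "m5", "m6", "m7", "m8", "m9", "m10"))
  audit <- attr(out, "filter_audit")
  expect_equal(unname(audit["n_input"]), 10)
  expect_equal(unname(audit["n_kept"]), 7)
  # all markers removed -> error with audit
  g_mono <- geno_matrix(matrix(0, n, 2, dimnames = list(rownames(geno), c("a", "b"))),
                        rep("dent", n), data.frame(marker = c("a", "b"), chrom = 1,
                                                   pos_cM = 1:2))
  expect_error(filter_markers(g_mono), "all markers removed")
})

test_that("imputation fills missing calls with the pool allele frequency", {
  geno <- matrix(c(0, 1, NA,
                   1, 1, 0,
                   NA, 0.5, 0), 3, 3, byrow = FALSE)
  dimnames(geno) <- list(paste0("l", 1:3), paste0("m", 1:3))
  map <- data.frame(marker = colnames(geno), chrom = 1, pos_cM = 1:3)
  g <- geno_matrix(geno, rep("dent", 3), map)
  imp <- impute_missing(g)
  expect_equal(imp$geno[3, "m1"], 0.5)        # mean of (0, 1)
  expect_equal(imp$geno[1, "m3"], 0.25)       # mean of (0.5, 0)
  expect_false(anyNA(imp$geno))
  # idempotence on complete data
  expect_identical(impute_missing(imp)$geno, imp$geno)
  # column means unchanged by imputation
  set.seed(4)
  big <- matrix(sample(c(0, 0.5, 1), 600, replace = TRUE), 30, 20,
                dimnames = list(paste0("l", 1:30), paste0("m", 1:20)))
  big[sample(length(big), 30)] <- NA
  gb <- geno_matrix(big, rep("dent", 30),
                    data.frame(marker = colnames(big), chrom = 1, pos_cM = 1:20))
  before <- colMeans(big, na.rm = TRUE)
  after <- colMeans(impute_missing(gb)$geno)
  expect_equal(after, before, tolerance = 1e-12)
})

test_that("VanRaden kinship matches the double-loop oracle", {
  set.seed(11)
  for (rep in 1:3) {
    n <- 10; M <- 20
    geno <- matrix(sample(c(0, 1), n * M, replace = TRUE, prob = c(0.4, 0.6)), n, M,
                   dimnames = list(paste0("l", 1:n), paste0("m", 1:M)))
    # ensure polymorphism
    geno[1, ] <- 0; geno[2, ] <- 1
    g <- geno_matrix(geno, rep("dent", n),
                     data.frame(marker = colnames(geno), chrom = 1, pos_cM = 1:M))
    K <- as.matrix(vanraden_gca_kinship(g))
    f <- colMeans(geno)
    denom <- sum(f * (1 - f))
    oracle <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      oracle[i, j] <- sum((geno[i, ] - f) * (geno[j, ] - f)) / denom
    }
    expect_equal(unname(K), oracle, tolerance = 1e-12)
  }
})

test_that("VanRaden kinship has the expected structural properties", {
  set.seed(12)
  n <- 8; M <- 30
  geno <- matrix(sample(c(0, 1), n * M, replace = TRUE), n, M,
                 dimnames = list(paste0("l", 1:n), paste0("m", 1:M)))
  geno[2, ] <- geno[1, ]  # two identical lines
  g <- geno_matrix(geno, rep("dent", n),
                   data.frame(marker = colnames(geno), chrom = 1, pos_cM = 1:M))
  g <- filter_markers(g, min_maf = 1e-9)
  K <- as.matrix(vanraden_gca_kinship(g))
  expect_equal(K[1, 2], K[1, 1])
  expect_equal(K[1, 2], K[2, 2])
  expect_equal(K, t(K), tolerance = 1e-12)
  # a line sitting exactly at the allele frequencies has a zero row
  f <- allele_freq(g)
  geno2 <- rbind(g$geno, at_freq = f)
  g2 <- geno_matrix(round(geno2 * 2) / 2, rep("dent", n + 1), g$map)
  g2$geno <- geno2  # fractional row allowed internally for this check
  K2 <- as.matrix(vanraden_gca_kinship(structure(g2, class = "geno_matrix")))
  expect_equal(unname(K2["at_freq", ]), rep(0, n + 1), tolerance = 1e-10)
  # monomorphic marker triggers the filtering-violated error
  g_bad <- g; g_bad$geno[, 1] <- 1
  expect_error(vanraden_gca_kinship(g_bad), "filtering violated")
})

test_that("spectral H matrix matches the explicit product oracle", {
  set.seed(13)
  m <- matrix(rnorm(3 * 5), 3, 5, dimnames = list(paste0("g", 1:3), NULL))
  H <- as.matrix(spectral_relationship(m))
  S <- scale(m)  # centered, unit variance columns
  L <- 5
  oracle <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) oracle[i, j] <- sum(S[i, ] * S[j, ]) / L
  expect_equal(unname(H), oracle, tolerance = 1e-12)
  # orthogonal rows of squared norm L -> identity
  Sstar <- rbind(c(2, 0, 0, 0), c(0, 2, 0, 0), c(0, 0, 2, 0))
  # construct data whose scaled matrix is Sstar: use it directly via tcrossprod
  expect_equal(tcrossprod(Sstar) / 4, diag(3))
  # duplicated genotype rows give identical kernel rows
  m2 <- rbind(m, g4 = m[1, ])
  H2 <- as.matrix(spectral_relationship(m2))
  expect_equal(H2["g4", ], H2["g1", ], tolerance = 1e-12)
  # zero-variance wavelength dropped with warning
  m3 <- cbind(m, 7)
  expect_warning(H3 <- spectral_relationship(m3), "zero-variance")
  expect_equal(as.matrix(H3), H, tolerance = 1e-12)
})

test_that("SCA kernel is the entrywise product of parental kernels", {
  kd <- kernel_matrix(matrix(c(1, 0.5, 0.5, 1), 2, 2,
                             dimnames = list(c("d1", "d2"), c("d1", "d2"))),
                      source = "genomic", role = "GCA_dent")
  kf <- kernel_matrix(matrix(c(1.2, -0.3, -0.3, 0.8), 2, 2,
                             dimnames = list(c("f1", "f2"), c("f1", "f2"))),
                      source = "genomic", role = "GCA_flint")
  des <- toy_design()  # h1 = d1xf1, h2 = d1xf2, h3 = d2xf2
  Ks <- as.matrix(sca_kernel(kd, kf, des))
  hand <- matrix(c(1 * 1.2,   1 * -0.3,  0.5 * -0.3,
                   1 * -0.3,  1 * 0.8,   0.5 * 0.8,
                   0.5 * -0.3, 0.5 * 0.8, 1 * 0.8), 3, 3, byrow = TRUE)
  expect_equal(unname(Ks), hand, tolerance = 1e-12)
  expect_equal(rownames(Ks), c("h1", "h2", "h3"))
  # diagonal is the product of parental diagonals
  expect_equal(Ks["h3", "h3"], kd["d2", "d2"] * kf["f2", "f2"])
  # unrelated parent pair zeroes all its SCA entries
  kd0 <- kernel_matrix(matrix(c(1, 0, 0, 1), 2, 2,
                              dimnames = list(c("d1", "d2"), c("d1", "d2"))),
                       source = "genomic", role = "GCA_dent")
  Ks0 <- as.matrix(sca_kernel(kd0, kf, des))
  expect_equal(Ks0["h1", "h3"], 0)  # crosses d1 vs d2
  # missing parent is a keyed error
  kf_small <- kernel_matrix(matrix(1, 1, 1, dimnames = list("f1", "f1")),
                            source = "genomic", role = "GCA_flint")
  expect_error(sca_kernel(kd, kf_small, des), "f2")
  # mixed sources refused
  kp <- kernel_matrix(as.matrix(kf), source = "pedigree", role = "GCA_flint")
  expect_error(sca_kernel(kd, kp, des), "source")
})

test_that("SCA kernel of a complete factorial is the Kronecker product", {
  ids_d <- paste0("d", 1:3); ids_f <- paste0("f", 1:3)
  kd <- random_kernel(ids_d, seed = 1, role = "GCA_dent")
  kf <- random_kernel(ids_f, seed = 2, role = "GCA_flint")
  hyb <- expand.grid(flint_parent = ids_f, dent_parent = ids_d,
                     stringsAsFactors = FALSE)[, 2:1]
  hyb$hybrid_id <- paste0(hyb$dent_parent, hyb$flint_parent)
  des <- factorial_design(hyb, setNames(rep("a", 3), ids_d),
                          setNames(rep("b", 3), ids_f))
  Ks <- as.matrix(sca_kernel(kd, kf, des))
  expect_equal(unname(Ks), kronecker(as.matrix(kd), as.matrix(kf)), tolerance = 1e-12)
})

test_that("unit-variance scaling produces entry variance 1 and is idempotent", {
  K <- random_kernel(paste0("x", 1:6), seed = 3)
  Ks <- scale_unit_variance(K)
  expect_equal(var(as.vector(as.matrix(Ks))), 1, tolerance = 1e-10)
  expect_true(attr(Ks, "scaled"))
  expect_identical(as.matrix(scale_unit_variance(Ks)), as.matrix(Ks))
  # scale factor equals the direct standard deviation of the entries
  expect_equal(as.matrix(Ks), as.matrix(K) / sd(as.vector(as.matrix(K))), tolerance = 1e-14)
  flat <- kernel_matrix(matrix(2, 3, 3, dimnames = list(letters[1:3], letters[1:3])),
                        source = "genomic", role = "SCA")
  expect_error(scale_unit_variance(flat), "constant")
})

test_that("kernels from the pipeline are symmetric and PSD after repair", {
  dat <- small_dataset()
  kb <- genomic_kernel_bundle(dat)
  for (k in kb) {
    expect_lt(max(abs(as.matrix(k) - t(as.matrix(k)))), 1e-10)
    ev <- eigen(as.matrix(k), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
  }
  # repair adds the promised jitter
  m <- diag(c(1, 1, -0.5))
  dimnames(m) <- list(letters[1:3], letters[1:3])
  k_bad <- kernel_matrix(m, source = "genomic", role = "SCA")
  k_fix <- ensure_psd(k_bad)
  expect_gt(attr(k_fix, "jitter"), 0.5)
  ev <- eigen(as.matrix(k_fix), only.values = TRUE)$values
  expect_gte(min(ev), 1e-7)
})

test_that("pedigree kernel has the two-level family structure", {
  fam <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C")
  P <- as.matrix(pedigree_kernel(fam, diag_value = 1, within = 0.5, between = 0.25))
  expect_equal(diag(P), setNames(rep(1, 5), names(fam)))
  expect_equal(P["a1", "a2"], 0.5)
  expect_equal(P["a1", "b1"], 0.25)
  off_cross <- P[fam[rownames(P)][row(P)] != fam[colnames(P)][col(P)]]
  expect_true(all(off_cross == 0.25))
})
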