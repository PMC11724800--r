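# shared small fixtures, built once per test run

# small two-pool configuration: 2 families x 8 lines per pool
small_cfg <- function(seed = 42L, ...) {
  defaults <- list(founders_per_pool = 3L, families_per_pool = 2L,
                   lines_per_family = 8L, n_chromosomes = 2L,
                   markers_per_chromosome = 30L, map_length = 100,
                   hybrids_per_parent = 3L,
                   wavelength_grid = seq(1000, 1590, by = 10), seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(small_cfg())
    cache
  }
})

# founders fixture with an explicit tiny map, for meiosis tests
toy_founders <- function(geno, map_pos, chrom = rep(1L, length(map_pos)),
                         pool = "dent") {
  map <- data.frame(marker = paste0("m", seq_along(map_pos)), chrom = chrom,
                    pos_cM = map_pos, stringsAsFactors = FALSE)
  colnames(geno) <- map$marker
  geno_matrix(geno, rep(pool, nrow(geno)), map)
}

# deterministic tiny factorial over explicit parents
toy_design <- function() {
  hyb <- data.frame(hybrid_id = c("h1", "h2", "h3"),
                    dent_parent = c("d1", "d1", "d2"),
                    flint_parent = c("f1", "f2", "f2"),
                    stringsAsFactors = FALSE)
  factorial_design(hyb,
                   dent_family = c(d1 = "dA", d2 = "dA"),
                   flint_family = c(f1 = "fA", f2 = "fA"))
}

# a random symmetric PSD kernel over given ids
random_kernel <- function(ids, seed, role = "GCA_dent", source = "genomic") {
  n <- length(ids)
  set.seed(seed)
  A <- matrix(rnorm(n * (n + 2)), n + 2, n)
  K <- crossprod(A) / (n + 2)
  rownames(K) <- colnames(K) <- ids
  kernel_matrix(K, source = source, role = role)
}
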