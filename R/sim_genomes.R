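#' Simulate founder genomes for both heterotic pools
#'
#' Founders are fully homozygous inbreds: at each marker the line carries the
#' reference allele (1) or the alternative (0). Per-marker reference-allele
#' frequencies are drawn uniformly from `cfg$founder_freq_range` and shared
#' across pools (the pools later diverge through family sampling). Markers sit
#' at uniform genetic positions along each chromosome.
#'
#' @param cfg a [sim_config()].
#' @param seed optional seed override (defaults to a child of `cfg$seed`).
#' @return a [geno_matrix()] with `founders_per_pool` rows per pool, rownames
#'   like `dent_F1`; all entries in \{0, 1\}.
#' @export
simulate_founder_genomes <- function(cfg, seed = child_seed(cfg$seed, 1L)) {
  cfg <- validate_sim_config(cfg)
  n_mrk <- cfg$n_chromosomes * cfg$markers_per_chromosome
  map <- data.frame(
    marker = sprintf("M%d_%d", rep(seq_len(cfg$n_chromosomes), each = cfg$markers_per_chromosome),
                     rep(seq_len(cfg$markers_per_chromosome), cfg$n_chromosomes)),
    chrom = rep(seq_len(cfg$n_chromosomes), each = cfg$markers_per_chromosome),
    pos_cM = rep(seq(0, cfg$map_length, length.out = cfg$markers_per_chromosome),
                 cfg$n_chromosomes),
    stringsAsFactors = FALSE
  )
  with_seed(seed, {
    freq <- stats::runif(n_mrk, cfg$founder_freq_range[1L], cfg$founder_freq_range[2L])
    n_f <- cfg$founders_per_pool
    geno <- matrix(stats::rbinom(2L * n_f * n_mrk, 1L, rep(freq, each = 2L * n_f)),
                   nrow = 2L * n_f, ncol = n_mrk)
    rownames(geno) <- c(sprintf("%s_F%d", cfg$pools[1L], seq_len(n_f)),
                        sprintf("%s_F%d", cfg$pools[2L], seq_len(n_f)))
    colnames(geno) <- map$marker
    geno_matrix(geno, rep(cfg$pools, each = n_f), map)
  })
}

# one meiotic gamete from two parental haplotypes (rows of 0/1),
# Haldane map function, no interference
meiosis_gamete <- function(hapA, hapB, map) {
  gamete <- numeric(length(hapA))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    d <- diff(map$pos_cM[idx])
    r <- 0.5 * (1 - exp(-2 * d / 100))
    cross <- stats::runif(length(r)) < r
    origin <- cumsum(c(stats::runif(1) < 0.5, cross)) %% 2L
    gamete[idx] <- ifelse(origin == 0L, hapA[idx], hapB[idx])
  }
  gamete
}

#' Derive an inbred family from two homozygous parents
#'
#' Simulates meiosis with the Haldane map function (recombination fraction
#' `r = (1 - exp(-2 d / 100)) / 2` between markers `d` cM apart, no
#' interference). `"DH"` takes one gamete from the F1 and doubles it, giving
#' fully homozygous lines; `"SSD"` selfs the F1 for
#' `cfg$n_selfing_generations` generations, so residual heterozygosity (0.5
#' calls) can remain.
#'
#' @param founders a [geno_matrix()] holding the parents.
#' @param parent_a,parent_b rownames of the two (homozygous) parents.
#' @param n_lines number of offspring lines.
#' @param cfg a [sim_config()] (derivation, selfing generations, map checks).
#' @param seed RNG seed.
#' @param line_prefix prefix for offspring rownames.
#' @param family family label recorded for the offspring.
#' @return a `geno_matrix` of `n_lines` offspring.
#' @export
derive_family <- function(founders, parent_a, parent_b, n_lines, cfg,
                          seed, line_prefix = "L", family = NA_character_) {
  stopifnot(inherits(founders, "geno_matrix"))
  for (p in c(parent_a, parent_b)) {
    if (!p %in% rownames(founders$geno)) {
      stop("parent '", p, "' not found in founders", call. = FALSE)
    }
  }
  gA <- founders$geno[parent_a, ]
  gB <- founders$geno[parent_b, ]
  if (anyNA(c(gA, gB)) || any(c(gA, gB) == 0.5)) {
    stop("parents must be fully homozygous with no missing calls", call. = FALSE)
  }
  pool <- unique(founders$pool[rownames(founders$geno) %in% c(parent_a, parent_b)])
  if (length(pool) != 1L) stop("parents must come from the same pool", call. = FALSE)
  map <- founders$map
  with_seed(seed, {
    geno <- matrix(NA_real_, nrow = n_lines, ncol = length(gA))
    for (i in seq_len(n_lines)) {
      if (cfg$derivation == "DH") {
        geno[i, ] <- meiosis_gamete(gA, gB, map)
      } else {
        h1 <- meiosis_gamete(gA, gB, map)  # F1 gametes: parents homozygous, so
        h2 <- meiosis_gamete(gA, gB, map)  # the F1 haplotypes are gA and gB
        for (gen in seq_len(cfg$n_selfing_generations - 1L)) {
          n1 <- meiosis_gamete(h1, h2, map)
          n2 <- meiosis_gamete(h1, h2, map)
          h1 <- n1; h2 <- n2
        }
        geno[i, ] <- (h1 + h2) / 2
      }
    }
    rownames(geno) <- sprintf("%s%d", line_prefix, seq_len(n_lines))
    colnames(geno) <- colnames(founders$geno)
    geno_matrix(geno, rep(pool, n_lines), map,
                family = rep(family, n_lines))
  })
}

#' Simulate a full heterotic pool as connected biparental families
#'
#' Picks `families_per_pool` distinct founder pairs (in a fixed enumeration
#' order of the `choose(founders, 2)` pairs) and derives `lines_per_family`
#' inbreds from each with [derive_family()].
#'
#' @param founders a [geno_matrix()] from [simulate_founder_genomes()].
#' @param pool which pool label to build.
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @return a `geno_matrix` of `families_per_pool * lines_per_family` lines
#'   with family labels like `dent_fam1`.
#' @export
simulate_pool <- function(founders, pool, cfg, seed = child_seed(cfg$seed, 2L)) {
  cfg <- validate_sim_config(cfg)
  f_ids <- rownames(founders$geno)[founders$pool == pool]
  pairs <- utils::combn(f_ids, 2L)
  pairs <- pairs[, seq_len(cfg$families_per_pool), drop = FALSE]
  fams <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    fams[[k]] <- derive_family(
      founders, pairs[1L, k], pairs[2L, k], cfg$lines_per_family, cfg,
      seed = child_seed(seed, k),
      line_prefix = sprintf("%s_f%d_", pool, k),
      family = sprintf("%s_fam%d", pool, k)
    )
  }
  do.call(rbind_geno, fams)
}
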