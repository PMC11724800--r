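#' Sparse factorial crossing design
#'
#' A set of dent x flint hybrid records with the family membership of every
#' parent.
#'
#' @param hybrids data.frame with columns `hybrid_id`, `dent_parent`,
#'   `flint_parent` (pairs unique).
#' @param dent_family,flint_family named character vectors mapping every
#'   referenced parent line to its family.
#' @return object of class `factorial_design`.
#' @export
factorial_design <- function(hybrids, dent_family, flint_family) {
  need <- c("hybrid_id", "dent_parent", "flint_parent")
  if (!all(need %in% names(hybrids))) {
    stop("`hybrids` needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  hybrids <- as.data.frame(hybrids, stringsAsFactors = FALSE)
  key <- paste(hybrids$dent_parent, hybrids$flint_parent, sep = "::")
  if (anyDuplicated(key)) stop("duplicate dent x flint cross in design", call. = FALSE)
  if (anyDuplicated(hybrids$hybrid_id)) stop("duplicate hybrid_id", call. = FALSE)
  if (length(intersect(hybrids$dent_parent, hybrids$flint_parent))) {
    stop("dent and flint parent id sets must be disjoint", call. = FALSE)
  }
  miss_d <- setdiff(hybrids$dent_parent, names(dent_family))
  miss_f <- setdiff(hybrids$flint_parent, names(flint_family))
  if (length(miss_d) || length(miss_f)) {
    stop("parents without a family label: ",
         paste(c(miss_d, miss_f), collapse = ", "), call. = FALSE)
  }
  structure(list(hybrids = hybrids,
                 dent_family = dent_family, flint_family = flint_family),
            class = "factorial_design")
}

#' @export
print.factorial_design <- function(x, ...) {
  cat(sprintf("<factorial_design> %d hybrids; %d dent parents (%d families) x %d flint parents (%d families)\n",
              nrow(x$hybrids), length(unique(x$hybrids$dent_parent)),
              length(unique(x$dent_family[unique(x$hybrids$dent_parent)])),
              length(unique(x$hybrids$flint_parent)),
              length(unique(x$flint_family[unique(x$hybrids$flint_parent)]))))
  invisible(x)
}

#' Simulate a sparse factorial between two pools
#'
#' Randomized sparse bipartite matching: each parent receives
#' `cfg$hybrids_per_parent` crossing slots, slots are shuffled and paired,
#' and duplicate crosses are removed by random edge swaps. With equal pool
#' sizes every parent ends with exactly `hybrids_per_parent` crosses; with
#' unequal pools, surplus slots of the larger side are dropped at random.
#' The realized degree distribution is attached as attribute
#' `degree_audit`.
#'
#' @param dent_lines,flint_lines [geno_matrix()] objects (family labels
#'   required) or character vectors of line ids plus explicit family maps.
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @return a [factorial_design()].
#' @export
simulate_factorial <- function(dent_lines, flint_lines, cfg,
                               seed = child_seed(cfg$seed, 3L)) {
  cfg <- validate_sim_config(cfg)
  get_ids <- function(x) if (inherits(x, "geno_matrix")) rownames(x$geno) else as.character(x)
  get_fam <- function(x, ids) {
    if (inherits(x, "geno_matrix")) {
      if (is.null(x$family)) stop("lines need family labels", call. = FALSE)
      stats::setNames(x$family, rownames(x$geno))
    } else stats::setNames(rep(NA_character_, length(ids)), ids)
  }
  d_ids <- get_ids(dent_lines); f_ids <- get_ids(flint_lines)
  if (!length(d_ids) || !length(f_ids)) cfg_stop("both pools must be non-empty")
  h <- cfg$hybrids_per_parent
  if (h > length(f_ids) || h > length(d_ids)) {
    cfg_stop("hybrids_per_parent exceeds the opposite pool size")
  }
  with_seed(seed, {
    d_stub <- sample(rep(d_ids, each = h))
    f_stub <- sample(rep(f_ids, each = h))
    n <- min(length(d_stub), length(f_stub))
    d_stub <- d_stub[seq_len(n)]; f_stub <- f_stub[seq_len(n)]
    # resolve duplicate crosses by swapping flint partners between edges
    for (pass in 1:200) {
      key <- paste(d_stub, f_stub, sep = "::")
      dup <- which(duplicated(key))
      if (!length(dup)) break
      for (i in dup) {
        for (try in 1:50) {
          j <- sample.int(n, 1L)
          k_ij <- paste(d_stub[i], f_stub[j], sep = "::")
          k_ji <- paste(d_stub[j], f_stub[i], sep = "::")
          key_now <- paste(d_stub, f_stub, sep = "::")
          if (j != i && !(k_ij %in% key_now) && !(k_ji %in% key_now)) {
            tmp <- f_stub[i]; f_stub[i] <- f_stub[j]; f_stub[j] <- tmp
            break
          }
        }
      }
    }
    key <- paste(d_stub, f_stub, sep = "::")
    keep <- !duplicated(key)   # drop any irreducible duplicate rather than loop forever
    d_stub <- d_stub[keep]; f_stub <- f_stub[keep]
    hyb <- data.frame(
      hybrid_id = sprintf("H%03d", seq_along(d_stub)),
      dent_parent = d_stub, flint_parent = f_stub,
      stringsAsFactors = FALSE
    )
    des <- factorial_design(hyb, get_fam(dent_lines, d_ids), get_fam(flint_lines, f_ids))
    deg_d <- table(factor(hyb$dent_parent, levels = d_ids))
    deg_f <- table(factor(hyb$flint_parent, levels = f_ids))
    attr(des, "degree_audit") <- list(
      target = h,
      dent_range = range(deg_d), flint_range = range(deg_f),
      dent_degrees = deg_d, flint_degrees = deg_f
    )
    des
  })
}
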