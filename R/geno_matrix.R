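#' Genotype matrix container
#'
#' Lines x markers matrix of reference-allele shares coded 0, 0.5, 1 (or
#' `NA` before imputation), with a pool label per line, an optional family
#' label per line, and a genetic map.
#'
#' @param geno numeric matrix, rows = lines (rownames mandatory), columns =
#'   markers (colnames mandatory); values in \{0, 0.5, 1, NA\}.
#' @param pool character vector of pool labels, one per line.
#' @param map data.frame with columns `marker`, `chrom`, `pos_cM` matching
#'   the genotype columns.
#' @param family optional character vector of family labels per line.
#' @return object of class `geno_matrix`.
#' @export
geno_matrix <- function(geno, pool, map, family = NULL) {
  if (!is.matrix(geno) || is.null(rownames(geno)) || is.null(colnames(geno))) {
    stop("`geno` must be a matrix with row and column names", call. = FALSE)
  }
  ok <- geno %in% c(0, 0.5, 1) | is.na(geno)
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop(sprintf("genotype values must be 0, 0.5, 1 or NA; found %s at [%d, %d]",
                 format(geno[bad]), (bad - 1L) %% nrow(geno) + 1L,
                 (bad - 1L) %/% nrow(geno) + 1L), call. = FALSE)
  }
  if (length(pool) != nrow(geno)) stop("`pool` must have one label per line", call. = FALSE)
  if (!all(c("marker", "chrom", "pos_cM") %in% names(map)) ||
      nrow(map) != ncol(geno) || !identical(as.character(map$marker), colnames(geno))) {
    stop("`map` must describe exactly the genotype columns, in order", call. = FALSE)
  }
  if (!is.null(family) && length(family) != nrow(geno)) {
    stop("`family` must have one label per line", call. = FALSE)
  }
  structure(list(geno = geno, pool = as.character(pool), map = map,
                 family = if (is.null(family)) NULL else as.character(family)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d lines x %d markers; pools: %s; missing: %.1f%%\n",
              nrow(x$geno), ncol(x$geno),
              paste(sprintf("%s=%d", names(table(x$pool)), table(x$pool)), collapse = ", "),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix to one pool
#'
#' @param g a [geno_matrix()].
#' @param pool pool label to keep.
#' @return a `geno_matrix` containing only the lines of that pool.
#' @export
subset_pool <- function(g, pool) {
  stopifnot(inherits(g, "geno_matrix"))
  keep <- g$pool == pool
  if (!any(keep)) stop("no lines in pool '", pool, "'", call. = FALSE)
  geno_matrix(g$geno[keep, , drop = FALSE], g$pool[keep], g$map,
              family = if (is.null(g$family)) NULL else g$family[keep])
}

#' Reference-allele frequencies within a genotype matrix
#'
#' @param g a [geno_matrix()]; frequencies are the column means of the
#'   observed allele shares (missing entries ignored).
#' @return named numeric vector, one frequency per marker.
#' @export
allele_freq <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  colMeans(g$geno, na.rm = TRUE)
}

# combine geno_matrix objects sharing a map
rbind_geno <- function(...) {
  gs <- list(...)
  geno <- do.call(rbind, lapply(gs, `[[`, "geno"))
  fam <- lapply(gs, `[[`, "family")
  fam <- if (any(vapply(fam, is.null, logical(1)))) NULL else unlist(fam)
  geno_matrix(geno, unlist(lapply(gs, `[[`, "pool")), gs[[1L]]$map, family = fam)
}
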