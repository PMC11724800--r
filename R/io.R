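#' Read and write genotype matrices
#'
#' CSV dialect: columns `line_id`, `pool`, optional `family`, then one
#' numeric column per marker; values 0, 0.5, 1, or empty/NA for missing.
#' Map information (chromosome, position) travels in a JSON sidecar
#' written next to the CSV; when absent on read, a single-chromosome map
#' with unit spacing is assumed.
#'
#' @param path CSV file path.
#' @param g a [geno_matrix()].
#' @return `read_genotypes` returns a `geno_matrix`; `write_genotypes`
#'   returns `path` invisibly.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- intersect(c("line_id", "pool", "family"), names(df))
  if (!all(c("line_id", "pool") %in% meta_cols)) {
    stop("genotype CSV needs columns line_id and pool", call. = FALSE)
  }
  mk_cols <- setdiff(names(df), meta_cols)
  geno <- as.matrix(df[, mk_cols, drop = FALSE])
  mode(geno) <- "numeric"
  bad <- which(!(geno %in% c(0, 0.5, 1) | is.na(geno)))
  if (length(bad)) {
    i <- (bad[1L] - 1L) %% nrow(geno) + 1L
    j <- (bad[1L] - 1L) %/% nrow(geno) + 1L
    stop(sprintf("invalid genotype value '%s' at line %s, marker %s",
                 format(geno[bad[1L]]), df$line_id[i], mk_cols[j]), call. = FALSE)
  }
  rownames(geno) <- df$line_id
  side <- paste0(path, ".json")
  map <- if (file.exists(side)) {
    as.data.frame(jsonlite::read_json(side, simplifyVector = TRUE)$map)
  } else {
    data.frame(marker = mk_cols, chrom = 1L, pos_cM = seq_along(mk_cols),
               stringsAsFactors = FALSE)
  }
  geno_matrix(geno, df$pool, map,
              family = if ("family" %in% meta_cols) df$family else NULL)
}

#' @rdname read_genotypes
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "geno_matrix"))
  df <- data.frame(line_id = rownames(g$geno), pool = g$pool,
                   stringsAsFactors = FALSE)
  if (!is.null(g$family)) df$family <- g$family
  df <- cbind(df, as.data.frame(g$geno, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  jsonlite::write_json(list(map = g$map), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import genotypes from a biallelic VCF
#'
#' Collapses diploid GT calls to reference-allele shares: `0/0 -> 0`,
#' heterozygous `-> 0.5`, `1/1 -> 1` (the VCF ALT allele is taken as the
#' reference allele of the coding). Requires the `vcfR` package.
#'
#' @param path VCF file.
#' @param pool pool label(s) for the samples (recycled).
#' @return a [geno_matrix()].
#' @export
read_genotypes_vcf <- function(path, pool) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF import requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_real_, length(x))
    out[x %in% c("0/0")] <- 0
    out[x %in% c("0/1", "1/0")] <- 0.5
    out[x %in% c("1/1")] <- 1
    out
  }
  geno <- t(apply(gt, 1L, code))
  dimnames(geno) <- dimnames(gt)
  geno <- t(geno)  # samples x markers
  map <- data.frame(marker = colnames(geno),
                    chrom = as.character(v@fix[, "CHROM"]),
                    pos_cM = as.numeric(v@fix[, "POS"]) / 1e6,
                    stringsAsFactors = FALSE)
  geno_matrix(geno, rep_len(pool, nrow(geno)), map)
}

#' Read and write spectra sets
#'
#' CSV dialect: `sample_id`, metadata columns (`genotype_id`, `pool`,
#' `trial_id`, `row`, `column`, `replicate`, `plot_id`), then numeric
#' wavelength columns (header = wavelength in nm). The processing state is
#' written to a JSON sidecar.
#'
#' @param path CSV file path.
#' @param s a [spectra_set()].
#' @return `read_spectra` returns a `spectra_set`; the writer returns
#'   `path` invisibly.
#' @export
read_spectra <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  wl_col <- suppressWarnings(!is.na(as.numeric(names(df))))
  if (!any(wl_col)) stop("no numeric wavelength columns found", call. = FALSE)
  meta <- df[, !wl_col, drop = FALSE]
  vals <- as.matrix(df[, wl_col, drop = FALSE])
  mode(vals) <- "numeric"
  side <- paste0(path, ".json")
  state <- if (file.exists(side)) {
    jsonlite::read_json(side, simplifyVector = TRUE)$state
  } else "raw"
  spectra_set(vals, as.numeric(names(df)[wl_col]), meta, state = state)
}

#' @rdname read_spectra
#' @export
write_spectra <- function(s, path) {
  stopifnot(inherits(s, "spectra_set"))
  vals <- as.data.frame(s$values, check.names = FALSE)
  names(vals) <- as.character(s$wavelengths)
  utils::write.csv(cbind(s$meta, vals), path, row.names = FALSE, na = "")
  jsonlite::write_json(list(state = s$state), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read and write relationship kernels
#'
#' Square CSV with id header row and first column; a JSON sidecar stores
#' `source`, `role`, `scaled` and `jitter`. The reader re-checks symmetry
#' (tolerance 1e-8) and id uniqueness.
#'
#' @param path CSV file path.
#' @param k a [kernel_matrix()].
#' @return `read_kernel` returns a `kernel_matrix`; the writer returns
#'   `path` invisibly.
#' @export
read_kernel <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- ids
  if (!identical(colnames(m), ids)) stop("kernel row/column ids disagree", call. = FALSE)
  if (anyDuplicated(ids)) stop("kernel ids must be unique", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) {
    stop("kernel is asymmetric beyond tolerance 1e-8", call. = FALSE)
  }
  side <- paste0(path, ".json")
  a <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  kernel_matrix(m, source = a$source %||% "genomic", role = a$role %||% "GCA_dent",
                scaled = isTRUE(a$scaled), jitter = a$jitter %||% 0)
}

#' @rdname read_kernel
#' @export
write_kernel <- function(k, path) {
  stopifnot(inherits(k, "kernel_matrix"))
  df <- data.frame(id = rownames(k), as.data.frame(unclass(k), check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(kernel_attrs(k), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write factorial designs
#'
#' CSV with columns `hybrid_id`, `dent_parent`, `flint_parent`,
#' `dent_family`, `flint_family`.
#'
#' @param path CSV file path.
#' @param design a [factorial_design()].
#' @return `read_design` returns a `factorial_design`; the writer returns
#'   `path` invisibly.
#' @export
read_design <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("hybrid_id", "dent_parent", "flint_parent", "dent_family", "flint_family")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("design CSV lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyNA(df$dent_family) || anyNA(df$flint_family)) {
    bad <- df$hybrid_id[is.na(df$dent_family) | is.na(df$flint_family)]
    stop("missing family label for hybrid(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  dfam <- tapply(df$dent_family, df$dent_parent, `[`, 1L)
  ffam <- tapply(df$flint_family, df$flint_parent, `[`, 1L)
  factorial_design(df[, c("hybrid_id", "dent_parent", "flint_parent")],
                   stats::setNames(as.character(dfam), names(dfam)),
                   stats::setNames(as.character(ffam), names(ffam)))
}

#' @rdname read_design
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "factorial_design"))
  hyb <- design$hybrids
  hyb$dent_family <- design$dent_family[hyb$dent_parent]
  hyb$flint_family <- design$flint_family[hyb$flint_parent]
  utils::write.csv(hyb, path, row.names = FALSE)
  invisible(path)
}

#' Read and write hybrid phenotype tables
#'
#' Long CSV: `hybrid_id`, `trait`, `value` (one row per hybrid x trait).
#'
#' @param path CSV file path.
#' @param phenotypes long phenotype data.frame.
#' @param design optional [factorial_design()]; when given, hybrid ids are
#'   cross-checked against it.
#' @return `read_phenotypes` returns the data.frame; the writer returns
#'   `path` invisibly.
#' @export
read_phenotypes <- function(path, design = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("hybrid_id", "trait", "value")
  if (!all(need %in% names(df))) {
    stop("phenotype CSV needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df[, c("hybrid_id", "trait")])) {
    stop("duplicate (hybrid, trait) rows", call. = FALSE)
  }
  if (!is.null(design)) {
    unknown <- setdiff(df$hybrid_id, design$hybrids$hybrid_id)
    if (length(unknown)) stop("phenotypes reference unknown hybrid(s): ",
                              paste(utils::head(unknown, 5L), collapse = ", "),
                              call. = FALSE)
  }
  df
}

#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(phenotypes[, c("hybrid_id", "trait", "value")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' YAML file mirroring [sim_config()] fields plus scenario parameters; used
#' by the analysis drivers. Unknown fields raise an error so typos do not
#' silently fall back to defaults.
#'
#' @param path YAML file.
#' @return a list with a validated `sim_config` under `$sim` and the
#'   remaining entries as-is.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  sim_fields <- names(formals(sim_config))
  extra <- setdiff(names(cfg$sim %||% list()), sim_fields)
  if (length(extra)) stop("unknown sim config field(s): ",
                          paste(extra, collapse = ", "), call. = FALSE)
  sim <- do.call(sim_config, cfg$sim %||% list())
  c(list(sim = sim), cfg[setdiff(names(cfg), "sim")])
}
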