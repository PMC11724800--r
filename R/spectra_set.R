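#' NIR spectra container
#'
#' Samples x wavelengths absorbance matrix plus per-sample metadata and a
#' processing-state tag. The state tag enforces the preprocessing order
#' `raw -> adjusted -> normalized -> derivative`.
#'
#' @param values numeric matrix, samples x wavelengths, no missing entries.
#' @param wavelengths strictly increasing numeric vector (nm), one per column.
#' @param meta data.frame with one row per sample; required columns
#'   `sample_id`, `genotype_id`, `trial_id`; optional `pool`, `row`, `column`,
#'   `replicate`, `plot_id` (filled with `NA` when absent).
#' @param state one of `"raw"`, `"adjusted"`, `"normalized"`, `"derivative"`.
#' @return object of class `spectra_set`.
#' @export
spectra_set <- function(values, wavelengths, meta,
                        state = c("raw", "adjusted", "normalized", "derivative")) {
  state <- match.arg(state)
  if (!is.matrix(values)) values <- as.matrix(values)
  if (anyNA(values)) stop("spectra must not contain missing absorbance", call. = FALSE)
  if (length(wavelengths) != ncol(values)) {
    stop("one wavelength per column is required", call. = FALSE)
  }
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  for (col in c("sample_id", "genotype_id", "trial_id")) {
    if (!col %in% names(meta)) stop("meta needs column '", col, "'", call. = FALSE)
  }
  for (col in c("pool", "row", "column", "replicate", "plot_id")) {
    if (!col %in% names(meta)) meta[[col]] <- NA
  }
  if (nrow(meta) != nrow(values)) stop("meta must have one row per sample", call. = FALSE)
  if (anyDuplicated(meta$sample_id)) stop("sample_id must be unique", call. = FALSE)
  rownames(values) <- meta$sample_id
  structure(list(values = values, wavelengths = as.numeric(wavelengths),
                 meta = meta, state = state),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set:%s> %d samples x %d wavelengths (%.0f-%.0f nm); %d genotypes, %d trial(s)\n",
              x$state, nrow(x$values), ncol(x$values),
              min(x$wavelengths), max(x$wavelengths),
              length(unique(x$meta$genotype_id)), length(unique(x$meta$trial_id))))
  invisible(x)
}

require_state <- function(s, allowed) {
  if (!s$state %in% allowed) {
    stop(sprintf("spectra are in state '%s'; this step needs state %s (pipeline order: raw -> adjusted -> normalized -> derivative)",
                 s$state, paste(sQuote(allowed), collapse = " or ")), call. = FALSE)
  }
  invisible(s)
}

#' Extract a genotype x wavelength matrix for one trial
#'
#' Requires exactly one spectrum per genotype in that trial.
#'
#' @param s a [spectra_set()].
#' @param trial trial id to extract (default: the only trial present).
#' @return numeric matrix with genotype ids as rownames.
#' @export
spectra_matrix <- function(s, trial = NULL) {
  stopifnot(inherits(s, "spectra_set"))
  if (is.null(trial)) {
    trial <- unique(s$meta$trial_id)
    if (length(trial) != 1L) stop("several trials present; specify `trial`", call. = FALSE)
  }
  keep <- s$meta$trial_id == trial
  if (!any(keep)) stop("no samples for trial '", trial, "'", call. = FALSE)
  g <- s$meta$genotype_id[keep]
  if (anyDuplicated(g)) {
    stop("more than one spectrum per genotype in trial '", trial,
         "'; aggregate or adjust first", call. = FALSE)
  }
  m <- s$values[keep, , drop = FALSE]
  rownames(m) <- g
  m
}
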