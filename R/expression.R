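#' Counts-per-million normalisation
#'
#' Scales raw read counts by library size: `cpm = counts / library_size * 1e6`.
#' When `library_size` is omitted it defaults to the per-sample column total,
#' in which case every cpm column sums to exactly one million.
#'
#' @param counts Numeric matrix of non-negative read counts, genes in rows and
#'   samples in columns (a vector is treated as a single sample).
#' @param library_size Optional numeric vector of library sizes, one per
#'   sample, overriding the column totals (e.g. total mapped reads before any
#'   gene-level filtering). All values must be strictly positive.
#' @return A numeric matrix (or vector, matching the input) of cpm values.
#' @examples
#' compute_cpm(c(500, 1500), library_size = 25e6)
#' @export
compute_cpm <- function(counts, library_size = NULL) {
  vec_in <- is.null(dim(counts))
  m <- as.matrix(counts)
  if (any(m < 0, na.rm = TRUE)) {
    stop("counts must be non-negative")
  }
  if (is.null(library_size)) {
    library_size <- colSums(m)
  }
  if (length(library_size) != ncol(m)) {
    stop("library_size must have one entry per sample")
  }
  if (any(!is.finite(library_size)) || any(library_size <= 0)) {
    stop("library sizes must be strictly positive")
  }
  out <- sweep(m, 2, library_size, "/") * 1e6
  if (vec_in) drop(out) else out
}

#' Average cpm over biological replicates
#'
#' Collapses a cpm matrix to one column per (organ, zeitgeber time) cell by
#' taking the arithmetic mean over the replicates present in that cell.
#'
#' @param cpm Numeric matrix, genes x samples.
#' @param samples Data frame describing the columns of `cpm`, with columns
#'   `sample_id`, `organ`, `zt` and `replicate`. Every column of `cpm` must
#'   appear in `samples$sample_id`.
#' @return A list with one element per organ; each element is a genes x Zt
#'   matrix of replicate-averaged cpm, columns named by Zt and ordered by
#'   increasing Zt.
#' @export
average_replicates <- function(cpm, samples) {
  cpm <- as.matrix(cpm)
  req <- c("sample_id", "organ", "zt", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss)) {
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  }
  ids <- colnames(cpm)
  if (is.null(ids)) {
    if (nrow(samples) != ncol(cpm)) {
      stop("unnamed cpm columns and sample sheet differ in length")
    }
    ids <- samples$sample_id
    colnames(cpm) <- ids
  }
  if (!all(ids %in% samples$sample_id)) {
    stop("every cpm column must be described in the sample sheet")
  }
  meta <- samples[match(ids, samples$sample_id), ]
  out <- list()
  for (org in unique(meta$organ)) {
    zts <- sort(unique(meta$zt[meta$organ == org]))
    prof <- matrix(NA_real_, nrow(cpm), length(zts),
                   dimnames = list(rownames(cpm), as.character(zts)))
    for (k in seq_along(zts)) {
      sel <- ids[meta$organ == org & meta$zt == zts[k]]
      if (!length(sel)) stop("no replicate for organ ", org, " at Zt ", zts[k])
      prof[, k] <- rowMeans(cpm[, sel, drop = FALSE])
    }
    out[[org]] <- prof
  }
  out
}

#' Relative expression across timepoints
#'
#' Divides each timepoint value by the across-timepoint mean so that an
#' expressed gene's daily mean is exactly 1. An all-zero profile is returned
#' unchanged and flagged degenerate.
#'
#' @param x Numeric vector of replicate-averaged cpm over the sampled Zt, or a
#'   matrix with genes in rows (the scaling is applied per row).
#' @return For a vector, a numeric vector with attribute `degenerate`; for a
#'   matrix, a matrix with a logical `degenerate` attribute vector (one flag
#'   per row).
#' @examples
#' relative_expression(c(2, 0, 0, 0, 0, 0, 0, 0))
#' @export
relative_expression <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("cpm values must be non-negative")
  if (is.null(dim(x))) {
    mu <- mean(x)
    if (mu == 0) {
      return(structure(x, degenerate = TRUE))
    }
    return(structure(x / mu, degenerate = FALSE))
  }
  mu <- rowMeans(x)
  deg <- mu == 0
  scl <- ifelse(deg, 1, mu)
  structure(x / scl, degenerate = deg)
}

#' Expressed-gene filter
#'
#' A gene counts as expressed in an organ when its replicate-averaged cpm
#' exceeds `threshold` (strictly) at `min_timepoints` or more of the sampled
#' timepoints.
#'
#' @param mean_cpm Numeric vector of replicate-averaged cpm over the sampled
#'   Zt, or a genes x Zt matrix.
#' @param threshold cpm value that must be strictly exceeded (default 1).
#' @param min_timepoints Minimum number of timepoints above the threshold
#'   (default 2 of the 8 sampled).
#' @return Logical scalar (vector input) or logical vector with one flag per
#'   gene (matrix input).
#' @export
expressed_filter <- function(mean_cpm, threshold = 1, min_timepoints = 2) {
  if (is.null(dim(mean_cpm))) {
    return(sum(mean_cpm > threshold) >= min_timepoints)
  }
  rowSums(mean_cpm > threshold) >= min_timepoints
}

#' Per-organ expression profiles
#'
#' Runs the normalisation chain on a raw count matrix: cpm (library size =
#' column total unless overridden in the sample sheet's optional
#' `library_size` column), replicate averaging, the expressed-gene filter and
#' relative expression.
#'
#' @param counts Integer matrix of read counts, genes x samples.
#' @param samples Sample sheet data frame (`sample_id`, `organ`, `zt`,
#'   `replicate`, optional `library_size`).
#' @inheritParams expressed_filter
#' @return A list with one element per organ, each a list with elements
#'   `organ`, `mean_cpm` (genes x Zt), `relative` (genes x Zt),
#'   `expressed` (logical per gene) and `degenerate` (logical per gene).
#' @export
organ_profiles <- function(counts, samples, threshold = 1, min_timepoints = 2) {
  lib <- NULL
  if ("library_size" %in% names(samples) && !all(is.na(samples$library_size))) {
    ids <- colnames(counts)
    if (is.null(ids)) ids <- samples$sample_id
    lib <- samples$library_size[match(ids, samples$sample_id)]
  }
  cpm <- compute_cpm(counts, library_size = lib)
  prof <- average_replicates(cpm, samples)
  lapply(names(prof), function(org) {
    m <- prof[[org]]
    rel <- relative_expression(m)
    list(organ = org,
         mean_cpm = m,
         relative = unclass(rel),
         expressed = expressed_filter(m, threshold, min_timepoints),
         degenerate = attr(rel, "degenerate"))
  }) |> stats::setNames(names(prof))
}
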