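## NanoString nCounter normalisation: positive-control scaling with sample
## qualification, housekeeping geometric-mean normalisation, negative-control
## background subtraction. Counts arrive as a probe x sample matrix with a
## probe-class annotation (endogenous / positive / negative / housekeeping).

.geo_mean <- function(x) exp(mean(log(x)))

#' Positive-control scaling factors and sample qualification
#'
#' Each sample's factor is the cohort average of per-sample positive-control
#' means divided by that sample's positive-control mean, so an average sample
#' gets factor 1. Samples qualify when the factor lies in \[0.3, 3\]; a zero
#' positive-control mean disqualifies the sample.
#'
#' @param counts Numeric probe x sample matrix of raw counts.
#' @param probe_class Character vector, one entry per row of `counts`, in
#'   `c("endogenous", "positive", "negative", "housekeeping")`.
#' @param limits Qualification interval for the factor (default `c(0.3, 3)`).
#' @return Data frame: `sample`, `factor`, `qualified`, `pos_mean`.
#' @export
scaling_factor <- function(counts, probe_class, limits = c(0.3, 3)) {
  counts <- as.matrix(counts)
  stopifnot(length(probe_class) == nrow(counts))
  pos <- counts[probe_class == "positive", , drop = FALSE]
  if (!nrow(pos)) stop("no positive-control probes present")
  pos_mean <- colMeans(pos)
  cohort <- mean(pos_mean)
  fac <- ifelse(pos_mean > 0, cohort / pos_mean, NA_real_)
  data.frame(
    sample = colnames(counts) %||% as.character(seq_len(ncol(counts))),
    factor = fac,
    qualified = !is.na(fac) & fac >= limits[1] & fac <= limits[2],
    pos_mean = pos_mean,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Housekeeping geometric-mean normalisation of scaled counts
#'
#' Multiplies each sample by its positive-control scaling factor, then
#' divides by the sample's housekeeping geometric mean and re-centres by the
#' cohort geometric mean of those housekeeping values, so a cohort-average
#' sample passes through unchanged.
#'
#' @inheritParams scaling_factor
#' @param drop_unqualified Drop samples failing qualification (default TRUE).
#' @return List: `normalized` (probe x sample matrix over retained samples),
#'   `qc` (the [scaling_factor()] table), `hk_geomean` (per retained sample).
#' @export
normalize_counts <- function(counts, probe_class, limits = c(0.3, 3),
                             drop_unqualified = TRUE) {
  counts <- as.matrix(counts)
  qc <- scaling_factor(counts, probe_class, limits)
  keep <- if (drop_unqualified) qc$qualified else rep(TRUE, ncol(counts))
  m <- counts[, keep, drop = FALSE]
  fac <- qc$factor[keep]
  hk <- m[probe_class == "housekeeping", , drop = FALSE]
  if (!nrow(hk)) stop("no housekeeping probes present")
  scaled_hk <- sweep(hk, 2, fac, "*")
  if (any(scaled_hk == 0)) {
    stop("housekeeping count of zero; cannot normalize")
  }
  hk_gm <- apply(scaled_hk, 2, .geo_mean)
  cohort_gm <- .geo_mean(hk_gm)
  scaled <- sweep(m, 2, fac, "*")
  norm <- sweep(scaled, 2, cohort_gm / hk_gm, "*")
  list(normalized = norm, qc = qc, hk_geomean = hk_gm)
}

#' Negative-control background subtraction
#'
#' Subtracts each sample's mean negative-control count from its normalized
#' counts, flooring at zero.
#'
#' @param normalized Probe x sample matrix of normalized counts (typically
#'   `normalize_counts()$normalized`).
#' @param probe_class Probe classes aligned with the rows of `normalized`.
#' @return Matrix of background-corrected counts (negative-control rows are
#'   retained, corrected like the rest).
#' @export
subtract_background <- function(normalized, probe_class) {
  normalized <- as.matrix(normalized)
  neg <- normalized[probe_class == "negative", , drop = FALSE]
  if (!nrow(neg)) stop("no negative-control probes present")
  bg <- colMeans(neg)
  pmax(sweep(normalized, 2, bg, "-"), 0)
}

#' Full nCounter normalisation pipeline
#'
#' Scaling-factor qualification, housekeeping normalisation and background
#' subtraction in one call, returning endogenous probes only.
#'
#' @inheritParams normalize_counts
#' @return List: `expression` (endogenous probe x sample matrix, background
#'   corrected), `qc`, `normalized` (all probes, pre-background).
#' @export
ncounter_normalize <- function(counts, probe_class, limits = c(0.3, 3)) {
  nm <- normalize_counts(counts, probe_class, limits)
  corr <- subtract_background(nm$normalized, probe_class)
  list(expression = corr[probe_class == "endogenous", , drop = FALSE],
       qc = nm$qc, normalized = nm$normalized)
}
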