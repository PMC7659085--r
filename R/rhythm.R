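## Nonparametric detection of cyclic expression over a sampled 24-h cycle.
##
## The test statistic follows the umbrella-alternative construction: for a
## hypothesised (peak, trough) pair of timepoints the cycle splits into a
## rising arc (trough -> peak, circularly) and a falling arc (peak -> trough),
## and the statistic is the sum, over all ordered group pairs within each arc,
## of Mann-Whitney U counts of concordant value pairs (ties count 1/2).
## Jonckheere-Terpstra style: all ordered pairs within an arc, not just
## adjacent ones. Every admissible (peak, trough) hypothesis is scored and the
## per-hypothesis right-tail p-values are Bonferroni-combined.

# Mann-Whitney concordance count: pairs (x in a, y in b) with y > x, ties 1/2.
.pair_u <- function(a, b) {
  sum(outer(a, b, "<")) + 0.5 * sum(outer(a, b, "=="))
}

# Hypothesis bookkeeping for G circular groups: every ordered (peak, trough)
# pair. Returns a coefficient matrix C (H x G^2, vec layout column-major in
# (a, b) meaning U_{a,b} = #{value in group b exceeds value in group a}).
# The arc endpoints belong to both arcs, so the (trough, peak) comparison is
# counted once per slope.
.umbrella_hypotheses <- function(G) {
  stopifnot(G >= 2)
  hyp <- expand.grid(peak = seq_len(G), trough = seq_len(G))
  hyp <- hyp[hyp$peak != hyp$trough, , drop = FALSE]
  C <- matrix(0, nrow(hyp), G * G)
  for (h in seq_len(nrow(hyp))) {
    p <- hyp$peak[h]; t <- hyp$trough[h]
    rising <- if (t < p) t:p else c(t:G, 1:p)      # trough .. peak
    falling <- if (p < t) p:t else c(p:G, 1:t)     # peak .. trough
    nr <- length(rising); nf <- length(falling)
    for (i in seq_len(nr - 1)) for (j in (i + 1):nr) {
      a <- rising[i]; b <- rising[j]               # later value larger
      C[h, (b - 1) * G + a] <- C[h, (b - 1) * G + a] + 1
    }
    for (i in seq_len(nf - 1)) for (j in (i + 1):nf) {
      a <- falling[i]; b <- falling[j]             # earlier value larger
      C[h, (a - 1) * G + b] <- C[h, (a - 1) * G + b] + 1
    }
  }
  list(hyp = hyp, C = C)
}

# S_max per hypothesis: sum of n_a * n_b over the counted (with multiplicity)
# group pairs.
.umbrella_smax <- function(C, sizes) {
  G <- length(sizes)
  nn <- as.vector(outer(sizes, sizes))   # column-major (a, b) -> n_a * n_b
  drop(C %*% nn)
}

# U values for all ordered group pairs, vectorised over rows of X (each row
# one arrangement of the pooled values; columns grouped by `slots`).
# Returns an nrow(X) x G^2 matrix in the same vec layout as the C matrix.
.u_matrix_rows <- function(X, slots) {
  G <- length(slots)
  B <- nrow(X)
  U <- matrix(0, B, G * G)
  for (a in seq_len(G - 1)) for (b in (a + 1):G) {
    u_ab <- numeric(B)
    ties <- numeric(B)
    for (i in slots[[a]]) for (j in slots[[b]]) {
      u_ab <- u_ab + (X[, j] > X[, i])
      ties <- ties + (X[, j] == X[, i])
    }
    u_ab <- u_ab + 0.5 * ties
    U[, (b - 1) * G + a] <- u_ab
    U[, (a - 1) * G + b] <- length(slots[[a]]) * length(slots[[b]]) - u_ab
  }
  U
}

# All distinct assignments of N pooled positions to groups of the given
# sizes; rows index assignments, columns are group slots in order.
.enumerate_assignments <- function(sizes) {
  rec <- function(avail, sizes) {
    if (!length(sizes)) return(matrix(integer(0), 1, 0))
    if (length(sizes) == 1) return(matrix(avail, 1))
    ch <- utils::combn(avail, sizes[1])
    out <- vector("list", ncol(ch))
    for (k in seq_len(ncol(ch))) {
      rest <- rec(setdiff(avail, ch[, k]), sizes[-1])
      out[[k]] <- cbind(matrix(ch[, k], nrow(rest), sizes[1], byrow = TRUE),
                        rest)
    }
    do.call(rbind, out)
  }
  rec(seq_len(sum(sizes)), sizes)
}

#' Umbrella rank statistic for one (peak, trough) hypothesis
#'
#' Sums Mann-Whitney U concordance counts over all ordered group pairs of the
#' rising arc (trough to peak, circular) and the falling arc (peak to
#' trough). Ties count 1/2, so the statistic ranges over \[0, S_max\] with
#' S_max = sum of group-size products over the counted pairs.
#'
#' @param groups List of numeric vectors, one per timepoint, in circular time
#'   order; each non-empty.
#' @param peak_index,trough_index Positions (1-based) of the hypothesised peak
#'   and trough groups; must differ.
#' @return The statistic, with attribute `s_max`.
#' @examples
#' g <- list(c(1, 2), c(3, 4), c(5, 6), c(2, 3))
#' umbrella_statistic(g, peak_index = 3, trough_index = 1)
#' @export
umbrella_statistic <- function(groups, peak_index, trough_index) {
  G <- length(groups)
  if (peak_index == trough_index) stop("peak and trough must differ")
  if (any(!vapply(groups, length, 1L))) stop("all groups must be non-empty")
  sizes <- vapply(groups, length, 1L)
  hs <- .umbrella_hypotheses(G)
  h <- which(hs$hyp$peak == peak_index & hs$hyp$trough == trough_index)
  slots <- split(seq_len(sum(sizes)), rep(seq_len(G), sizes))
  X <- matrix(unlist(groups), 1)
  U <- .u_matrix_rows(X, slots)
  s <- drop(U %*% t(hs$C[h, , drop = FALSE]))
  structure(s, s_max = .umbrella_smax(hs$C[h, , drop = FALSE], sizes))
}

#' Umbrella rhythm test for one gene
#'
#' Scores every admissible (peak, trough) hypothesis on the circular
#' timepoint groups, computes each statistic's right-tail probability under
#' the permutation null (all arrangements of the pooled values equally
#' likely) and Bonferroni-combines across hypotheses. The null is evaluated
#' by full enumeration when 10 or fewer observations are available
#' (`method = "auto"`), otherwise by seeded Monte-Carlo permutation.
#'
#' @param groups List of numeric replicate values per timepoint, circular
#'   time order; at least 3 groups.
#' @param alpha Significance cutoff for the cyclic call (default 0.01).
#' @param method `"auto"`, `"exact"` or `"monte_carlo"`.
#' @param n_perm Number of Monte-Carlo permutations (>= 100).
#' @param seed Optional integer seed for the Monte-Carlo draw.
#' @return A list: `statistic` (best hypothesis), `s_max`, `p_value`
#'   (Bonferroni-combined), `is_cyclic`, `best_peak`, `best_trough` (group
#'   indices), `p_per_hypothesis`, `n_hypotheses`, `method`.
#' @export
rhythm_pvalue <- function(groups, alpha = 0.01,
                          method = c("auto", "exact", "monte_carlo"),
                          n_perm = 10000, seed = NULL) {
  method <- match.arg(method)
  G <- length(groups)
  if (G < 3) stop("need at least 3 timepoint groups")
  sizes <- vapply(groups, length, 1L)
  if (any(sizes < 1)) stop("all groups must be non-empty")
  N <- sum(sizes)
  if (method == "auto") method <- if (N <= 10) "exact" else "monte_carlo"
  if (method == "monte_carlo" && n_perm < 100) {
    stop("n_perm must be at least 100")
  }
  vals <- unlist(groups)
  hs <- .umbrella_hypotheses(G)
  slots <- split(seq_len(N), rep(seq_len(G), sizes))
  s_max <- .umbrella_smax(hs$C, sizes)
  s_obs <- drop(.u_matrix_rows(matrix(vals, 1), slots) %*% t(hs$C))

  if (method == "exact") {
    A <- .enumerate_assignments(sizes)
    X <- matrix(vals[A], nrow(A))
    S <- .u_matrix_rows(X, slots) %*% t(hs$C)
    p <- vapply(seq_len(ncol(S)),
                function(h) mean(S[, h] >= s_obs[h] - 1e-9), 0)
  } else {
    if (!is.null(seed)) set.seed(seed)
    P <- t(vapply(seq_len(n_perm), function(i) sample.int(N), integer(N)))
    X <- matrix(vals[P], n_perm)
    S <- .u_matrix_rows(X, slots) %*% t(hs$C)
    cnt <- vapply(seq_len(ncol(S)),
                  function(h) sum(S[, h] >= s_obs[h] - 1e-9), 0)
    p <- (1 + cnt) / (n_perm + 1)
  }
  H <- nrow(hs$hyp)
  best <- order(p, -s_obs / s_max)[1]
  p_comb <- min(1, H * min(p))
  list(statistic = s_obs[best], s_max = s_max[best], p_value = p_comb,
       is_cyclic = p_comb < alpha,
       best_peak = hs$hyp$peak[best], best_trough = hs$hyp$trough[best],
       p_per_hypothesis = p, n_hypotheses = H, method = method)
}

#' Peak time, peak shape and amplitude of a relative-expression profile
#'
#' @param relative Numeric vector of relative expression at the sampled Zt.
#' @param zt Numeric vector of the sampled zeitgeber times (hours in
#'   \[0, 24)), same length as `relative`.
#' @param period Cycle length in hours (default 24).
#' @return A list: `peak_zt` (Zt of the maximum), `peak_shape` (circular
#'   forward distance in hours from peak to minimum), `amplitude`
#'   (max - min, relative units) and `degenerate` (TRUE for an all-equal
#'   profile, in which case peak fields are `NA`).
#' @examples
#' peak_statistics(c(1, 2, 3, 2, 1, 0.5, 0.2, 0.3), zt = seq(0.5, 21.5, 3))
#' @export
peak_statistics <- function(relative, zt, period = 24) {
  stopifnot(length(relative) == length(zt))
  if (length(unique(relative)) == 1L) {
    return(list(peak_zt = NA_real_, peak_shape = NA_real_, amplitude = 0,
                degenerate = TRUE))
  }
  i_max <- which.max(relative)
  i_min <- which.min(relative)
  shape <- (zt[i_min] - zt[i_max]) %% period
  list(peak_zt = zt[i_max], peak_shape = shape,
       amplitude = max(relative) - min(relative), degenerate = FALSE)
}

#' Rhythm detection across a gene x sample matrix
#'
#' Applies the umbrella rhythm test to every row of a cpm matrix for one
#' organ, grouping columns by zeitgeber time. Genes whose pooled values
#' contain no ties share a single permutation (or enumeration) null
#' distribution, since the rank statistic only depends on the arrangement of
#' ranks; tied genes are re-permuted individually with the same permutation
#' set.
#'
#' @param cpm Numeric matrix of per-replicate cpm, genes x samples, for one
#'   organ.
#' @param zt Numeric vector of zeitgeber times, one per column of `cpm`.
#' @param alpha Cyclic-call cutoff on the combined p-value (default 0.01).
#' @param method,n_perm,seed As in [rhythm_pvalue()]; the seed governs the
#'   shared permutation set.
#' @param adjust `"none"` (default; raw p against `alpha`) or `"BH"` to apply
#'   a Benjamini-Hochberg correction across genes before the cyclic call.
#' @param organ Optional organ label copied to the result.
#' @param period Cycle length in hours (default 24).
#' @return A data frame with one row per gene: `gene`, `organ`, `statistic`,
#'   `s_max`, `p_value`, `is_cyclic`, `peak_zt`, `peak_shape`, `amplitude`,
#'   `degenerate`.
#' @export
rhythm_test <- function(cpm, zt, alpha = 0.01,
                        method = c("auto", "exact", "monte_carlo"),
                        n_perm = 10000, seed = NULL, adjust = c("none", "BH"),
                        organ = NA_character_, period = 24) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  cpm <- as.matrix(cpm)
  stopifnot(length(zt) == ncol(cpm))
  zts <- sort(unique(zt))
  G <- length(zts)
  if (G < 3) stop("need at least 3 distinct timepoints")
  ord <- order(match(zt, zts))       # columns grouped by Zt, circular order
  cpm <- cpm[, ord, drop = FALSE]
  ztc <- zt[ord]
  sizes <- as.integer(table(factor(ztc, levels = zts)))
  N <- sum(sizes)
  if (method == "auto") method <- if (N <= 10) "exact" else "monte_carlo"
  if (method == "monte_carlo" && n_perm < 100) {
    stop("n_perm must be at least 100")
  }
  hs <- .umbrella_hypotheses(G)
  H <- nrow(hs$hyp)
  slots <- split(seq_len(N), rep(seq_len(G), sizes))
  s_max <- .umbrella_smax(hs$C, sizes)
  tC <- t(hs$C)

  # shared arrangement set (row 1..N = slot positions)
  if (method == "exact") {
    P <- .enumerate_assignments(sizes)
  } else {
    if (!is.null(seed)) set.seed(seed)
    P <- t(vapply(seq_len(n_perm), function(i) sample.int(N), integer(N)))
  }
  # null statistic matrix for tie-free genes: ranks 1..N arranged by P
  S_free <- .u_matrix_rows(matrix(seq_len(N)[P], nrow(P)), slots) %*% tC

  tail_p <- function(S, s_obs) {
    cnt <- vapply(seq_len(H), function(h) sum(S[, h] >= s_obs[h] - 1e-9), 0)
    if (method == "exact") cnt / nrow(S) else (1 + cnt) / (nrow(S) + 1)
  }

  n_genes <- nrow(cpm)
  res <- data.frame(
    gene = if (is.null(rownames(cpm))) as.character(seq_len(n_genes))
           else rownames(cpm),
    organ = organ, statistic = NA_real_, s_max = NA_real_,
    p_value = NA_real_, is_cyclic = FALSE, peak_zt = NA_real_,
    peak_shape = NA_real_, amplitude = NA_real_, degenerate = FALSE,
    stringsAsFactors = FALSE)

  mean_prof <- vapply(seq_len(G),
                      function(k) rowMeans(cpm[, ztc == zts[k], drop = FALSE]),
                      numeric(n_genes))
  if (n_genes == 1) mean_prof <- matrix(mean_prof, 1)

  for (g in seq_len(n_genes)) {
    vals <- cpm[g, ]
    if (length(unique(vals)) == 1L) {        # flat profile: nothing to test
      res$statistic[g] <- NA; res$p_value[g] <- 1
      res$degenerate[g] <- TRUE; res$amplitude[g] <- 0
      next
    }
    s_obs <- drop(.u_matrix_rows(matrix(vals, 1), slots) %*% tC)
    if (anyDuplicated(vals)) {
      S <- .u_matrix_rows(matrix(vals[P], nrow(P)), slots) %*% tC
      p <- tail_p(S, s_obs)
    } else {
      p <- tail_p(S_free, s_obs)
    }
    best <- order(p, -s_obs / s_max)[1]
    res$statistic[g] <- s_obs[best]
    res$s_max[g] <- s_max[best]
    res$p_value[g] <- min(1, H * min(p))
    prof <- mean_prof[g, ]
    # amplitude is defined on relative expression; fall back to the raw
    # profile for inputs that are not cpm-like (negative values)
    if (all(prof >= 0)) prof <- unclass(relative_expression(prof))
    pk <- peak_statistics(prof, zts, period = period)
    res$peak_zt[g] <- pk$peak_zt
    res$peak_shape[g] <- pk$peak_shape
    res$amplitude[g] <- pk$amplitude
    res$degenerate[g] <- pk$degenerate
  }
  pcall <- if (adjust == "BH") stats::p.adjust(res$p_value, "BH") else
    res$p_value
  res$is_cyclic <- pcall < alpha & !res$degenerate
  res
}
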