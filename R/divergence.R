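## Functional-divergence classification of cyclic duplicate pairs.
##
## A duplicate pair's rhythm calls (which gene cycles, in which organ, with
## what peak Zt) are compared to decide whether the pair kept, split or lost
## the cyclic expression pattern: sub-/neo-functionalization shows up as only
## one copy cycling or the two copies cycling differently, while both copies
## cycling with the same peak ("superfunctionalization") is the redundant
## outcome.

.INTRA_LEVELS <- c("ONE_CYCLIC", "BOTH_CYCLIC_DIFFERENT", "BOTH_CYCLIC_SAME")
.INTER_LEVELS <- c("ONE_CYCLIC_MULTI", "DIFFERENT_BY_ORGAN",
                   "SYNCHRONIZED_MULTI")

# rhythm rows for one gene, keyed by organ
.cyclic_calls <- function(rhythm, gene) {
  rows <- rhythm[rhythm$gene == gene & rhythm$is_cyclic, , drop = FALSE]
  stats::setNames(rows$peak_zt, rows$organ)
}

.same_peak <- function(a, b, tol, period = 24) {
  d <- abs(a - b) %% period
  pmin(d, period - d) <= tol
}

#' Classify a duplicate pair cyclic in exactly one organ
#'
#' @param gene_a,gene_b The two gene ids of the pair.
#' @param rhythm Rhythm-result data frame (`gene`, `organ`, `is_cyclic`,
#'   `peak_zt`), covering both genes.
#' @param peak_tolerance Hours within which two peak Zt count as the same
#'   pattern (default 0: identical at the sampling resolution).
#' @return One of `"ONE_CYCLIC"`, `"BOTH_CYCLIC_DIFFERENT"`,
#'   `"BOTH_CYCLIC_SAME"`.
#' @export
classify_intra_organ <- function(gene_a, gene_b, rhythm, peak_tolerance = 0) {
  pa <- .cyclic_calls(rhythm, gene_a)
  pb <- .cyclic_calls(rhythm, gene_b)
  organs <- union(names(pa), names(pb))
  if (length(organs) != 1) {
    stop("pair is cyclic in ", length(organs),
         " organs; intra-organ classification needs exactly one")
  }
  org <- organs
  in_a <- org %in% names(pa)
  in_b <- org %in% names(pb)
  if (xor(in_a, in_b)) return("ONE_CYCLIC")
  if (.same_peak(pa[[org]], pb[[org]], peak_tolerance)) {
    "BOTH_CYCLIC_SAME"
  } else {
    "BOTH_CYCLIC_DIFFERENT"
  }
}

#' Classify a duplicate pair cyclic across several organs
#'
#' `ONE_CYCLIC_MULTI` when only one gene ever cycles;
#' `SYNCHRONIZED_MULTI` when both genes cycle, share at least one cyclic
#' organ, and agree in peak Zt in every shared cyclic organ; otherwise
#' `DIFFERENT_BY_ORGAN` (including both genes cycling in disjoint organ
#' sets).
#'
#' @inheritParams classify_intra_organ
#' @return One of `"ONE_CYCLIC_MULTI"`, `"DIFFERENT_BY_ORGAN"`,
#'   `"SYNCHRONIZED_MULTI"`.
#' @export
classify_inter_organ <- function(gene_a, gene_b, rhythm, peak_tolerance = 0) {
  pa <- .cyclic_calls(rhythm, gene_a)
  pb <- .cyclic_calls(rhythm, gene_b)
  organs <- union(names(pa), names(pb))
  if (length(organs) < 2) {
    stop("pair is cyclic in ", length(organs),
         " organ(s); inter-organ classification needs at least two")
  }
  if (!length(pa) || !length(pb)) return("ONE_CYCLIC_MULTI")
  shared <- intersect(names(pa), names(pb))
  if (length(shared) &&
      all(.same_peak(pa[shared], pb[shared], peak_tolerance))) {
    return("SYNCHRONIZED_MULTI")
  }
  "DIFFERENT_BY_ORGAN"
}

#' Classify a singleton cyclic in several organs
#'
#' @param gene Singleton gene id.
#' @inheritParams classify_intra_organ
#' @return `"SYNCHRONIZED"` when the peak Zt agrees across all cyclic
#'   organs, else `"DIFFERENT"`.
#' @export
classify_singleton_multi_organ <- function(gene, rhythm, peak_tolerance = 0) {
  p <- .cyclic_calls(rhythm, gene)
  if (length(p) < 2) {
    stop("singleton ", gene, " is cyclic in fewer than two organs")
  }
  if (all(.same_peak(p[-1], p[1], peak_tolerance))) "SYNCHRONIZED"
  else "DIFFERENT"
}

#' Classify every ohnolog pair (and optionally singletons)
#'
#' Routes each pair by the span of its cyclic calls: no cyclic call in any
#' organ -> `NOT_CYCLIC` scope; cyclic calls confined to one organ ->
#' `intra_organ`; otherwise `inter_organ`. Multi-organ cyclic singletons get
#' the `singleton_multi_organ` scope.
#'
#' @param pairs Data frame with columns `gene_a`, `gene_b` (e.g. from
#'   [identify_ohnolog_pairs()]).
#' @param rhythm Rhythm-result data frame covering all genes and organs.
#' @param singletons Optional character vector of singleton gene ids.
#' @param peak_tolerance Hours within which peaks count as equal (default 0).
#' @return Data frame of calls: `id`, `scope`, `category`, `n_organs`.
#' @export
classify_divergence <- function(pairs, rhythm, singletons = NULL,
                                peak_tolerance = 0) {
  calls <- list()
  for (k in seq_len(nrow(pairs))) {
    a <- pairs$gene_a[k]; b <- pairs$gene_b[k]
    organs <- union(names(.cyclic_calls(rhythm, a)),
                    names(.cyclic_calls(rhythm, b)))
    if (!length(organs)) {
      calls[[length(calls) + 1L]] <- data.frame(
        id = paste(a, b, sep = "|"), scope = "not_cyclic",
        category = "NOT_CYCLIC", n_organs = 0L, stringsAsFactors = FALSE)
    } else if (length(organs) == 1) {
      calls[[length(calls) + 1L]] <- data.frame(
        id = paste(a, b, sep = "|"), scope = "intra_organ",
        category = classify_intra_organ(a, b, rhythm, peak_tolerance),
        n_organs = 1L, stringsAsFactors = FALSE)
    } else {
      calls[[length(calls) + 1L]] <- data.frame(
        id = paste(a, b, sep = "|"), scope = "inter_organ",
        category = classify_inter_organ(a, b, rhythm, peak_tolerance),
        n_organs = length(organs), stringsAsFactors = FALSE)
    }
  }
  for (g in singletons) {
    p <- .cyclic_calls(rhythm, g)
    if (length(p) >= 2) {
      calls[[length(calls) + 1L]] <- data.frame(
        id = g, scope = "singleton_multi_organ",
        category = classify_singleton_multi_organ(g, rhythm, peak_tolerance),
        n_organs = length(p), stringsAsFactors = FALSE)
    }
  }
  if (!length(calls)) {
    return(data.frame(id = character(), scope = character(),
                      category = character(), n_organs = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, calls)
}

#' Summary count table of divergence calls
#'
#' Tallies calls per scope x category and derives the headline shares: the
#' fraction of cyclic pairs whose cyclic calls are confined to one organ, and
#' the total number of cyclic pairs (intra + inter).
#'
#' @param calls Data frame as returned by [classify_divergence()], or any
#'   data frame with `scope` and `category` columns.
#' @return A list: `table` (scope, category, count, percent-within-scope),
#'   `n_cyclic_pairs`, `n_intra`, `n_inter`,
#'   `single_organ_share_percent` (intra / cyclic pairs x 100).
#' @examples
#' calls <- data.frame(
#'   scope = rep(c("intra_organ", "inter_organ"), c(3, 3)),
#'   category = c("ONE_CYCLIC", "BOTH_CYCLIC_DIFFERENT", "BOTH_CYCLIC_SAME",
#'                "ONE_CYCLIC_MULTI", "DIFFERENT_BY_ORGAN",
#'                "SYNCHRONIZED_MULTI"))
#' summarize_divergence(calls)$n_cyclic_pairs
#' @export
summarize_divergence <- function(calls) {
  scopes <- list(intra_organ = .INTRA_LEVELS, inter_organ = .INTER_LEVELS,
                 singleton_multi_organ = c("SYNCHRONIZED", "DIFFERENT"),
                 not_cyclic = "NOT_CYCLIC")
  rows <- list()
  for (sc in names(scopes)) {
    sub <- calls[calls$scope == sc, , drop = FALSE]
    cnt <- table(factor(sub$category, levels = scopes[[sc]]))
    tot <- sum(cnt)
    rows[[sc]] <- data.frame(
      scope = sc, category = names(cnt), count = as.integer(cnt),
      percent = if (tot > 0) round(100 * as.integer(cnt) / tot, 1) else 0,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  n_intra <- sum(tab$count[tab$scope == "intra_organ"])
  n_inter <- sum(tab$count[tab$scope == "inter_organ"])
  n_pairs <- n_intra + n_inter
  list(table = tab,
       n_cyclic_pairs = n_pairs,
       n_intra = n_intra,
       n_inter = n_inter,
       single_organ_share_percent =
         if (n_pairs > 0) round(100 * n_intra / n_pairs, 1) else NA_real_)
}
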