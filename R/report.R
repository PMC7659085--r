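## Pipeline orchestration: expression -> rhythm -> homology -> divergence,
## plus the per-gene query that mirrors the expression-browser output and the
## machine-readable summary.

#' Run the full diurnal-expression pipeline
#'
#' Normalises counts to cpm, filters expressed genes per organ, runs the
#' umbrella rhythm test on expressed genes, and — when a homology table is
#' supplied — identifies ohnolog pairs and singletons and classifies their
#' functional divergence. Unexpressed genes are reported with `is_cyclic =
#' FALSE` and `NA` test fields. Deterministic given `seed`.
#'
#' @param counts Integer gene x sample count matrix.
#' @param samples Sample sheet (`sample_id`, `organ`, `zt`, `replicate`,
#'   optional `library_size`).
#' @param homology Optional homology table (see [read_homology_table()]).
#' @param alpha Cyclic-call p-value cutoff (default 0.01).
#' @param n_perm Monte-Carlo permutations for the rhythm test.
#' @param seed Integer seed for the permutation null.
#' @param peak_tolerance Peak-equality tolerance in hours for divergence
#'   classification (default 0).
#' @param chromosomes Anchored-chromosome list for the ohnolog filter.
#' @param out_dir Optional directory; when given, per-stage TSVs and a
#'   `summary.json` are written there.
#' @param verbose Log stage timings and record counts (default TRUE).
#' @return A list: `profiles` (per-organ expression profiles), `rhythm`
#'   (data frame over all organs and genes), `ohnologs`, `singletons`,
#'   `divergence` (calls + summary) or `NULL` when no homology table was
#'   given, and `summary` (see [summarize_counts()]).
#' @export
run_pipeline <- function(counts, samples, homology = NULL, alpha = 0.01,
                         n_perm = 10000, seed = 1L, peak_tolerance = 0,
                         chromosomes = as.character(1:24), out_dir = NULL,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  profiles <- organ_profiles(counts, samples)
  say("expression: %d organs, %d genes [%.1fs]", length(profiles),
      nrow(counts), as.numeric(Sys.time() - t0, units = "secs"))

  cpm <- compute_cpm(counts,
                     library_size = if ("library_size" %in% names(samples))
                       samples$library_size[match(colnames(counts),
                                                  samples$sample_id)])
  rhythm <- list()
  for (org in names(profiles)) {
    t1 <- Sys.time()
    expressed <- profiles[[org]]$expressed
    sel <- samples$sample_id[samples$organ == org]
    res <- data.frame(gene = rownames(counts), organ = org,
                      statistic = NA_real_, s_max = NA_real_,
                      p_value = NA_real_, is_cyclic = FALSE,
                      peak_zt = NA_real_, peak_shape = NA_real_,
                      amplitude = NA_real_, degenerate = FALSE,
                      expressed = expressed, stringsAsFactors = FALSE)
    if (any(expressed)) {
      sub <- rhythm_test(cpm[expressed, sel, drop = FALSE],
                         zt = samples$zt[match(sel, samples$sample_id)],
                         alpha = alpha, n_perm = n_perm, seed = seed,
                         organ = org)
      res[expressed, names(sub)] <- sub
    }
    rhythm[[org]] <- res
    say("rhythm[%s]: %d expressed, %d cyclic [%.1fs]", org, sum(expressed),
        sum(res$is_cyclic), as.numeric(Sys.time() - t1, units = "secs"))
  }
  rhythm <- do.call(rbind, c(rhythm, list(make.row.names = FALSE)))

  ohnologs <- NULL; singletons <- NULL; divergence <- NULL
  if (!is.null(homology)) {
    t1 <- Sys.time()
    ohnologs <- identify_ohnolog_pairs(homology, chromosomes = chromosomes)
    singletons <- identify_singletons(homology)
    calls <- classify_divergence(ohnologs, rhythm, singletons,
                                 peak_tolerance = peak_tolerance)
    divergence <- list(calls = calls, summary = summarize_divergence(calls))
    say("homology: %d pairs, %d singletons; divergence: %d calls [%.1fs]",
        nrow(ohnologs), length(singletons), nrow(calls),
        as.numeric(Sys.time() - t1, units = "secs"))
  } else {
    say("homology table absent; divergence stage skipped")
  }

  summary <- summarize_counts(
    rhythm = rhythm,
    n_pairs = if (!is.null(ohnologs)) nrow(ohnologs) else NA_integer_,
    n_singletons = if (!is.null(singletons)) length(singletons)
                   else NA_integer_,
    n_genes = nrow(counts),
    divergence = divergence$summary)

  result <- list(profiles = profiles, rhythm = rhythm, ohnologs = ohnologs,
                 singletons = singletons, divergence = divergence,
                 summary = summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(rhythm, file.path(out_dir, "rhythm_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(ohnologs)) {
      utils::write.table(ohnologs, file.path(out_dir, "ohnolog_pairs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(data.frame(gene = singletons),
                         file.path(out_dir, "singletons.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(divergence$calls,
                         file.path(out_dir, "divergence_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

#' Per-gene summary across organs (the browser's query table)
#'
#' @param result A [run_pipeline()] result.
#' @param gene Gene id present in the results.
#' @return A list: `summary` (one row per organ: mean daily cpm, expressed,
#'   cyclic, p-value, peak Zt, peak shape, amplitude) and `relative` (organ
#'   x Zt matrix of the gene's relative-expression series).
#' @export
query_gene <- function(result, gene) {
  rows <- result$rhythm[result$rhythm$gene == gene, , drop = FALSE]
  if (!nrow(rows)) {
    stop("gene '", gene, "' not found; use search_genes() to look up ids ",
         "by name keyword")
  }
  organs <- names(result$profiles)
  mean_cpm <- vapply(organs, function(org) {
    mean(result$profiles[[org]]$mean_cpm[gene, ])
  }, 0)
  summary <- data.frame(
    organ = organs,
    mean_cpm = mean_cpm,
    expressed = vapply(organs, function(org)
      result$profiles[[org]]$expressed[[gene]], TRUE),
    p_value = rows$p_value[match(organs, rows$organ)],
    is_cyclic = rows$is_cyclic[match(organs, rows$organ)],
    peak_zt = rows$peak_zt[match(organs, rows$organ)],
    peak_shape = rows$peak_shape[match(organs, rows$organ)],
    amplitude = rows$amplitude[match(organs, rows$organ)],
    row.names = NULL, stringsAsFactors = FALSE)
  rel <- t(vapply(organs, function(org)
    result$profiles[[org]]$relative[gene, ],
    numeric(ncol(result$profiles[[1]]$relative))))
  list(summary = summary, relative = rel)
}

#' Search gene ids by name keyword
#'
#' Case-insensitive substring search through a homology table's gene names,
#' mirroring the browser's common-name-to-id converter.
#'
#' @param homology Homology table with `ensembl_gene_id` and
#'   `external_gene_name`.
#' @param keyword Substring to match.
#' @return Data frame `ensembl_gene_id`, `external_gene_name` of matches.
#' @export
search_genes <- function(homology, keyword) {
  hit <- grepl(keyword, homology$external_gene_name, ignore.case = TRUE)
  out <- unique(homology[hit & !is.na(homology$external_gene_name),
                         c("ensembl_gene_id", "external_gene_name")])
  rownames(out) <- NULL
  out
}

#' Machine-readable pipeline summary
#'
#' Per-organ expressed/cyclic counts with the percentage of expressed genes
#' called cyclic, plus the homology tallies and the share of genes trackable
#' through the duplication (`(2 * pairs + singletons) / total genes`).
#' Counts may come from a pipeline run (`rhythm`) or be supplied directly
#' (`per_organ`), e.g. to recompute published arithmetic.
#'
#' @param rhythm Rhythm data frame with `organ`, `expressed`, `is_cyclic`
#'   columns (as produced by [run_pipeline()]).
#' @param per_organ Alternative to `rhythm`: data frame with columns
#'   `organ`, `expressed` (count), `cyclic` (count).
#' @param n_pairs,n_singletons,n_genes Homology tallies (optional).
#' @param divergence Optional [summarize_divergence()] result to embed.
#' @return A list: `per_organ` (organ, expressed, cyclic,
#'   `cyclic_percent` to 1 d.p.), `n_ohnolog_pairs`, `n_singletons`,
#'   `n_genes`, `tracked_genes`, `tracked_percent` (0 d.p.), `divergence`.
#' @examples
#' summarize_counts(per_organ = data.frame(organ = "eye", expressed = 18377,
#'                                         cyclic = 4033))
#' @export
summarize_counts <- function(rhythm = NULL, per_organ = NULL,
                             n_pairs = NA_integer_,
                             n_singletons = NA_integer_,
                             n_genes = NA_integer_, divergence = NULL) {
  if (is.null(per_organ)) {
    if (is.null(rhythm)) stop("supply either rhythm results or per_organ")
    orgs <- unique(rhythm$organ)
    per_organ <- data.frame(
      organ = orgs,
      expressed = vapply(orgs, function(o)
        sum(rhythm$expressed[rhythm$organ == o], na.rm = TRUE), 0),
      cyclic = vapply(orgs, function(o)
        sum(rhythm$is_cyclic[rhythm$organ == o], na.rm = TRUE), 0),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  per_organ$cyclic_percent <- ifelse(
    per_organ$expressed > 0,
    round(100 * per_organ$cyclic / per_organ$expressed, 1), 0)
  tracked <- if (!is.na(n_pairs) && !is.na(n_singletons))
    2L * n_pairs + n_singletons else NA_integer_
  list(per_organ = per_organ,
       n_ohnolog_pairs = n_pairs,
       n_singletons = n_singletons,
       n_genes = n_genes,
       tracked_genes = tracked,
       tracked_percent = if (!is.na(tracked) && !is.na(n_genes) &&
                             n_genes > 0)
         round(100 * tracked / n_genes) else NA_real_,
       divergence = divergence)
}
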