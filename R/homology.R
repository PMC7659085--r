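## Ohnolog / singleton identification from Biomart-style homology tables and
## the synteny co-linearity score.
##
## The duplicate-history logic: after a whole-genome duplication, a retained
## duplicate pair ("ohnologs") descends from the duplication node and maps
## 2:1 onto a non-duplicated outgroup (spotted gar); a gene resolved back to
## one copy ("singleton") maps 1:1. Both relationships are read off Ensembl
## Compara annotations; this module only filters them.

.HOMOLOGY_COLS <- c("ensembl_gene_id", "paralog_gene_id", "paralog_subtype",
                    "paralog_orthology_type", "gar_ortholog_id",
                    "gar_orthology_type", "chromosome_name", "start_position",
                    "end_position", "external_gene_name")

#' Duplication-ancestor labels treated as TGD / post-TGD duplications
#'
#' The singleton screen drops genes whose paralog annotations carry any of
#' these duplication-ancestor labels. The list keeps the misspelt variants
#' found in some Biomart exports ("Cyprinodontlformes", "Cyprinodontoldel",
#' "Poecllilnae") alongside the corrected spellings, so either form of user
#' table is handled.
#'
#' @return Character vector of ancestor labels.
#' @export
post_tgd_ancestors <- function() {
  c("Clupeocephala", "Euteleosteomorpha", "Percomorphaceae", "Ovalentaria",
    "Atherinomorphae", "Cyprinodontlformes", "Cyprinodontoldel",
    "Poecllilnae", "Xiphophorus",
    "Cyprinodontiformes", "Cyprinodontoidei", "Poeciliinae")
}

.check_homology <- function(table) {
  miss <- setdiff(.HOMOLOGY_COLS, names(table))
  if (length(miss)) {
    stop("homology table is missing column(s): ", paste(miss, collapse = ", "))
  }
  invisible(table)
}

.not_blank <- function(x) !is.na(x) & x != ""

# distinct non-empty gar orthologs annotated to a gene
.gar_set <- function(table, gene) {
  g <- table$gar_ortholog_id[table$ensembl_gene_id == gene]
  sort(unique(g[.not_blank(g)]))
}

#' Identify ohnolog pairs (2:1 gene relationships to gar)
#'
#' Builds candidate pairs from the paralog annotations and applies, in order,
#' the five retention filters: (1) drop pairs whose duplication ancestor is
#' "Clupeocephala" (a node younger than the gar split); (2) drop pairs whose
#' two genes do not share exactly one gar ortholog; (3) drop every pair
#' containing a gene that occurs in more than one surviving candidate pair;
#' (4) drop pairs with a gene not annotated to a declared chromosome
#' (unanchored contigs, mitochondrion); (5) drop pairs whose genes lie less
#' than `min_separation_bp` apart on the same chromosome (tandem duplicates).
#'
#' The five predicates are conjunctive: the multiplicity filter counts gene
#' occurrences among pairs surviving the two row-level ancestry/orthology
#' filters, so the final set does not depend on application order.
#'
#' @param table Homology data frame with the columns listed in
#'   [read_homology_table()].
#' @param chromosomes Character vector of chromosome names that count as
#'   anchored; default `as.character(1:24)`.
#' @param min_separation_bp Minimum start-to-start distance for a same-
#'   chromosome pair (default 5e6).
#' @param excluded_ancestors Duplication-ancestor labels failing filter 1
#'   (default `"Clupeocephala"`).
#' @param diagnostics If `TRUE`, return every candidate pair with one logical
#'   column per filter (`fail_ancestor`, `fail_gar`, `fail_multiplicity`,
#'   `fail_unanchored`, `fail_tandem`) instead of only the passing pairs.
#' @return Data frame of pairs sorted by `gene_a`: columns `gene_a`,
#'   `gene_b`, `gar_id`, `chromosome_a`, `start_a`, `chromosome_b`,
#'   `start_b` (plus the filter columns when `diagnostics = TRUE`).
#' @export
identify_ohnolog_pairs <- function(table,
                                   chromosomes = as.character(1:24),
                                   min_separation_bp = 5e6,
                                   excluded_ancestors = "Clupeocephala",
                                   diagnostics = FALSE) {
  .check_homology(table)
  par_rows <- table[.not_blank(table$paralog_gene_id), , drop = FALSE]
  if (!nrow(par_rows)) {
    empty <- data.frame(gene_a = character(), gene_b = character(),
                        gar_id = character(), chromosome_a = character(),
                        start_a = numeric(), chromosome_b = character(),
                        start_b = numeric(), stringsAsFactors = FALSE)
    return(empty)
  }
  a <- pmin(par_rows$ensembl_gene_id, par_rows$paralog_gene_id)
  b <- pmax(par_rows$ensembl_gene_id, par_rows$paralog_gene_id)
  key <- paste(a, b)
  first <- !duplicated(key)
  cand <- data.frame(gene_a = a[first], gene_b = b[first],
                     subtype = par_rows$paralog_subtype[first],
                     stringsAsFactors = FALSE)

  loc <- table[!duplicated(table$ensembl_gene_id),
               c("ensembl_gene_id", "chromosome_name", "start_position")]
  ia <- match(cand$gene_a, loc$ensembl_gene_id)
  ib <- match(cand$gene_b, loc$ensembl_gene_id)
  cand$chromosome_a <- loc$chromosome_name[ia]
  cand$start_a <- loc$start_position[ia]
  cand$chromosome_b <- loc$chromosome_name[ib]
  cand$start_b <- loc$start_position[ib]

  gar_a <- lapply(cand$gene_a, .gar_set, table = table)
  gar_b <- lapply(cand$gene_b, .gar_set, table = table)
  shared_one <- mapply(function(x, y) {
    length(x) >= 1 && length(y) >= 1 && length(union(x, y)) == 1
  }, gar_a, gar_b)
  cand$gar_id <- ifelse(shared_one,
                        vapply(gar_a, function(x) x[1] %||% NA_character_,
                               ""), NA_character_)

  cand$fail_ancestor <- cand$subtype %in% excluded_ancestors
  cand$fail_gar <- !shared_one
  row_pass <- !cand$fail_ancestor & !cand$fail_gar
  genes_pass <- c(cand$gene_a[row_pass], cand$gene_b[row_pass])
  multi <- names(which(table(genes_pass) > 1))
  cand$fail_multiplicity <- (cand$gene_a %in% multi) |
    (cand$gene_b %in% multi)
  cand$fail_unanchored <- !(cand$chromosome_a %in% chromosomes) |
    !(cand$chromosome_b %in% chromosomes)
  cand$fail_tandem <- !cand$fail_unanchored &
    cand$chromosome_a == cand$chromosome_b &
    abs(cand$start_a - cand$start_b) < min_separation_bp
  cand$fail_tandem[is.na(cand$fail_tandem)] <- FALSE

  cand <- cand[order(cand$gene_a), , drop = FALSE]
  rownames(cand) <- NULL
  keep_cols <- c("gene_a", "gene_b", "gar_id", "chromosome_a", "start_a",
                 "chromosome_b", "start_b")
  if (diagnostics) {
    return(cand[, c(keep_cols, grep("^fail_", names(cand), value = TRUE))])
  }
  pass <- !(cand$fail_ancestor | cand$fail_gar | cand$fail_multiplicity |
              cand$fail_unanchored | cand$fail_tandem)
  out <- cand[pass, keep_cols, drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(x, y) if (is.null(x) || !length(x)) y else x

#' Identify singletons (1:1 gene relationships to gar)
#'
#' Applies the four singleton exclusions: (1) drop genes with any paralog row
#' whose duplication ancestor indicates a TGD or post-TGD lineage-specific
#' duplication (see [post_tgd_ancestors()]); (2) drop genes with a
#' "Neopterygii" duplication ancestor (a node prone to tree-reconstruction
#' artifacts); (3) drop genes whose name carries a duplication hint
#' ("one of many" / "1 of many", case-insensitive); (4) require exactly one
#' gar ortholog of orthology type `ortholog_one2one`.
#'
#' @inheritParams identify_ohnolog_pairs
#' @param excluded_ancestors Ancestor labels for exclusion 1.
#' @param artifact_ancestors Ancestor labels for exclusion 2.
#' @param diagnostics If `TRUE`, return every gene with one logical column
#'   per exclusion (`fail_tgd_ancestor`, `fail_neopterygii`, `fail_name`,
#'   `fail_orthology`).
#' @return Character vector of singleton gene ids (sorted), or the
#'   diagnostics data frame.
#' @export
identify_singletons <- function(table,
                                excluded_ancestors = post_tgd_ancestors(),
                                artifact_ancestors = "Neopterygii",
                                diagnostics = FALSE) {
  .check_homology(table)
  genes <- sort(unique(table$ensembl_gene_id))
  sub_by_gene <- split(table$paralog_subtype[.not_blank(table$paralog_gene_id)],
                       table$ensembl_gene_id[.not_blank(table$paralog_gene_id)])
  has_anc <- function(g, labels) {
    any(sub_by_gene[[g]] %in% labels)
  }
  name_of <- table$external_gene_name[match(genes, table$ensembl_gene_id)]
  dup_name <- grepl("(one|1) of many", name_of, ignore.case = TRUE)
  dup_name[is.na(dup_name)] <- FALSE

  one2one <- vapply(genes, function(g) {
    rows <- table[table$ensembl_gene_id == g, ]
    ids <- unique(rows$gar_ortholog_id[.not_blank(rows$gar_ortholog_id)])
    types <- unique(rows$gar_orthology_type[.not_blank(rows$gar_ortholog_id)])
    length(ids) == 1 && all(types == "ortholog_one2one")
  }, TRUE)

  diag <- data.frame(
    gene = genes,
    fail_tgd_ancestor = vapply(genes, has_anc, TRUE,
                               labels = excluded_ancestors),
    fail_neopterygii = vapply(genes, has_anc, TRUE,
                              labels = artifact_ancestors),
    fail_name = dup_name,
    fail_orthology = !one2one,
    stringsAsFactors = FALSE)
  rownames(diag) <- NULL
  if (diagnostics) return(diag)
  diag$gene[!(diag$fail_tgd_ancestor | diag$fail_neopterygii |
                diag$fail_name | diag$fail_orthology)]
}

# coordinate-ordered neighbours of a gene on its chromosome, up to n per side
.window_neighbours <- function(gene, coords, n) {
  i <- match(gene, coords$gene_id)
  if (is.na(i)) stop("gene ", gene, " absent from the coordinate table")
  chr <- coords$chromosome[i]
  on_chr <- coords[coords$chromosome == chr, , drop = FALSE]
  on_chr <- on_chr[order(on_chr$start), , drop = FALSE]
  pos <- match(gene, on_chr$gene_id)
  down <- on_chr$gene_id[seq_len(pos - 1)]
  down <- utils::tail(down, n)
  up <- on_chr$gene_id[-seq_len(pos)]
  up <- utils::head(up, n)
  list(down = down, up = up)
}

#' Synteny co-linearity score for a (gene, candidate ortholog) pair
#'
#' Takes the focal gene's up to `n` upstream and `n` downstream chromosome
#' neighbours and asks how many of them have a gar ortholog lying among the
#' candidate gar gene's own +/- `n` neighbours. The score is that count
#' divided by the number of focal neighbours considered (2n for an interior
#' gene; windows truncate at chromosome ends), so it lies in \[0, 1\].
#'
#' @param gene Focal gene id.
#' @param gar_gene Candidate gar ortholog id.
#' @param gene_coords Data frame `gene_id`, `chromosome`, `start` for the
#'   focal genome.
#' @param gar_coords Same for the gar genome.
#' @param ortholog_map Data frame `gene_id`, `gar_id` listing known
#'   gene -> gar orthology assignments (typically derived from the homology
#'   table).
#' @param n Window half-width in genes (default 10).
#' @return Score in \[0, 1\]; attribute `n_neighbours` gives the window size
#'   actually used. An empty window returns 0 with attribute `empty = TRUE`.
#' @export
synteny_score <- function(gene, gar_gene, gene_coords, gar_coords,
                          ortholog_map, n = 10) {
  stopifnot(n >= 1)
  w <- .window_neighbours(gene, gene_coords, n)
  focal_nb <- c(w$down, w$up)
  if (!length(focal_nb)) {
    return(structure(0, n_neighbours = 0L, empty = TRUE))
  }
  gw <- .window_neighbours(gar_gene, gar_coords, n)
  gar_nb <- c(gw$down, gw$up)
  hits <- vapply(focal_nb, function(g) {
    orth <- ortholog_map$gar_id[ortholog_map$gene_id == g]
    any(orth %in% gar_nb)
  }, TRUE)
  structure(sum(hits) / length(focal_nb),
            n_neighbours = length(focal_nb), empty = FALSE)
}

#' Resolve a gene's gar ortholog by maximal synteny score
#'
#' When a gene is annotated orthologous to several gar genes, the candidate
#' with the highest synteny co-linearity score is assigned. Ties are broken
#' towards the lexicographically smallest gar id, with a warning.
#'
#' @param gene Focal gene id.
#' @param candidates Character vector of candidate gar gene ids (>= 1).
#' @inheritParams synteny_score
#' @return A list: `gene`, `gar_id` (the chosen candidate), `score`, and
#'   `scores` (named vector over all candidates).
#' @export
assign_best_ortholog <- function(gene, candidates, gene_coords, gar_coords,
                                 ortholog_map, n = 10) {
  if (!length(candidates)) stop("no candidate gar orthologs for gene ", gene)
  sc <- vapply(candidates, function(gg) {
    as.numeric(synteny_score(gene, gg, gene_coords, gar_coords,
                             ortholog_map, n = n))
  }, 0)
  top <- which(sc == max(sc))
  if (length(top) > 1) {
    pick <- top[order(candidates[top])[1]]
    warning("synteny-score tie for gene ", gene, "; choosing ",
            candidates[pick])
  } else {
    pick <- top
  }
  list(gene = gene, gar_id = candidates[pick], score = sc[pick], scores = sc)
}

#' Read a Biomart-style homology table from TSV
#'
#' Expects the columns `ensembl_gene_id`, `paralog_gene_id`,
#' `paralog_subtype`, `paralog_orthology_type`, `gar_ortholog_id`,
#' `gar_orthology_type`, `chromosome_name`, `start_position`,
#' `end_position`, `external_gene_name`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return Data frame with the columns above.
#' @export
read_homology_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character",
                           na.strings = c("NA", ""))
  .check_homology(tab)
  tab$start_position <- as.numeric(tab$start_position)
  tab$end_position <- as.numeric(tab$end_position)
  tab
}
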