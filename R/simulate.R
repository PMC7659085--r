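## Seeded generators for the study design: negative-binomial organ time
## courses with a planted fraction of cosine-rhythmic genes, and
## Biomart-style homology tables with planted ohnolog pairs, singletons and
## decoy genes that each violate exactly one identification rule.

.DEFAULT_ORGANS <- c("skin", "brain", "ovary", "heart", "muscle", "eye",
                     "gills", "liver", "testis")
.DEFAULT_ZT <- seq(0.5, 21.5, by = 3)

.DECOY_CLASSES <- c("clupeocephala_ancestor", "multi_gar_ortholog",
                    "repeated_gene", "unanchored_contig", "tandem_lt_5Mbp",
                    "neopterygii_ancestor", "one_of_many_name",
                    "non_one2one_ortholog")

#' Configuration for the expression time-course simulator
#'
#' Defaults mirror the study design: 9 organs sampled at 8 zeitgeber times
#' 3 h apart (Zt 0.5 ... 21.5) with 2 biological replicates, library sizes in
#' the 46.1-51.8 million read range, and a planted 10% of cosine-rhythmic
#' genes per organ.
#'
#' @param n_genes Number of genes.
#' @param organs Character vector of organ labels.
#' @param timepoints_zt Strictly increasing hours in \[0, 24).
#' @param n_replicates Biological replicates per (organ, Zt), >= 1.
#' @param cyclic_fraction Planted fraction of cyclic genes per organ, in
#'   \[0, 1\]; exactly `round(n_genes * cyclic_fraction)` genes are planted.
#' @param amplitude_range Interval for the relative cosine amplitude A in the
#'   mean model `mu(t) = b * (1 + A * cos(2*pi*(t - phi)/24))`; A in \[0, 1\].
#' @param baseline_mean_range Interval for the baseline mean b (counts).
#' @param dispersion Negative-binomial dispersion alpha
#'   (`var = mu + alpha * mu^2`), > 0.
#' @param library_size_range Interval for per-sample sequencing depth
#'   (reads); realised totals hit the drawn depth exactly via multinomial
#'   resampling.
#' @param seed Integer seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000,
                       organs = .DEFAULT_ORGANS,
                       timepoints_zt = .DEFAULT_ZT,
                       n_replicates = 2,
                       cyclic_fraction = 0.1,
                       amplitude_range = c(0.3, 1),
                       baseline_mean_range = c(5, 500),
                       dispersion = 0.05,
                       library_size_range = c(46.1e6, 51.8e6),
                       seed = 1L) {
  if (!length(organs)) stop("config error: at least one organ required")
  if (!length(timepoints_zt)) stop("config error: timepoints required")
  if (any(diff(timepoints_zt) <= 0) ||
      any(timepoints_zt < 0 | timepoints_zt >= 24)) {
    stop("config error: timepoints must be strictly increasing in [0, 24)")
  }
  if (cyclic_fraction < 0 || cyclic_fraction > 1) {
    stop("config error: cyclic_fraction must lie in [0, 1]")
  }
  if (n_replicates < 1) stop("config error: n_replicates must be >= 1")
  if (dispersion <= 0) stop("config error: dispersion must be positive")
  if (any(amplitude_range < 0) || any(amplitude_range > 1)) {
    stop("config error: amplitude_range must lie in [0, 1]")
  }
  structure(list(n_genes = n_genes, organs = organs,
                 timepoints_zt = timepoints_zt, n_replicates = n_replicates,
                 cyclic_fraction = cyclic_fraction,
                 amplitude_range = amplitude_range,
                 baseline_mean_range = baseline_mean_range,
                 dispersion = dispersion,
                 library_size_range = library_size_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# cosine mean model; A = 0 gives a flat profile at b
.cosine_mean <- function(t, b, A, phi, period = 24) {
  b * (1 + A * cos(2 * pi * (t - phi) / period))
}

#' Simulate an organ x timepoint x replicate count matrix with planted
#' rhythms
#'
#' For each organ, a planted subset of genes follows the cosine mean model
#' `mu(t) = b * (1 + A * cos(2*pi*(t - phi)/24))` with phase phi drawn from
#' the sampled Zt grid (so planted peaks are recoverable at the sampling
#' resolution); the rest are flat at b. Counts are negative-binomial draws
#' that are then multinomially resampled to a drawn per-sample library size,
#' which preserves relative means while making cpm normalisation
#' non-trivial.
#'
#' @param config A [sim_config()] object.
#' @return A list: `counts` (integer genes x samples matrix), `samples`
#'   (data frame `sample_id`, `organ`, `zt`, `replicate`), `truth`
#'   (data frame `gene`, `organ`, `is_cyclic`, `true_peak_zt`,
#'   `true_amplitude`, one row per gene x organ).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- sprintf("gene_%04d", seq_len(config$n_genes))
  samples <- expand.grid(replicate = seq_len(config$n_replicates),
                         zt = config$timepoints_zt,
                         organ = config$organs,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[, c("organ", "zt", "replicate")]
  samples$sample_id <- sprintf("%s_zt%04.1f_r%d", samples$organ, samples$zt,
                               samples$replicate)
  counts <- matrix(0L, config$n_genes, nrow(samples),
                   dimnames = list(genes, samples$sample_id))
  truth <- list()
  n_cyc <- round(config$n_genes * config$cyclic_fraction)
  for (org in config$organs) {
    b <- stats::runif(config$n_genes, config$baseline_mean_range[1],
                      config$baseline_mean_range[2])
    cyc <- sort(sample.int(config$n_genes, n_cyc))
    A <- numeric(config$n_genes)
    A[cyc] <- stats::runif(n_cyc, config$amplitude_range[1],
                           config$amplitude_range[2])
    phi <- rep(NA_real_, config$n_genes)
    phi[cyc] <- sample(config$timepoints_zt, n_cyc, replace = TRUE)
    for (j in which(samples$organ == org)) {
      mu <- ifelse(seq_len(config$n_genes) %in% cyc,
                   .cosine_mean(samples$zt[j], b, A, phi), b)
      raw <- stats::rnbinom(config$n_genes, mu = mu,
                            size = 1 / config$dispersion)
      if (sum(raw) == 0) raw <- mu   # degenerate draw: fall back to means
      lib <- round(stats::runif(1, config$library_size_range[1],
                                config$library_size_range[2]))
      counts[, j] <- as.integer(stats::rmultinom(1, size = lib, prob = raw))
    }
    truth[[org]] <- data.frame(
      gene = genes, organ = org,
      is_cyclic = seq_len(config$n_genes) %in% cyc,
      true_peak_zt = phi, true_amplitude = A, stringsAsFactors = FALSE)
  }
  list(counts = counts,
       samples = samples[, c("sample_id", "organ", "zt", "replicate")],
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Configuration for the homology-table simulator
#'
#' @param n_ohnolog_pairs Planted ohnolog pairs (2:1 to gar).
#' @param n_singletons Planted singletons (1:1 to gar).
#' @param decoy_counts Named integer vector over the decoy classes
#'   `clupeocephala_ancestor`, `multi_gar_ortholog`, `repeated_gene`,
#'   `unanchored_contig`, `tandem_lt_5Mbp`, `neopterygii_ancestor`,
#'   `one_of_many_name`, `non_one2one_ortholog`; each decoy unit violates
#'   exactly the identification rule it is named for and passes all others.
#' @param n_chromosomes Chromosomes in each genome.
#' @param genes_per_chromosome Gene slots per chromosome (slots are spaced
#'   6 Mbp apart so distinct slots always clear the 5 Mbp tandem rule).
#' @param seed Integer seed.
#' @return A validated list of class `homology_sim_config`.
#' @export
homology_sim_config <- function(n_ohnolog_pairs = 50,
                                n_singletons = 100,
                                decoy_counts = stats::setNames(
                                  rep(1L, length(.DECOY_CLASSES)),
                                  .DECOY_CLASSES),
                                n_chromosomes = 24,
                                genes_per_chromosome = 100,
                                seed = 1L) {
  if (length(decoy_counts)) {
    bad <- setdiff(names(decoy_counts), .DECOY_CLASSES)
    if (length(bad)) {
      stop("config error: unknown decoy class(es): ",
           paste(bad, collapse = ", "))
    }
  }
  if (n_ohnolog_pairs < 0 || n_singletons < 0 || any(decoy_counts < 0)) {
    stop("config error: counts must be non-negative")
  }
  structure(list(n_ohnolog_pairs = n_ohnolog_pairs,
                 n_singletons = n_singletons,
                 decoy_counts = decoy_counts,
                 n_chromosomes = n_chromosomes,
                 genes_per_chromosome = genes_per_chromosome,
                 seed = as.integer(seed)),
            class = "homology_sim_config")
}

#' Simulate a Biomart-style homology table with planted ground truth
#'
#' Planted pairs satisfy every ohnolog inclusion rule (TGD-era duplication
#' ancestor `"Osteoglossocephalai"`, exactly one shared gar ortholog, genes
#' on anchored chromosomes at least 6 Mbp apart when co-located); planted
#' singletons have no paralog annotations and a single `ortholog_one2one`
#' gar ortholog; each decoy unit violates only its named rule. Both genomes
#' are laid out co-linearly (gene slots 6 Mbp apart, gar order mirroring
#' fish order), so neighbourhood synteny scores are high for true orthologs.
#'
#' @param config A [homology_sim_config()] object.
#' @return A list: `table` (homology data frame, see
#'   [read_homology_table()] for columns), `truth` (data frame `gene`,
#'   `label` in `ohnolog | singleton | <decoy class>`, `unit`),
#'   `gene_coords` and `gar_coords` (data frames `gene_id`, `chromosome`,
#'   `start`), `ortholog_map` (`gene_id`, `gar_id`, true assignments).
#' @export
simulate_homology <- function(config) {
  stopifnot(inherits(config, "homology_sim_config"))
  set.seed(config$seed)
  spacing <- 6e6
  gene_len <- 1e4
  env <- new.env()
  env$rows <- list(); env$truth <- list()
  env$fish_slot <- 0L; env$gar_slot <- 0L
  env$fish_n <- 0L; env$gar_n <- 0L
  env$gene_coords <- list(); env$gar_coords <- list()
  env$ortho <- list()

  place_fish <- function(chrom = NULL, start = NULL) {
    env$fish_n <- env$fish_n + 1L
    id <- sprintf("FISHG%05d", env$fish_n)
    if (is.null(chrom)) {
      env$fish_slot <- env$fish_slot + 1L
      chrom <- as.character(((env$fish_slot - 1L) %/%
                               config$genes_per_chromosome) + 1L)
      if (as.integer(chrom) > config$n_chromosomes) {
        stop("config error: genome layout exhausted; increase ",
             "n_chromosomes or genes_per_chromosome")
      }
      slot <- (env$fish_slot - 1L) %% config$genes_per_chromosome
      start <- 1 + slot * spacing
    }
    env$gene_coords[[id]] <- data.frame(gene_id = id, chromosome = chrom,
                                        start = start,
                                        stringsAsFactors = FALSE)
    list(id = id, chrom = chrom, start = start, end = start + gene_len)
  }
  place_gar <- function() {
    env$gar_n <- env$gar_n + 1L
    id <- sprintf("GARG%05d", env$gar_n)
    env$gar_slot <- env$gar_slot + 1L
    chrom <- paste0("LG", ((env$gar_slot - 1L) %/%
                             config$genes_per_chromosome) + 1L)
    start <- 1 + ((env$gar_slot - 1L) %% config$genes_per_chromosome) *
      spacing
    env$gar_coords[[id]] <- data.frame(gene_id = id, chromosome = chrom,
                                       start = start,
                                       stringsAsFactors = FALSE)
    id
  }
  add_row <- function(g, paralog = NA, subtype = NA, ptype = NA,
                      gar = NA, gar_type = NA, name = NA) {
    env$rows[[length(env$rows) + 1L]] <- data.frame(
      ensembl_gene_id = g$id, paralog_gene_id = paralog,
      paralog_subtype = subtype, paralog_orthology_type = ptype,
      gar_ortholog_id = gar, gar_orthology_type = gar_type,
      chromosome_name = g$chrom, start_position = g$start,
      end_position = g$end, external_gene_name = name,
      stringsAsFactors = FALSE)
  }
  add_truth <- function(id, label, unit) {
    env$truth[[length(env$truth) + 1L]] <- data.frame(
      gene = id, label = label, unit = unit, stringsAsFactors = FALSE)
  }
  add_ortho <- function(fish_id, gar_id) {
    env$ortho[[length(env$ortho) + 1L]] <- data.frame(
      gene_id = fish_id, gar_id = gar_id, stringsAsFactors = FALSE)
  }
  tgd <- "Osteoglossocephalai"

  # a pair passing every ohnolog filter, parameterisable for decoy variants
  emit_pair <- function(unit, label, subtype = tgd, tandem = FALSE,
                        unanchored = FALSE, extra_gar = FALSE) {
    a <- place_fish()
    b <- if (tandem) {
      place_fish(chrom = a$chrom, start = a$start + 3e6)
    } else if (unanchored) {
      place_fish(chrom = sprintf("contig_%05d", env$fish_n + 1L),
                 start = 1)
    } else {
      place_fish()
    }
    gar <- place_gar()
    add_row(a, b$id, subtype, "within_species_paralog", gar,
            "ortholog_one2many", paste0("g", env$fish_n - 1L))
    if (extra_gar) {
      gar2 <- place_gar()
      add_row(a, b$id, subtype, "within_species_paralog", gar2,
              "ortholog_one2many", paste0("g", env$fish_n - 1L))
    }
    add_row(b, a$id, subtype, "within_species_paralog", gar,
            "ortholog_one2many", paste0("g", env$fish_n))
    add_truth(a$id, label, unit)
    add_truth(b$id, label, unit)
    add_ortho(a$id, gar); add_ortho(b$id, gar)
    list(a = a, b = b, gar = gar)
  }
  emit_singleton <- function(unit, label, name = NULL,
                             gar_type = "ortholog_one2one",
                             paralog_of = NULL, subtype = NA) {
    s <- place_fish()
    gar <- place_gar()
    if (is.null(name)) name <- paste0("s", env$fish_n)
    if (is.null(paralog_of)) {
      add_row(s, NA, NA, NA, gar, gar_type, name)
    } else {
      add_row(s, paralog_of, subtype, "within_species_paralog", gar,
              gar_type, name)
    }
    add_truth(s$id, label, unit)
    add_ortho(s$id, gar)
    s
  }

  for (k in seq_len(config$n_ohnolog_pairs)) {
    emit_pair(sprintf("pair_%03d", k), "ohnolog")
  }
  for (k in seq_len(config$n_singletons)) {
    emit_singleton(sprintf("singleton_%03d", k), "singleton")
  }
  dc0 <- config$decoy_counts
  dc <- function(cls) { v <- dc0[cls]; if (is.na(v)) 0L else as.integer(v) }
  for (k in seq_len(dc("clupeocephala_ancestor"))) {
    emit_pair(sprintf("clup_%02d", k), "clupeocephala_ancestor",
              subtype = "Clupeocephala")
  }
  for (k in seq_len(dc("multi_gar_ortholog"))) {
    emit_pair(sprintf("mgar_%02d", k), "multi_gar_ortholog",
              extra_gar = TRUE)
  }
  for (k in seq_len(dc("repeated_gene"))) {
    # gene A paired with both B and C; all three share one gar ortholog
    a <- place_fish(); b <- place_fish(); cc <- place_fish()
    gar <- place_gar()
    for (pr in list(list(a, b), list(b, a), list(a, cc), list(cc, a))) {
      add_row(pr[[1]], pr[[2]]$id, tgd, "within_species_paralog", gar,
              "ortholog_one2many", "rep_decoy")
    }
    for (g in list(a, b, cc)) {
      add_truth(g$id, "repeated_gene", sprintf("rept_%02d", k))
      add_ortho(g$id, gar)
    }
  }
  for (k in seq_len(dc("unanchored_contig"))) {
    emit_pair(sprintf("unan_%02d", k), "unanchored_contig",
              unanchored = TRUE)
  }
  for (k in seq_len(dc("tandem_lt_5Mbp"))) {
    emit_pair(sprintf("tand_%02d", k), "tandem_lt_5Mbp", tandem = TRUE)
  }
  for (k in seq_len(dc("neopterygii_ancestor"))) {
    # two would-be singletons joined by a "Neopterygii" paralog annotation;
    # distinct one2one gar orthologs keep every other rule satisfied
    x <- place_fish(); y <- place_fish()
    gx <- place_gar(); gy <- place_gar()
    add_row(x, y$id, "Neopterygii", "within_species_paralog", gx,
            "ortholog_one2one", paste0("n", 2 * k - 1))
    add_row(y, x$id, "Neopterygii", "within_species_paralog", gy,
            "ortholog_one2one", paste0("n", 2 * k))
    add_truth(x$id, "neopterygii_ancestor", sprintf("neop_%02d", k))
    add_truth(y$id, "neopterygii_ancestor", sprintf("neop_%02d", k))
    add_ortho(x$id, gx); add_ortho(y$id, gy)
  }
  for (k in seq_len(dc("one_of_many_name"))) {
    emit_singleton(sprintf("name_%02d", k), "one_of_many_name",
                   name = sprintf("sox%d (1 of many)", k))
  }
  for (k in seq_len(dc("non_one2one_ortholog"))) {
    emit_singleton(sprintf("o2m_%02d", k), "non_one2one_ortholog",
                   gar_type = "ortholog_one2many")
  }

  bind <- function(lst, template) {
    if (length(lst)) do.call(rbind, c(lst, list(make.row.names = FALSE)))
    else template
  }
  empty_tab <- data.frame(
    ensembl_gene_id = character(), paralog_gene_id = character(),
    paralog_subtype = character(), paralog_orthology_type = character(),
    gar_ortholog_id = character(), gar_orthology_type = character(),
    chromosome_name = character(), start_position = numeric(),
    end_position = numeric(), external_gene_name = character(),
    stringsAsFactors = FALSE)
  list(table = bind(env$rows, empty_tab),
       truth = bind(env$truth,
                    data.frame(gene = character(), label = character(),
                               unit = character(), stringsAsFactors = FALSE)),
       gene_coords = bind(env$gene_coords,
                          data.frame(gene_id = character(),
                                     chromosome = character(),
                                     start = numeric(),
                                     stringsAsFactors = FALSE)),
       gar_coords = bind(env$gar_coords,
                         data.frame(gene_id = character(),
                                    chromosome = character(),
                                    start = numeric(),
                                    stringsAsFactors = FALSE)),
       ortholog_map = bind(env$ortho,
                           data.frame(gene_id = character(),
                                      gar_id = character(),
                                      stringsAsFactors = FALSE)))
}

#' Write a simulation to TSV files
#'
#' Writes `counts.tsv`, `samples.tsv` and `truth.tsv` for an expression
#' simulation, or `homology.tsv`, `truth.tsv`, `gene_coords.tsv` and
#' `gar_coords.tsv` for a homology simulation. Truth labels live in sidecar
#' files, never in gene identifiers.
#'
#' @param sim Result of [simulate_counts()] or [simulate_homology()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  wt <- function(x, name, rn = FALSE) {
    f <- file.path(dir, name)
    utils::write.table(x, f, sep = "\t", quote = FALSE, row.names = rn,
                       col.names = if (rn) NA else TRUE)
    written <<- c(written, f)
  }
  if (!is.null(sim$counts)) {
    wt(sim$counts, "counts.tsv", rn = TRUE)
    wt(sim$samples, "samples.tsv")
    wt(sim$truth, "truth.tsv")
  } else {
    wt(sim$table, "homology.tsv")
    wt(sim$truth, "truth.tsv")
    wt(sim$gene_coords, "gene_coords.tsv")
    wt(sim$gar_coords, "gar_coords.tsv")
  }
  invisible(written)
}
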