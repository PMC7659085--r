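# two-gene ohnolog-style candidate pair, configurable for filter checks
pair_rows <- function(a = "GA", b = "GB", subtype = "Osteoglossocephalai",
                      gar = "LOC1", chrom_a = "1", chrom_b = "2",
                      start_a = 1e6, start_b = 1e6) {
  rbind(hom_row(a, b, subtype, "within_species_paralog", gar,
                "ortholog_one2many", chrom_a, start_a, start_a + 1e4),
        hom_row(b, a, subtype, "within_species_paralog", gar,
                "ortholog_one2many", chrom_b, start_b, start_b + 1e4))
}

test_that("each ohnolog filter excludes its targeted case", {
  # Clupeocephala ancestor
  expect_equal(nrow(identify_ohnolog_pairs(
    pair_rows(subtype = "Clupeocephala"))), 0)
  # tandem rule: 3 Mbp apart excluded, 6 Mbp retained
  expect_equal(nrow(identify_ohnolog_pairs(
    pair_rows(chrom_b = "1", start_a = 1e6, start_b = 4e6))), 0)
  kept <- identify_ohnolog_pairs(
    pair_rows(chrom_b = "1", start_a = 1e6, start_b = 7e6))
  expect_equal(kept$gene_a, "GA")
  # more than one gar ortholog
  tab <- rbind(pair_rows(),
               hom_row("GA", "GB", "Osteoglossocephalai",
                       "within_species_paralog", "LOC2",
                       "ortholog_one2many", "1", 1e6, 1.01e6))
  expect_equal(nrow(identify_ohnolog_pairs(tab)), 0)
  # gene in two candidate pairs: all pairs containing it removed
  tab2 <- rbind(pair_rows(a = "GA", b = "GB", gar = "LOC1"),
                pair_rows(a = "GA", b = "GC", gar = "LOC1",
                          chrom_a = "1", chrom_b = "3"))
  expect_equal(nrow(identify_ohnolog_pairs(tab2)), 0)
  # unanchored contig
  expect_equal(nrow(identify_ohnolog_pairs(
    pair_rows(chrom_b = "contig_0042"))), 0)
  # a clean pair passes
  expect_equal(nrow(identify_ohnolog_pairs(pair_rows())), 1)
  # schema error names the missing column
  expect_error(identify_ohnolog_pairs(pair_rows()[, -5]), "gar_ortholog_id")
})

test_that("singleton exclusions match the rule list", {
  # post-TGD lineage duplication ancestor
  tab <- rbind(hom_row("S1", "SX", "Xiphophorus", "within_species_paralog",
                       "LOC1", "ortholog_one2one"),
               hom_row("S2", NA, NA, NA, "LOC2", "ortholog_one2one",
                       name = "sox4 (1 of many)"),
               hom_row("S3", NA, NA, NA, "LOC3", "ortholog_one2one",
                       name = "pax7"),
               hom_row("S4", "SY", "Neopterygii", "within_species_paralog",
                       "LOC4", "ortholog_one2one"),
               hom_row("S5", NA, NA, NA, "LOC5", "ortholog_one2many"))
  out <- identify_singletons(tab)
  expect_true("S3" %in% out)
  expect_false(any(c("S1", "S2", "S4", "S5") %in% out))
  diag <- identify_singletons(tab, diagnostics = TRUE)
  expect_true(diag$fail_tgd_ancestor[diag$gene == "S1"])
  expect_true(diag$fail_name[diag$gene == "S2"])
  expect_true(diag$fail_neopterygii[diag$gene == "S4"])
  expect_true(diag$fail_orthology[diag$gene == "S5"])
})

test_that("planted pairs and singletons are recovered exactly from fixtures", {
  sim <- simulate_homology(homology_sim_config(n_ohnolog_pairs = 50,
                                               n_singletons = 100, seed = 7))
  pairs <- identify_ohnolog_pairs(sim$table)
  truth_pairs <- sim$truth[sim$truth$label == "ohnolog", ]
  expect_equal(nrow(pairs), 50)
  expect_setequal(c(pairs$gene_a, pairs$gene_b), truth_pairs$gene)
  # recovered pairing matches the planted units
  unit_of <- setNames(truth_pairs$unit, truth_pairs$gene)
  expect_true(all(unit_of[pairs$gene_a] == unit_of[pairs$gene_b]))

  singles <- identify_singletons(sim$table)
  expect_setequal(singles, sim$truth$gene[sim$truth$label == "singleton"])
})

test_that("every decoy fails exactly its named rule", {
  sim <- simulate_homology(homology_sim_config(n_ohnolog_pairs = 5,
                                               n_singletons = 5, seed = 9))
  pair_diag <- identify_ohnolog_pairs(sim$table, diagnostics = TRUE)
  sing_diag <- identify_singletons(sim$table, diagnostics = TRUE)
  label_of <- setNames(sim$truth$label, sim$truth$gene)
  pair_rule <- c(clupeocephala_ancestor = "fail_ancestor",
                 multi_gar_ortholog = "fail_gar",
                 repeated_gene = "fail_multiplicity",
                 unanchored_contig = "fail_unanchored",
                 tandem_lt_5Mbp = "fail_tandem")
  fail_cols <- grep("^fail_", names(pair_diag), value = TRUE)
  for (k in seq_len(nrow(pair_diag))) {
    lab <- unname(label_of[pair_diag$gene_a[k]])
    fails <- fail_cols[unlist(pair_diag[k, fail_cols])]
    if (lab == "ohnolog") {
      expect_length(fails, 0)
    } else if (lab %in% names(pair_rule)) {
      expect_equal(fails, unname(pair_rule[lab]))
    }
  }
  sing_rule <- c(neopterygii_ancestor = "fail_neopterygii",
                 one_of_many_name = "fail_name",
                 non_one2one_ortholog = "fail_orthology")
  scols <- grep("^fail_", names(sing_diag), value = TRUE)
  for (k in seq_len(nrow(sing_diag))) {
    lab <- unname(label_of[sing_diag$gene[k]])
    fails <- scols[unlist(sing_diag[k, scols])]
    if (lab == "singleton") expect_length(fails, 0)
    if (lab %in% names(sing_rule)) {
      expect_equal(fails, unname(sing_rule[lab]))
    }
  }
})

test_that("ohnolog output is a perfect matching disjoint from singletons", {
  sim <- simulate_homology(homology_sim_config(seed = 13))
  pairs <- identify_ohnolog_pairs(sim$table)
  genes <- c(pairs$gene_a, pairs$gene_b)
  expect_equal(anyDuplicated(genes), 0)
  singles <- identify_singletons(sim$table)
  expect_length(intersect(genes, singles), 0)
})

test_that("the five ohnolog predicates are conjunctive (order-free)", {
  sim <- simulate_homology(homology_sim_config(seed = 23))
  diag <- identify_ohnolog_pairs(sim$table, diagnostics = TRUE)
  fail_cols <- rev(grep("^fail_", names(diag), value = TRUE))
  keep <- rep(TRUE, nrow(diag))
  for (col in fail_cols) keep <- keep & !diag[[col]]   # reversed order
  reversed <- diag[keep, c("gene_a", "gene_b")]
  forward <- identify_ohnolog_pairs(sim$table)[, c("gene_a", "gene_b")]
  expect_equal(reversed[order(reversed$gene_a), ],
               forward[order(forward$gene_a), ], ignore_attr = TRUE)
})

test_that("synteny score counts conserved neighbourhood orthologies", {
  # 11 fish genes and 11 gar genes laid out co-linearly on one chromosome
  fish <- data.frame(gene_id = sprintf("F%02d", 1:11), chromosome = "1",
                     start = (1:11) * 1e6)
  gar <- data.frame(gene_id = sprintf("L%02d", 1:11), chromosome = "LG1",
                    start = (1:11) * 1e6)
  omap <- data.frame(gene_id = fish$gene_id, gar_id = gar$gene_id)
  s <- synteny_score("F06", "L06", fish, gar, omap, n = 5)
  expect_equal(as.numeric(s), 1)

  # independent brute-force check: count focal neighbours whose mapped gar
  # gene sits in the gar window
  brute <- function(focal, garg, n) {
    fi <- match(focal, fish$gene_id); gi <- match(garg, gar$gene_id)
    nb <- setdiff(intersect(seq_len(11), (fi - n):(fi + n)), fi)
    gwin <- gar$gene_id[setdiff(intersect(seq_len(11), (gi - n):(gi + n)),
                                gi)]
    hits <- sum(vapply(fish$gene_id[nb], function(g)
      any(omap$gar_id[omap$gene_id == g] %in% gwin), TRUE))
    hits / length(nb)
  }
  for (f in c("F01", "F03", "F06", "F11")) {
    expect_equal(as.numeric(synteny_score(f, gar$gene_id[match(f,
                   fish$gene_id)], fish, gar, omap, n = 5)),
                 brute(f, gar$gene_id[match(f, fish$gene_id)], 5))
  }

  # no neighbour orthologies at all
  omap0 <- data.frame(gene_id = "F06", gar_id = "L06")
  expect_equal(as.numeric(synteny_score("F06", "L06", fish, gar, omap0,
                                        n = 5)), 0)

  # half the neighbourhood conserved
  omap_half <- omap[c(1:3, 9:11, 6), ]   # 3 left + 3 right of F06 retained
  expect_equal(as.numeric(synteny_score("F06", "L06", fish, gar, omap_half,
                                        n = 5)), 0.6)
})

test_that("best-ortholog assignment maximises the score with a stable tie", {
  fish <- data.frame(gene_id = sprintf("F%02d", 1:11), chromosome = "1",
                     start = (1:11) * 1e6)
  gar <- data.frame(gene_id = c(sprintf("L%02d", 1:11), "ZZ1"),
                    chromosome = c(rep("LG1", 11), "LG2"),
                    start = c((1:11) * 1e6, 1e6))
  omap <- data.frame(gene_id = fish$gene_id, gar_id = sprintf("L%02d", 1:11))
  one <- assign_best_ortholog("F06", "L06", fish, gar, omap, n = 5)
  expect_equal(one$gar_id, "L06")
  two <- assign_best_ortholog("F06", c("L06", "ZZ1"), fish, gar, omap, n = 5)
  expect_equal(two$gar_id, "L06")
  expect_gt(two$score, 0.5)
  expect_warning(
    tie <- assign_best_ortholog("F06", c("ZZ1", "AA1"), fish,
                                rbind(gar, data.frame(gene_id = "AA1",
                                                      chromosome = "LG3",
                                                      start = 1e6)),
                                omap, n = 5),
    "tie")
  expect_equal(tie$gar_id, "AA1")
  expect_error(assign_best_ortholog("F06", character(), fish, gar, omap),
               "no candidate")
})

test_that("homology tables round-trip through TSV", {
  sim <- simulate_homology(homology_sim_config(n_ohnolog_pairs = 3,
                                               n_singletons = 3, seed = 2))
  dir <- tempfile()
  write_simulation(sim, dir)
  back <- read_homology_table(file.path(dir, "homology.tsv"))
  expect_equal(identify_ohnolog_pairs(back), identify_ohnolog_pairs(sim$table))
  expect_equal(identify_singletons(back), identify_singletons(sim$table))
})
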