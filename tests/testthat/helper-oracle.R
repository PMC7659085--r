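# Independent brute-force oracle for the umbrella rank statistic: explicit
# double loops over every ordered group pair and every value pair within
# each arc, no shared code with the implementation.
brute_umbrella <- function(groups, peak, trough) {
  G <- length(groups)
  rising <- if (trough < peak) trough:peak else c(trough:G, 1:peak)
  falling <- if (peak < trough) peak:trough else c(peak:G, 1:trough)
  s <- 0
  s_max <- 0
  arc_sum <- function(arc, direction) {
    for (i in seq_len(length(arc) - 1)) {
      for (j in (i + 1):length(arc)) {
        early <- groups[[arc[i]]]
        late <- groups[[arc[j]]]
        for (x in early) {
          for (y in late) {
            if (direction == "rising") {
              s <<- s + (y > x) + 0.5 * (y == x)
            } else {
              s <<- s + (x > y) + 0.5 * (x == y)
            }
            s_max <<- s_max + 1
          }
        }
      }
    }
  }
  arc_sum(rising, "rising")
  arc_sum(falling, "falling")
  list(s = s, s_max = s_max)
}

# random grouped dataset for property tests
random_groups <- function(n_groups, reps, tie_prone = FALSE) {
  lapply(seq_len(n_groups), function(i) {
    v <- stats::rnorm(reps)
    if (tie_prone) round(v) else v
  })
}

# small homology table builder for filter tests; positions in bp
hom_row <- function(gene, paralog = NA, subtype = NA, ptype = NA, gar = NA,
                    gar_type = NA, chrom = "1", start = 1, end = 1e4,
                    name = NA) {
  data.frame(ensembl_gene_id = gene, paralog_gene_id = paralog,
             paralog_subtype = subtype, paralog_orthology_type = ptype,
             gar_ortholog_id = gar, gar_orthology_type = gar_type,
             chromosome_name = chrom, start_position = start,
             end_position = end, external_gene_name = name,
             stringsAsFactors = FALSE)
}
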