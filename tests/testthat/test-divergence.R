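# minimal rhythm-result rows for classification tests
rcall <- function(gene, organ, cyclic = TRUE, peak = 6.5) {
  data.frame(gene = gene, organ = organ, is_cyclic = cyclic, peak_zt = peak,
             stringsAsFactors = FALSE)
}

test_that("intra-organ categories follow the definitions", {
  one <- rcall("A", "skin")
  expect_equal(classify_intra_organ("A", "B", one), "ONE_CYCLIC")
  diff <- rbind(rcall("A", "skin", peak = 0.5),
                rcall("B", "skin", peak = 12.5))
  expect_equal(classify_intra_organ("A", "B", diff), "BOTH_CYCLIC_DIFFERENT")
  same <- rbind(rcall("A", "skin", peak = 6.5), rcall("B", "skin", peak = 6.5))
  expect_equal(classify_intra_organ("A", "B", same), "BOTH_CYCLIC_SAME")
  multi <- rbind(rcall("A", "skin"), rcall("B", "liver"))
  expect_error(classify_intra_organ("A", "B", multi), "exactly one")
  # tolerance widens pattern equality
  near <- rbind(rcall("A", "skin", peak = 6.5), rcall("B", "skin", peak = 9.5))
  expect_equal(classify_intra_organ("A", "B", near), "BOTH_CYCLIC_DIFFERENT")
  expect_equal(classify_intra_organ("A", "B", near, peak_tolerance = 3),
               "BOTH_CYCLIC_SAME")
})

test_that("inter-organ categories follow the definitions", {
  one <- rbind(rcall("A", "skin"), rcall("A", "liver"))
  expect_equal(classify_inter_organ("A", "B", one), "ONE_CYCLIC_MULTI")
  diff <- rbind(rcall("A", "skin"), rcall("B", "liver"))
  expect_equal(classify_inter_organ("A", "B", diff), "DIFFERENT_BY_ORGAN")
  sync <- rbind(rcall("A", "skin", peak = 3.5), rcall("A", "liver", peak = 9.5),
                rcall("B", "skin", peak = 3.5), rcall("B", "liver", peak = 9.5))
  expect_equal(classify_inter_organ("A", "B", sync), "SYNCHRONIZED_MULTI")
  offset <- rbind(rcall("A", "skin", peak = 3.5),
                  rcall("B", "skin", peak = 15.5),
                  rcall("B", "liver", peak = 9.5))
  expect_equal(classify_inter_organ("A", "B", offset), "DIFFERENT_BY_ORGAN")
  expect_error(classify_inter_organ("A", "B", rcall("A", "skin")),
               "at least two")
})

test_that("singleton multi-organ classification compares peaks circularly", {
  sync <- rbind(rcall("S", "eye", peak = 3.5), rcall("S", "brain", peak = 3.5))
  expect_equal(classify_singleton_multi_organ("S", sync), "SYNCHRONIZED")
  diff <- rbind(rcall("S", "eye", peak = 3.5), rcall("S", "brain", peak = 9.5))
  expect_equal(classify_singleton_multi_organ("S", diff), "DIFFERENT")
  expect_error(classify_singleton_multi_organ("S", rcall("S", "eye")),
               "fewer than two")
})

test_that("classification is symmetric in the two genes", {
  set.seed(31)
  organs <- c("skin", "liver", "eye")
  for (i in 1:30) {
    rows <- list()
    for (org in organs) {
      for (g in c("A", "B")) {
        if (runif(1) < 0.5) {
          rows[[length(rows) + 1]] <-
            rcall(g, org, peak = sample(seq(0.5, 21.5, 3), 1))
        }
      }
    }
    if (!length(rows)) next
    rhythm <- do.call(rbind, rows)
    pairs_ab <- data.frame(gene_a = "A", gene_b = "B")
    pairs_ba <- data.frame(gene_a = "B", gene_b = "A")
    call_ab <- classify_divergence(pairs_ab, rhythm)
    call_ba <- classify_divergence(pairs_ba, rhythm)
    expect_equal(call_ab$scope, call_ba$scope)
    expect_equal(call_ab$category, call_ba$category)
  }
})

test_that("divergence routing conserves pair counts", {
  rhythm <- rbind(rcall("A1", "skin"), rcall("B1", "skin"),
                  rcall("A2", "skin"), rcall("A2", "liver"),
                  rcall("A4", "eye", peak = 9.5))
  pairs <- data.frame(gene_a = c("A1", "A2", "A3", "A4"),
                      gene_b = c("B1", "B2", "B3", "B4"))
  calls <- classify_divergence(pairs, rhythm)
  sm <- summarize_divergence(calls)
  n_any_cyclic <- 3   # A3/B3 never cyclic
  expect_equal(sm$n_cyclic_pairs, n_any_cyclic)
  expect_equal(sm$n_intra + sm$n_inter, n_any_cyclic)
  expect_equal(sum(calls$scope == "not_cyclic"), 1)
})

test_that("summary reproduces the published count arithmetic", {
  calls <- data.frame(
    scope = rep(c("intra_organ", "intra_organ", "intra_organ",
                  "inter_organ", "inter_organ", "inter_organ"),
                c(295, 21, 24, 126, 159, 1)),
    category = rep(c("ONE_CYCLIC", "BOTH_CYCLIC_DIFFERENT",
                     "BOTH_CYCLIC_SAME", "ONE_CYCLIC_MULTI",
                     "DIFFERENT_BY_ORGAN", "SYNCHRONIZED_MULTI"),
                   c(295, 21, 24, 126, 159, 1)),
    stringsAsFactors = FALSE)
  sm <- summarize_divergence(calls)
  expect_equal(sm$n_cyclic_pairs, 626)
  expect_equal(sm$n_intra, 340)
  expect_equal(sm$single_organ_share_percent, 54.3)

  empty <- summarize_divergence(calls[0, ])
  expect_equal(empty$n_cyclic_pairs, 0)
  expect_true(all(empty$table$count == 0))
})

test_that("planted categories are recovered exactly under perfect detection", {
  # build rhythm calls directly from a planted truth, one pair per category
  set.seed(41)
  plan <- list(
    list(cat = "ONE_CYCLIC", rows = function(a, b)
      rcall(a, "skin")),
    list(cat = "BOTH_CYCLIC_DIFFERENT", rows = function(a, b)
      rbind(rcall(a, "skin", peak = 0.5), rcall(b, "skin", peak = 12.5))),
    list(cat = "BOTH_CYCLIC_SAME", rows = function(a, b)
      rbind(rcall(a, "skin", peak = 6.5), rcall(b, "skin", peak = 6.5))),
    list(cat = "ONE_CYCLIC_MULTI", rows = function(a, b)
      rbind(rcall(a, "skin"), rcall(a, "liver"))),
    list(cat = "DIFFERENT_BY_ORGAN", rows = function(a, b)
      rbind(rcall(a, "skin"), rcall(b, "liver"))),
    list(cat = "SYNCHRONIZED_MULTI", rows = function(a, b)
      rbind(rcall(a, "skin", peak = 3.5), rcall(b, "skin", peak = 3.5),
            rcall(a, "eye", peak = 9.5), rcall(b, "eye", peak = 9.5))))
  planted_n <- sample(1:5, length(plan), replace = TRUE)
  rows <- list(); pairs <- list(); want <- character()
  idx <- 0
  for (k in seq_along(plan)) {
    for (r in seq_len(planted_n[k])) {
      idx <- idx + 1
      a <- sprintf("A%03d", idx); b <- sprintf("B%03d", idx)
      rows[[idx]] <- plan[[k]]$rows(a, b)
      pairs[[idx]] <- data.frame(gene_a = a, gene_b = b)
      want <- c(want, plan[[k]]$cat)
    }
  }
  calls <- classify_divergence(do.call(rbind, pairs), do.call(rbind, rows))
  expect_equal(unname(table(factor(calls$category, levels = unique(want)))[
    unique(want)]), unname(table(factor(want, levels = unique(want)))[
      unique(want)]), ignore_attr = TRUE)
  sm <- summarize_divergence(calls)
  expect_equal(sm$n_cyclic_pairs, sum(planted_n))
})
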