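test_that("gene usage is dense, proportional, and flags empty samples", {
  sh <- shared_repertoire()
  ut <- gene_usage(sh$cells, "TRG", "V")
  expect_equal(colSums(ut$proportions), rep(1, ncol(ut$proportions)),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_true(all(ut$counts >= 0))
  # 5 of 10 gamma chains TRGV7 -> proportion 0.5
  tab <- data.table::data.table(
    cell_id = sprintf("c%d", 1:10), sample_id = "s", genotype = "KO",
    segment = "ileum", locus = "TRG",
    v_call = c(rep("TRGV7*01", 5), rep("TRGV1", 5)),
    j_call = "TRGJ1", cdr3_nt = "TGTGCTAGT", cdr3_aa = "CAS",
    productive = TRUE, umi_count = 1L, contig_id = sprintf("k%d", 1:10))
  u <- gene_usage(pair_cells(tab), "TRG", "V")
  expect_equal(u$proportions["TRGV7", "s"], 0.5)
  # VJ level concatenates gene symbols
  uvj <- gene_usage(pair_cells(tab), "TRG", "VJ")
  expect_true("TRGV7-TRGJ1" %in% rownames(uvj$counts))
})

test_that("generated usage converges to configured weights", {
  sh <- shared_repertoire()
  ut <- gene_usage(sh$cells, "TRG", "V")
  pooled <- rowSums(ut$counts) / sum(ut$counts)
  w <- sh$cfg$gamma_v_weights
  expect_true(all(abs(pooled[names(w)] - w) < 0.02))
  ud <- gene_usage(sh$cells, "TRD", "V")
  pd <- rowSums(ud$counts) / sum(ud$counts)
  dom <- c("TRDV2-2", "TRDV5", "TRDV6D-1", "TRDV6D-2")
  expect_gt(sum(pd[dom]), 0.8)
})

test_that("usage chi-squared matches the hand-computed table and R's test", {
  res <- usage_chisq(c(a = 10, b = 90), c(a = 20, b = 80))
  expect_equal(res$chi2, 3.9216, tolerance = 1e-3)
  expect_equal(res$df, 1)
  expect_equal(res$p_value, 0.0477, tolerance = 1e-3)
  # independent oracle: stats::chisq.test without continuity correction
  oracle <- stats::chisq.test(rbind(c(10, 90), c(20, 80)), correct = FALSE)
  expect_equal(res$chi2, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, oracle$p.value, tolerance = 1e-10)

  ident <- usage_chisq(c(x = 7, y = 13), c(x = 7, y = 13))
  expect_equal(ident$chi2, 0)
  expect_equal(ident$p_value, 1)
  prop <- usage_chisq(c(10, 10, 10), c(30, 30, 30))
  expect_equal(prop$chi2, 0, tolerance = 1e-12)
  # symmetry in sample order
  s1 <- usage_chisq(c(a = 12, b = 30, c = 8), c(a = 25, b = 14, c = 11))
  s2 <- usage_chisq(c(a = 25, b = 14, c = 11), c(a = 12, b = 30, c = 8))
  expect_equal(s1$chi2, s2$chi2)
  expect_equal(s1$p_value, s2$p_value)
  # low-expected genes are pooled with a warning
  expect_warning(pool <- usage_chisq(c(a = 500, b = 1), c(a = 400, b = 0)),
                 "pooling")
  expect_true("other" %in% colnames(pool$observed))
  expect_error(usage_chisq(c(a = 0), c(a = 0)), "all-zero")
})

test_that("clonotype overlap reports the three sharing fractions", {
  ov <- clonotype_overlap(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(ov$n_shared, 2)
  expect_equal(ov$fraction_union, 0.5)
  expect_equal(ov$fraction_a, 2 / 3)
  expect_equal(ov$fraction_b, 2 / 3)
  expect_equal(clonotype_overlap(c("a"), c("b"))$fraction_union, 0)
  expect_equal(clonotype_overlap(c("a", "b"), c("b", "a"))$fraction_union, 1)
  # symmetry with a/b fractions swapped
  f <- clonotype_overlap(c("a", "b", "c", "x"), c("b", "y"))
  r <- clonotype_overlap(c("b", "y"), c("a", "b", "c", "x"))
  expect_equal(f$fraction_a, r$fraction_b)
  expect_equal(f$fraction_b, r$fraction_a)
  expect_equal(f$fraction_union, r$fraction_union)
})

test_that("cross-segment sharing produces a consistent 7-region partition", {
  venn <- cross_segment_sharing(list(duodenum = c("a", "b"),
                                     jejunum = c("b", "c"),
                                     ileum = c("c", "b")))
  expect_equal(venn$all_three, 1)       # b
  expect_equal(venn$jejunum_ileum, 1)   # c
  expect_equal(venn$duodenum_only, 1)   # a
  expect_equal(venn$n_union, 3)

  same <- cross_segment_sharing(list(duodenum = c("a", "b"),
                                     jejunum = c("a", "b"),
                                     ileum = c("b", "a")))
  expect_equal(same$all_three, 2)
  expect_equal(same$duodenum_only + same$jejunum_only + same$ileum_only, 0)

  disj <- cross_segment_sharing(list(duodenum = "a", jejunum = "b",
                                     ileum = "c"))
  expect_equal(disj$all_three, 0)
  expect_equal(disj$duodenum_only + disj$jejunum_only + disj$ileum_only, 3)

  expect_error(cross_segment_sharing(list(duodenum = "a", jejunum = "b")),
               "missing segment")

  # partition counts always sum to the union (property)
  set.seed(5)
  for (i in 1:20) {
    keys <- sprintf("k%02d", 1:30)
    sets <- list(duodenum = sample(keys, sample(0:20, 1)),
                 jejunum = sample(keys, sample(1:20, 1)),
                 ileum = sample(keys, sample(1:20, 1)))
    v <- cross_segment_sharing(sets)
    expect_equal(v$duodenum_only + v$jejunum_only + v$ileum_only +
                   v$duodenum_jejunum + v$duodenum_ileum + v$jejunum_ileum +
                   v$all_three,
                 v$n_union)
    expect_equal(v$n_union, length(unique(unlist(sets))))
  }
})

test_that("top-clone tables rank by focal size with deterministic ties", {
  sh <- shared_repertoire()
  by_sample <- lapply(split(sh$cells, sh$cells$sample_id),
                      group_clonotypes, locus = "TRG")
  top <- top_clone_table(by_sample, k = 10)
  expect_equal(nrow(top), 10)
  foc <- names(by_sample)[1]
  expect_true(all(diff(top[[paste0("size_", foc)]]) <= 0))
  # the planted 10% public clone ranks first everywhere
  expect_equal(top$key[1], sh$rep$truth$public_key)
  # ties break lexicographically on cdr3_aa
  tied <- data.table::as.data.table(list(
    key = c("TRG|TRGV7|TRGJ1|CB", "TRG|TRGV7|TRGJ1|CA"),
    cdr3_aa = c("CB", "CA"), size = c(3L, 3L)))
  tt <- top_clone_table(list(s = tied), k = 2)
  expect_equal(tt$cdr3_aa, c("CA", "CB"))
  # k beyond the table returns everything with a note
  all_rows <- top_clone_table(list(s = tied), k = 99)
  expect_equal(nrow(all_rows), 2)
  expect_match(attr(all_rows, "note"), "returning all")
})
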