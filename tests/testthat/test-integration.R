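annotated_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$ann)) {
      sh <- shared_repertoire()
      labels <- generate_cluster_labels(sh$cells, sh$cfg,
                                        sh$rep$truth$cluster_weights)
      cache$sh <- sh
      cache$labels <- labels
      cache$ann <- attach_clusters(sh$cells, labels)
    }
    list(sh = cache$sh, labels = cache$labels, ann = cache$ann)
  }
})

test_that("attach_clusters left-joins labels and flags the unlabeled", {
  cells <- shared_repertoire()$cells[1:3]
  asg <- data.frame(cell_id = cells$cell_id[1:2], cluster_label = c("0", "4"))
  ann <- attach_clusters(cells, asg)
  expect_equal(ann$cluster, c("0", "4", "unassigned"))
  empty <- attach_clusters(cells, asg[0, ])
  expect_true(all(empty$cluster == "unassigned"))
  dup <- rbind(asg, asg[1, ])
  expect_error(attach_clusters(cells, dup), "duplicate")
})

test_that("clonotype cluster distributions count and normalize correctly", {
  fx <- annotated_fixture()
  key <- fx$sh$rep$truth$public_key
  dist <- clonotype_cluster_distribution(fx$ann, key)
  expect_equal(sum(dist$proportions), 1, tolerance = 1e-9)
  expect_equal(sum(dist$counts), dist$n_cells)
  # absent key -> empty distribution
  none <- clonotype_cluster_distribution(fx$ann, "TRG|TRGV9|TRGJ9|CZZF")
  expect_equal(none$n_cells, 0)
  expect_length(none$counts, 0)
  # hand-built: 5/3/2 over three clusters
  cells <- fx$sh$cells[!is.na(fx$sh$cells$gamma_v_call)][1:10]
  k <- make_clonotype_key(cells$gamma_v_call, cells$gamma_j_call,
                          cells$gamma_cdr3_aa)
  one <- data.table::copy(cells)
  one$gamma_v_call <- "TRGV7"; one$gamma_j_call <- "TRGJ1"
  one$gamma_cdr3_aa <- "CAAF"
  asg <- data.frame(cell_id = one$cell_id,
                    cluster_label = rep(c("0", "1", "4"), c(5, 3, 2)))
  d <- clonotype_cluster_distribution(attach_clusters(one, asg),
                                      "TRG|TRGV7|TRGJ1|CAAF")
  expect_equal(unname(d$proportions[c("0", "1", "4")]), c(0.5, 0.3, 0.2))
})

test_that("summed clonotype distributions reproduce per-cluster totals", {
  fx <- annotated_fixture()
  sub <- fx$ann[fx$ann$sample_id == "KO_ileum"]
  cl <- group_clonotypes(sub, "TRG")
  per_cluster <- Reduce(`+`, lapply(cl$key, function(k) {
    d <- clonotype_cluster_distribution(sub, k)
    out <- stats::setNames(rep(0, 9), as.character(0:8))
    out[names(d$counts)] <- d$counts
    out
  }))
  gamma_cells <- sub[!is.na(sub$gamma_v_call) & sub$cluster != "unassigned"]
  truth <- table(factor(gamma_cells$cluster, levels = as.character(0:8)))
  expect_equal(unname(per_cluster), as.numeric(truth))
})

test_that("pairing profiles split the focal gamma clone by delta partner", {
  fx <- annotated_fixture()
  key <- fx$sh$rep$truth$public_key
  prof <- pairing_cluster_profiles(fx$ann, key)
  sizes <- vapply(prof, `[[`, integer(1), "pair_size")
  expect_true(all(diff(sizes) <= 0))  # ordered by pair size desc
  paired_cells <- fx$ann[!is.na(fx$ann$gamma_v_call) &
                           !is.na(fx$ann$delta_v_call)]
  gk <- make_clonotype_key(paired_cells$gamma_v_call,
                           paired_cells$gamma_j_call,
                           paired_cells$gamma_cdr3_aa)
  expect_equal(sum(sizes), sum(gk == key))
  # unknown gamma key -> empty mapping
  expect_length(pairing_cluster_profiles(fx$ann, "TRG|TRGV9|TRGJ9|CZZF"), 0)
})

test_that("planted pairing-specific cluster preferences are recovered", {
  fx <- annotated_fixture()
  truth <- fx$sh$rep$truth
  # take the largest pairing and check its preferred cluster dominates
  big <- truth$pairing[which.max(truth$pairing$prob)]
  w <- truth$cluster_weights[[big$pair_key]]
  pref <- as.character(which.max(w) - 1L)
  prof <- pairing_cluster_profiles(fx$ann, big$gamma_key)
  d <- prof[[big$delta_key]]
  expect_false(is.null(d))
  observed <- d$proportions[pref]
  expect_gt(unname(observed), 0.4)  # true weight 0.6, n in the hundreds
})

test_that("cluster usage shift detects a planted V-gene composition change", {
  fx <- annotated_fixture()
  same <- cluster_usage_shift(fx$ann, fx$ann, "0", "TRG")
  expect_equal(same$chi2, 0, tolerance = 1e-9)
  expect_error(cluster_usage_shift(fx$ann, fx$ann, "not_a_cluster", "TRG"),
               "absent")

  # direct multinomial construction: inside one cluster, 5 points of
  # TRGV7 mass move to TRGV1 (0.45 -> 0.40), mirroring a knockout-like
  # compositional shift; TRGV4 is untouched
  mk <- function(p7, n, seed) {
    set.seed(seed)
    v <- sample(c("TRGV7", "TRGV1", "TRGV4"), n, TRUE,
                prob = c(p7, 0.70 - p7, 0.30))
    data.table::data.table(
      cell_id = sprintf("s%d_c%05d", seed, seq_len(n)), sample_id = "s",
      genotype = "KO", segment = "ileum",
      gamma_v_call = v, gamma_j_call = "TRGJ1", gamma_cdr3_nt = "TGTGCTAGT",
      gamma_cdr3_aa = "CAS", gamma_umi_count = 1L, gamma_contig_id = "x",
      delta_v_call = NA_character_, delta_j_call = NA_character_,
      delta_cdr3_nt = NA_character_, delta_cdr3_aa = NA_character_,
      delta_umi_count = NA_integer_, delta_contig_id = NA_character_,
      multi_chain_flag = FALSE, cluster = "1")
  }
  hits <- 0
  n_runs <- 10
  for (r in seq_len(n_runs)) {
    a <- mk(0.40, 2000, 100 + r)
    b <- mk(0.45, 2000, 200 + r)
    res <- cluster_usage_shift(a, b, "1", "TRG")
    if (res$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 0.8 * n_runs)

  # a near-empty cluster is insufficient for the test
  tiny <- mk(0.40, 1, 1)
  expect_error(cluster_usage_shift(tiny, mk(0.45, 100, 2), "1", "TRG"),
               "fewer than 2")
})
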