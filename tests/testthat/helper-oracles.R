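# Independent oracles and small fixtures shared across test files.

# Exhaustive subsampling oracle: enumerate every without-replacement
# subsample of size m from the n labeled chains and average richness and
# Shannon entropy. Only feasible for n <= ~12; this is the ground truth
# the analytic interpolation formulas are checked against.
enum_subsample_oracle <- function(counts, m) {
  pool <- rep.int(seq_along(counts), counts)
  n <- length(pool)
  subs <- utils::combn(n, m)
  rich <- numeric(ncol(subs))
  ent <- numeric(ncol(subs))
  for (k in seq_len(ncol(subs))) {
    tab <- tabulate(pool[subs[, k]])
    tab <- tab[tab > 0]
    rich[k] <- length(tab)
    p <- tab / m
    ent[k] <- -sum(p * log(p))
  }
  list(richness = mean(rich), entropy = mean(ent))
}

# All abundance vectors (as multisets, i.e. non-increasing compositions)
# with total n over at most k_max parts.
all_abundance_vectors <- function(n, k_max) {
  partitions <- function(n, max_part, k) {
    if (n == 0) return(list(integer(0)))
    if (k == 0) return(list())
    out <- list()
    for (first in seq_len(min(n, max_part))) {
      for (rest in partitions(n - first, first, k - 1)) {
        out[[length(out) + 1L]] <- c(first, rest)
      }
    }
    out
  }
  partitions(n, n, k_max)
}

# Minimal hand-built chain table: 3 cells across 2 samples.
tiny_chain_table <- function() {
  data.table::data.table(
    cell_id = c("c1", "c1", "c2", "c3"),
    sample_id = c("KO_ileum", "KO_ileum", "KO_ileum", "WT_ileum"),
    genotype = c("KO", "KO", "KO", "WT"),
    segment = rep("ileum", 4),
    locus = c("TRG", "TRD", "TRG", "TRD"),
    v_call = c("TRGV7*02", "TRDV5*01", "TRGV1", "TRDV2-2"),
    j_call = c("TRGJ1*01", "TRDJ1", "TRGJ2", "TRDJ1"),
    cdr3_nt = c("TGTGCTAGT", "TGCGCCTCA", "TGTGCTAGT", "TGCGCCTCA"),
    cdr3_aa = c("CAS", "CAS", "CAS", "CAS"),
    productive = c(TRUE, TRUE, TRUE, FALSE),
    umi_count = c(5L, 3L, 2L, 4L),
    contig_id = c("c1_g1", "c1_d1", "c2_g1", "c3_d1"))
}

# Random valid chain table for property tests.
random_chain_table <- function(n, seed) {
  set.seed(seed)
  locus <- sample(c("TRG", "TRD"), n, replace = TRUE)
  v <- ifelse(locus == "TRG",
              paste0("TRGV", sample(c("1", "4", "7"), n, TRUE)),
              paste0("TRDV", sample(c("5", "2-2"), n, TRUE)))
  j <- ifelse(locus == "TRG", "TRGJ1", "TRDJ1")
  nts <- c("TGTGCTAGT", "TGCGCCTCA", "TGTGCCAGC")
  nt <- sample(nts, n, replace = TRUE)
  data.table::data.table(
    cell_id = sprintf("cell%03d", sample(ceiling(n / 2), n, replace = TRUE)),
    sample_id = "s1", genotype = "KO", segment = "ileum",
    locus = locus, v_call = v, j_call = j,
    cdr3_nt = nt, cdr3_aa = "CAS",
    productive = sample(c(TRUE, FALSE), n, TRUE, prob = c(0.8, 0.2)),
    umi_count = sample(1:9, n, replace = TRUE),
    contig_id = sprintf("contig%04d", seq_len(n)))
}

# One moderately sized generated repertoire, cached per test run so
# several test files can share it without regenerating.
shared_repertoire <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$rep)) {
      cfg <- tcrgd::sim_config(seed = 424242L, n_cells = 3000L)
      cache$cfg <- cfg
      cache$rep <- tcrgd::generate_repertoire(cfg)
      cache$cells <- tcrgd::pair_cells(
        tcrgd::filter_productive(cache$rep$chains))
    }
    list(cfg = cache$cfg, rep = cache$rep, cells = cache$cells)
  }
})
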