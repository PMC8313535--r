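# V/J gene-usage tables and tests, clonotype sharing, top-clone tables.

#' V/J gene-usage table
#'
#' Counts and proportions of chains using each V gene, J gene, or V-J
#' combination, per sample. The table is dense: a gene absent from a
#' sample appears with count 0 (rendered "ND" in reports).
#'
#' @param cells paired-cell table from [pair_cells()].
#' @param locus \code{"TRG"} or \code{"TRD"}.
#' @param level \code{"V"}, \code{"J"} or \code{"VJ"}.
#' @param by grouping column(s) defining a sample; default
#'   \code{"sample_id"}.
#' @return list of class \code{"usage_table"}: \code{counts} (gene x
#'   sample integer matrix), \code{proportions} (columns sum to 1; all-NA
#'   for empty samples), \code{locus}, \code{level}.
#' @export
gene_usage <- function(cells, locus = c("TRG", "TRD"),
                       level = c("V", "J", "VJ"), by = "sample_id") {
  locus <- match.arg(locus)
  level <- match.arg(level)
  cells <- data.table::as.data.table(cells)
  ch <- locus_block(cells, locus)
  gene <- switch(level,
    V = strip_allele(ch$v_call),
    J = strip_allele(ch$j_call),
    VJ = paste(strip_allele(ch$v_call), strip_allele(ch$j_call), sep = "-"))
  sample <- do.call(paste, c(unname(as.list(ch[, by, with = FALSE])),
                             sep = ":"))
  counts <- table(factor(gene), factor(sample))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  totals <- colSums(counts)
  props <- sweep(counts, 2, totals, "/")
  props[, totals == 0] <- NA_real_
  if (any(totals == 0)) {
    tcrgd_log("WARN", "empty sample column(s): ",
              paste(colnames(counts)[totals == 0], collapse = ", "))
  }
  structure(list(counts = counts, proportions = props, locus = locus,
                 level = level), class = "usage_table")
}

#' @export
print.usage_table <- function(x, digits = 3, ...) {
  cat(sprintf("%s %s-gene usage (%d genes x %d samples)\n", x$locus,
              x$level, nrow(x$counts), ncol(x$counts)))
  disp <- round(100 * x$proportions, digits - 2)
  disp[x$counts == 0] <- NA
  print(disp, na.print = "ND")
  invisible(x)
}

#' Pearson chi-squared test on two gene-usage count vectors
#'
#' Builds the 2 x G contingency table of raw chain counts and applies
#' Pearson's chi-squared test with no continuity correction. Genes whose
#' expected count falls below 1 in either row are pooled into an
#' \code{"other"} category (with a warning) before testing.
#'
#' @param counts_a,counts_b named integer vectors of per-gene chain
#'   counts over the same gene index (missing genes are filled with 0).
#' @return list of class \code{"usage_test"}: \code{chi2, df, p_value,
#'   expected, observed, pooled} (genes merged into "other").
#' @export
usage_chisq <- function(counts_a, counts_b) {
  genes <- union(names(counts_a) %||% seq_along(counts_a),
                 names(counts_b) %||% seq_along(counts_b))
  a <- rep(0, length(genes)); names(a) <- genes
  b <- a
  a[names(counts_a) %||% seq_along(counts_a)] <- counts_a
  b[names(counts_b) %||% seq_along(counts_b)] <- counts_b
  if (sum(a) + sum(b) == 0) stop_tcrgd("all-zero usage table")
  obs <- rbind(a = a, b = b)
  obs <- obs[, colSums(obs) > 0, drop = FALSE]
  expected <- function(o) outer(rowSums(o), colSums(o)) / sum(o)
  e <- expected(obs)
  low <- colSums(e < 1) > 0
  pooled <- character(0)
  if (any(low) && sum(low) < ncol(obs)) {
    pooled <- colnames(obs)[low]
    warning(sprintf("pooling %d low-expected gene(s) into 'other'",
                    length(pooled)))
    obs <- cbind(obs[, !low, drop = FALSE],
                 other = rowSums(obs[, low, drop = FALSE]))
    e <- expected(obs)
  }
  chi2 <- sum((obs - e)^2 / e)
  df <- (nrow(obs) - 1) * (ncol(obs) - 1)
  p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  structure(list(chi2 = chi2, df = df, p_value = p, expected = e,
                 observed = obs, pooled = pooled), class = "usage_test")
}

#' @export
print.usage_test <- function(x, ...) {
  cat(sprintf("Pearson chi-squared: X2 = %.4f, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Clonotype-set overlap between two repertoires
#'
#' Shared clonotype keys and three sharing fractions: over the union of
#' both repertoires (headline number), and over each repertoire
#' separately.
#'
#' @param keys_a,keys_b character vectors of clonotype keys.
#' @return list: \code{shared} (sorted keys), \code{n_shared},
#'   \code{fraction_union}, \code{fraction_a}, \code{fraction_b},
#'   \code{n_a}, \code{n_b}.
#' @export
clonotype_overlap <- function(keys_a, keys_b) {
  a <- unique(keys_a); b <- unique(keys_b)
  shared <- sort(intersect(a, b))
  un <- length(union(a, b))
  list(shared = shared, n_shared = length(shared),
       fraction_union = if (un == 0) 0 else length(shared) / un,
       fraction_a = if (length(a) == 0) 0 else length(shared) / length(a),
       fraction_b = if (length(b) == 0) 0 else length(shared) / length(b),
       n_a = length(a), n_b = length(b))
}

#' Clonotype sharing across the three intestinal segments
#'
#' Seven-region Venn partition of clonotype keys over duodenum, jejunum
#' and ileum: private to each segment, shared by each pair only, and
#' shared by all three.
#'
#' @param keys_by_segment named list with exactly the elements
#'   \code{duodenum}, \code{jejunum}, \code{ileum}, each a character
#'   vector of clonotype keys.
#' @return list of the 7 region counts (\code{duodenum_only}, ...,
#'   \code{duodenum_jejunum}, ..., \code{all_three}) plus
#'   \code{n_union}.
#' @export
cross_segment_sharing <- function(keys_by_segment) {
  segs <- c("duodenum", "jejunum", "ileum")
  missing <- setdiff(segs, names(keys_by_segment))
  if (length(missing) > 0) {
    stop_tcrgd("missing segment(s): %s", paste(missing, collapse = ", "))
  }
  sets <- lapply(keys_by_segment[segs], unique)
  all_keys <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_keys %in% s, logical(length(all_keys)))
  if (length(all_keys) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, segs))
  pattern <- member %*% c(1, 2, 4)  # duo=1, jej=2, ile=4
  cnt <- function(code) sum(pattern == code)
  list(duodenum_only = cnt(1), jejunum_only = cnt(2), ileum_only = cnt(4),
       duodenum_jejunum = cnt(3), duodenum_ileum = cnt(5),
       jejunum_ileum = cnt(6), all_three = cnt(7),
       n_union = length(all_keys))
}

#' Top-clone table across samples
#'
#' The k largest clonotypes of a focal sample, with their sizes and
#' presence in comparator samples. Ties in size break on the CDR3
#' amino-acid sequence so the ranking is deterministic.
#'
#' @param clonotypes_by_sample named list of [group_clonotypes()] tables;
#'   the first element (or \code{focal}) defines the ranking.
#' @param k number of top clones; if larger than available, all are
#'   returned with a note attribute.
#' @param focal name of the focal sample (default: first element).
#' @return a \code{data.table}: \code{rank, key, cdr3_aa},
#'   \code{size_<sample>} and \code{present_<sample>} per sample.
#' @export
top_clone_table <- function(clonotypes_by_sample, k = 20L, focal = NULL) {
  stopifnot(k >= 1, length(clonotypes_by_sample) >= 1)
  focal <- focal %||% names(clonotypes_by_sample)[1]
  foc <- data.table::as.data.table(clonotypes_by_sample[[focal]])
  data.table::setorderv(foc, c("size", "cdr3_aa"), order = c(-1L, 1L))
  note <- NULL
  if (k > nrow(foc)) {
    note <- sprintf("requested k = %d but only %d clonotypes; returning all",
                    k, nrow(foc))
    k <- nrow(foc)
  }
  top <- foc[seq_len(k), c("key", "cdr3_aa")]
  top$rank <- seq_len(k)
  for (nm in names(clonotypes_by_sample)) {
    tab <- data.table::as.data.table(clonotypes_by_sample[[nm]])
    sz <- tab$size[match(top$key, tab$key)]
    sz[is.na(sz)] <- 0L
    top[[paste0("size_", nm)]] <- sz
    top[[paste0("present_", nm)]] <- sz > 0L
  }
  data.table::setcolorder(top, c("rank", "key", "cdr3_aa"))
  if (!is.null(note)) data.table::setattr(top, "note", note)
  top[]
}
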