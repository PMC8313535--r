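# Amino-acid-level clonotypes, paired clonotypes, convergent recombination.
#
# A clonotype is the equivalence class of chains sharing (locus, V gene,
# J gene, CDR3 amino-acid sequence); alleles are stripped so TRGV7*01 and
# TRGV7*02 fall in one clonotype. The nucleotide variants of a clonotype's
# CDR3 partition its cells; two or more variants indicate convergent
# recombination (distinct rearrangements encoding one amino-acid junction).

#' Build a clonotype key
#'
#' The clonotype identity used throughout the package: locus, allele-
#' stripped V gene, allele-stripped J gene, and uppercase CDR3 amino-acid
#' sequence. With \code{allele_level = TRUE}, calls are kept verbatim for
#' sensitivity analyses.
#'
#' @param v_call,j_call gene calls, optionally with \code{"*NN"} allele.
#' @param cdr3_aa CDR3 amino-acid sequence(s), non-empty.
#' @param allele_level keep allele suffixes instead of stripping them.
#' @return character vector of keys, \code{"locus|V|J|CDR3aa"}; components
#'   recoverable with [parse_clonotype_key()].
#' @examples
#' make_clonotype_key("TRGV7*02", "TRGJ1*01", "CASWAGYSSGFHKVF")
#' @export
make_clonotype_key <- function(v_call, j_call, cdr3_aa, allele_level = FALSE) {
  if (any(is.na(cdr3_aa) | !nzchar(cdr3_aa))) {
    stop_tcrgd("cdr3_aa must be non-empty to form a clonotype key")
  }
  locus <- locus_from_v_call(v_call)
  if (anyNA(locus)) {
    stop_tcrgd("unsupported locus in v_call: %s",
               paste(unique(v_call[is.na(locus)]), collapse = ", "))
  }
  v <- if (allele_level) v_call else strip_allele(v_call)
  j <- if (allele_level) j_call else strip_allele(j_call)
  paste(locus, v, j, toupper(cdr3_aa), sep = "|")
}

#' Split clonotype keys into components
#'
#' @param keys character keys from [make_clonotype_key()].
#' @return a \code{data.table} with columns \code{locus, v_gene, j_gene,
#'   cdr3_aa}.
#' @export
parse_clonotype_key <- function(keys) {
  parts <- data.table::tstrsplit(keys, "|", fixed = TRUE)
  data.table::data.table(locus = parts[[1]], v_gene = parts[[2]],
                         j_gene = parts[[3]], cdr3_aa = parts[[4]])
}

# Pull the chain block of one locus out of a paired-cell table.
locus_block <- function(cells, locus = c("TRG", "TRD")) {
  locus <- match.arg(locus)
  pref <- if (locus == "TRG") "gamma_" else "delta_"
  cols <- paste0(pref, c("v_call", "j_call", "cdr3_nt", "cdr3_aa"))
  out <- cells[, c("cell_id", "sample_id", "genotype", "segment", cols),
               with = FALSE]
  data.table::setnames(out, cols, c("v_call", "j_call", "cdr3_nt", "cdr3_aa"))
  out[!is.na(out$v_call)]
}

#' Group cells into clonotypes for one locus
#'
#' Partitions all cells carrying a resolved chain of \code{locus} into
#' clonotypes, recording per-clonotype size, member barcodes, and the
#' partition of CDR3 nucleotide variants.
#'
#' @param cells paired-cell table from [pair_cells()].
#' @param locus \code{"TRG"} or \code{"TRD"}.
#' @param allele_level group at allele rather than gene level.
#' @return a \code{data.table}, one row per clonotype: \code{key, locus,
#'   v_gene, j_gene, cdr3_aa, size, cell_ids} (list column),
#'   \code{nt_variants} (list column of named counts), sorted by
#'   decreasing size then key.
#' @export
group_clonotypes <- function(cells, locus = c("TRG", "TRD"),
                             allele_level = FALSE) {
  locus <- match.arg(locus)
  cells <- data.table::as.data.table(cells)
  ch <- locus_block(cells, locus)
  if (nrow(ch) == 0) return(empty_clonotype_table())
  ch$key <- make_clonotype_key(ch$v_call, ch$j_call, ch$cdr3_aa, allele_level)
  grp <- ch[, list(
    size = .N,
    cell_ids = list(sort(cell_id)),
    nt_variants = list(sort(table(cdr3_nt), decreasing = TRUE))
  ), by = "key"]
  comp <- parse_clonotype_key(grp$key)
  out <- cbind(grp[, "key"], comp, grp[, c("size", "cell_ids", "nt_variants")])
  data.table::setorderv(out, c("size", "key"), order = c(-1L, 1L))
  out[]
}

empty_clonotype_table <- function() {
  data.table::as.data.table(list(
    key = character(0), locus = character(0),
    v_gene = character(0), j_gene = character(0),
    cdr3_aa = character(0), size = integer(0),
    cell_ids = list(), nt_variants = list()))
}

#' Group fully paired cells into gamma/delta paired clonotypes
#'
#' Only cells with both a gamma and a delta chain enter the pairing;
#' half-paired cells are counted in the attached diagnostics.
#'
#' @param cells paired-cell table.
#' @inheritParams group_clonotypes
#' @return a \code{data.table} with \code{gamma_key, delta_key, pair_key,
#'   size}, sorted by decreasing size; attribute \code{"n_unpaired"} holds
#'   the number of cells excluded for lacking one chain.
#' @export
group_paired_clonotypes <- function(cells, allele_level = FALSE) {
  cells <- data.table::as.data.table(cells)
  paired <- cells[!is.na(cells$gamma_v_call) & !is.na(cells$delta_v_call)]
  n_unpaired <- nrow(cells) - nrow(paired)
  if (nrow(paired) == 0) {
    out <- data.table::data.table(gamma_key = character(0),
                                  delta_key = character(0),
                                  pair_key = character(0), size = integer(0))
    data.table::setattr(out, "n_unpaired", n_unpaired)
    return(out)
  }
  gk <- make_clonotype_key(paired$gamma_v_call, paired$gamma_j_call,
                           paired$gamma_cdr3_aa, allele_level)
  dk <- make_clonotype_key(paired$delta_v_call, paired$delta_j_call,
                           paired$delta_cdr3_aa, allele_level)
  out <- data.table::data.table(gamma_key = gk, delta_key = dk)[
    , list(size = .N), by = c("gamma_key", "delta_key")]
  out$pair_key <- paste(out$gamma_key, out$delta_key, sep = "+")
  data.table::setorderv(out, c("size", "pair_key"), order = c(-1L, 1L))
  data.table::setcolorder(out, c("gamma_key", "delta_key", "pair_key", "size"))
  data.table::setattr(out, "n_unpaired", n_unpaired)
  out[]
}

#' Translate a CDR3 nucleotide junction
#'
#' Standard-genetic-code translation of an in-frame junction. A stop codon
#' is an error: the CDR3 of a productive chain contains none.
#'
#' @param nt DNA string over \{A,C,G,T\}, length divisible by 3.
#' @return the amino-acid string.
#' @export
translate_cdr3 <- function(nt) {
  nt <- toupper(nt)
  if (nchar(nt) == 0 || nchar(nt) %% 3 != 0) {
    stop_tcrgd("CDR3 length %d is not a positive multiple of 3", nchar(nt))
  }
  if (grepl("[^ACGT]", nt)) {
    stop_tcrgd("CDR3 contains characters outside {A,C,G,T}: %s", nt)
  }
  codons <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (any(aa == "*")) {
    stop_tcrgd("stop codon in CDR3 of a productive chain: %s", nt)
  }
  paste(aa, collapse = "")
}

#' Detect convergent recombination within a clonotype
#'
#' A clonotype whose cells carry two or more distinct CDR3 nucleotide
#' sequences arose from multiple independent rearrangements converging on
#' one amino-acid junction (or from variants of expanded progenitors; the
#' data cannot distinguish the two, so only counts are reported).
#' Every variant is checked to translate to the clonotype's CDR3.
#'
#' @param clonotype one row of a [group_clonotypes()] table (a list or
#'   single-row data.table with \code{key}, \code{cdr3_aa}, \code{size},
#'   \code{nt_variants}).
#' @return a one-row \code{data.table}: \code{key, n_nt_variants,
#'   dominant_variant_fraction, is_convergent}.
#' @export
detect_convergent_recombination <- function(clonotype) {
  if (data.table::is.data.table(clonotype)) {
    stopifnot(nrow(clonotype) == 1)
    clonotype <- as.list(clonotype)
    clonotype$nt_variants <- clonotype$nt_variants[[1]]
  }
  variants <- clonotype$nt_variants
  if (is.null(variants) || length(variants) == 0) {
    stop_tcrgd("clonotype %s has no nucleotide variants", clonotype$key)
  }
  counts <- as.integer(variants)
  seqs <- names(variants)
  for (s in seqs) {
    tr <- translate_cdr3(s)
    if (tr != clonotype$cdr3_aa) {
      stop_tcrgd("variant %s translates to %s, not %s", s, tr,
                 clonotype$cdr3_aa, class = "tcrgd_consistency_error")
    }
  }
  data.table::as.data.table(list(
    key = clonotype$key,
    n_nt_variants = length(counts),
    dominant_variant_fraction = max(counts) / sum(counts),
    is_convergent = length(counts) >= 2L
  ))
}

#' Convergence report for a whole clonotype table
#'
#' @param clonotypes table from [group_clonotypes()].
#' @return a \code{data.table}, one row per clonotype, columns as in
#'   [detect_convergent_recombination()] plus \code{size}.
#' @export
convergence_report <- function(clonotypes) {
  if (nrow(clonotypes) == 0) {
    return(data.table::as.data.table(list(
      key = character(0), n_nt_variants = integer(0),
      dominant_variant_fraction = numeric(0),
      is_convergent = logical(0), size = integer(0))))
  }
  rows <- lapply(seq_len(nrow(clonotypes)), function(i) {
    detect_convergent_recombination(clonotypes[i])
  })
  out <- data.table::rbindlist(rows)
  out$size <- clonotypes$size
  out[]
}

#' Flat clonotype export table
#'
#' @param clonotypes table from [group_clonotypes()].
#' @return a \code{data.table} without list columns, suitable for TSV
#'   output: clonotype components, size, variant count, dominant variant
#'   fraction.
#' @export
clonotype_export_table <- function(clonotypes) {
  conv <- convergence_report(clonotypes)
  out <- merge(
    clonotypes[, c("key", "locus", "v_gene", "j_gene", "cdr3_aa", "size")],
    conv[, c("key", "n_nt_variants", "dominant_variant_fraction")],
    by = "key", sort = FALSE)
  data.table::setorderv(out, c("size", "key"), order = c(-1L, 1L))
  out[]
}
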