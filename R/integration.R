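# Joining clonotypes with per-cell transcriptome cluster labels.
#
# Cluster labels are inputs from any upstream clustering tool (one label
# per barcode); this module never computes clusters. Cells without a
# label are carried as "unassigned" and reported, never dropped;
# proportions are taken over assigned cells only.

#' Attach cluster labels to paired cells
#'
#' Left join of a cluster-assignment table onto the paired-cell table.
#' Cells without a label get \code{cluster = "unassigned"}.
#'
#' @param cells paired-cell table from [pair_cells()].
#' @param assignments data.frame with columns \code{cell_id},
#'   \code{cluster_label} (one row per barcode; duplicates are an error)
#'   and optionally \code{x}, \code{y} embedding coordinates.
#' @return the cell table with an added \code{cluster} column (character).
#' @export
attach_clusters <- function(cells, assignments) {
  cells <- data.table::as.data.table(cells)
  assignments <- data.table::as.data.table(assignments)
  stopifnot(all(c("cell_id", "cluster_label") %in% names(assignments)))
  if (anyDuplicated(assignments$cell_id)) {
    stop_tcrgd("duplicate cell_id in cluster assignments: %s",
               paste(utils::head(unique(
                 assignments$cell_id[duplicated(assignments$cell_id)]), 3),
                 collapse = ", "))
  }
  out <- data.table::copy(cells)
  idx <- match(out$cell_id, assignments$cell_id)
  out$cluster <- as.character(assignments$cluster_label[idx])
  n_un <- sum(is.na(out$cluster))
  out$cluster[is.na(out$cluster)] <- "unassigned"
  tcrgd_log("DEBUG", sprintf("attached clusters: %d/%d labeled, %d unassigned",
                             nrow(out) - n_un, nrow(out), n_un))
  out[]
}

#' Cluster distribution of one clonotype
#'
#' How the cells carrying a clonotype distribute over transcriptome
#' clusters. Proportions are over assigned cells; unassigned cells are
#' counted separately.
#'
#' @param cells cluster-annotated cell table from [attach_clusters()].
#' @param key clonotype key ([make_clonotype_key()]) or paired key
#'   (\code{"gammaKey+deltaKey"}).
#' @return list of class \code{"cluster_distribution"}: \code{subject},
#'   \code{counts} (named, per cluster), \code{proportions} (sum to 1),
#'   \code{n_cells} (assigned), \code{n_unassigned}.
#' @export
clonotype_cluster_distribution <- function(cells, key) {
  cells <- data.table::as.data.table(cells)
  stopifnot("cluster" %in% names(cells))
  sel <- cells_carrying(cells, key)
  assigned <- sel[sel$cluster != "unassigned"]
  counts <- if (nrow(assigned) == 0) integer(0) else
    sort(table(assigned$cluster), decreasing = TRUE)
  counts <- stats::setNames(as.integer(counts), names(counts))
  props <- if (sum(counts) == 0) numeric(0) else counts / sum(counts)
  structure(list(subject = key, counts = counts, proportions = props,
                 n_cells = sum(counts),
                 n_unassigned = nrow(sel) - nrow(assigned)),
            class = "cluster_distribution")
}

# Rows of the annotated cell table whose gamma, delta, or gamma+delta
# clonotype matches `key` (paired keys contain "+").
cells_carrying <- function(cells, key) {
  paired <- grepl("+", key, fixed = TRUE)
  has_g <- !is.na(cells$gamma_v_call)
  has_d <- !is.na(cells$delta_v_call)
  gk <- rep(NA_character_, nrow(cells))
  dk <- gk
  if (any(has_g)) {
    gk[has_g] <- make_clonotype_key(cells$gamma_v_call[has_g],
                                    cells$gamma_j_call[has_g],
                                    cells$gamma_cdr3_aa[has_g])
  }
  if (any(has_d)) {
    dk[has_d] <- make_clonotype_key(cells$delta_v_call[has_d],
                                    cells$delta_j_call[has_d],
                                    cells$delta_cdr3_aa[has_d])
  }
  if (paired) {
    cells[!is.na(gk) & !is.na(dk) & paste(gk, dk, sep = "+") == key]
  } else {
    locus <- substr(key, 1, 3)
    if (locus == "TRG") cells[!is.na(gk) & gk == key]
    else cells[!is.na(dk) & dk == key]
  }
}

#' Cluster profiles of the delta partners of one gamma clonotype
#'
#' For a focal gamma clonotype, one cluster distribution per distinct
#' delta-chain partner among fully paired cells, ordered by pair size
#' descending. Cells carrying the gamma key without a delta chain are
#' excluded and reported in the \code{n_unpaired} attribute.
#'
#' @param cells cluster-annotated cell table.
#' @param gamma_key TRG clonotype key.
#' @return named list (delta key -> \code{cluster_distribution}, each
#'   with a \code{pair_size} element), attribute \code{"n_unpaired"}.
#' @export
pairing_cluster_profiles <- function(cells, gamma_key) {
  cells <- data.table::as.data.table(cells)
  sel <- cells_carrying(cells, gamma_key)
  paired <- sel[!is.na(sel$delta_v_call)]
  n_unpaired <- nrow(sel) - nrow(paired)
  if (nrow(paired) == 0) {
    out <- list()
    attr(out, "n_unpaired") <- n_unpaired
    return(out)
  }
  dk <- make_clonotype_key(paired$delta_v_call, paired$delta_j_call,
                           paired$delta_cdr3_aa)
  sizes <- sort(table(dk), decreasing = TRUE)
  out <- lapply(names(sizes), function(d) {
    dist <- clonotype_cluster_distribution(
      paired[dk == d], paste(gamma_key, d, sep = "+"))
    dist$pair_size <- as.integer(sizes[[d]])
    dist
  })
  names(out) <- names(sizes)
  attr(out, "n_unpaired") <- n_unpaired
  out
}

#' V-gene usage shift within one cluster
#'
#' Compares the V-gene composition of one transcriptome cluster between
#' two samples (e.g. genotypes) with Pearson's chi-squared test.
#'
#' @param cells_a,cells_b cluster-annotated cell tables.
#' @param cluster cluster label, present in both tables.
#' @param locus \code{"TRG"} or \code{"TRD"}.
#' @return a \code{usage_test} (see [usage_chisq()]).
#' @export
cluster_usage_shift <- function(cells_a, cells_b, cluster,
                                locus = c("TRG", "TRD")) {
  locus <- match.arg(locus)
  counts_in_cluster <- function(cells, label) {
    cells <- data.table::as.data.table(cells)
    stopifnot("cluster" %in% names(cells))
    # evaluate the mask outside [ ]: `cluster` is both an argument here
    # and a column name, and data.table would resolve it to the column
    keep <- cells$cluster == as.character(cluster)
    sub <- cells[which(keep)]
    if (nrow(sub) == 0) {
      stop_tcrgd("cluster %s absent from sample %s", cluster, label)
    }
    ch <- locus_block(sub, locus)
    if (nrow(ch) < 2) {
      stop_tcrgd("cluster %s has fewer than 2 %s chains in sample %s",
                 cluster, locus, label)
    }
    table(strip_allele(ch$v_call))
  }
  a <- counts_in_cluster(cells_a, "a")
  b <- counts_in_cluster(cells_b, "b")
  usage_chisq(stats::setNames(as.integer(a), names(a)),
              stats::setNames(as.integer(b), names(b)))
}
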