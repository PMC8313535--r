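# Chain-table ingestion, productive filtering, per-cell gamma/delta pairing.
#
# A chain table is a data.table with one row per annotated V(D)J contig:
#   cell_id, sample_id, genotype, segment, locus, v_call, j_call,
#   cdr3_nt, cdr3_aa, productive, umi_count, contig_id
# Loci are restricted to TRG and TRD; locus is always rederivable from the
# V-call prefix (TRGV -> TRG, TRDV -> TRD).

CHAIN_COLUMNS <- c("cell_id", "sample_id", "genotype", "segment", "locus",
                   "v_call", "j_call", "cdr3_nt", "cdr3_aa", "productive",
                   "umi_count", "contig_id")

# Fixed dialect column maps (chain-table column -> file column).
DIALECT_MAPS <- list(
  airr = c(cell_id = "cell_id", locus = "locus", v_call = "v_call",
           j_call = "j_call", cdr3_nt = "junction", cdr3_aa = "junction_aa",
           productive = "productive", umi_count = "duplicate_count",
           contig_id = "sequence_id", sample_id = "sample_id",
           genotype = "genotype", segment = "segment"),
  tenx = c(cell_id = "barcode", locus = "chain", v_call = "v_gene",
           j_call = "j_gene", cdr3_nt = "cdr3_nt", cdr3_aa = "cdr3",
           productive = "productive", umi_count = "umis",
           contig_id = "contig_id", sample_id = "sample_id",
           genotype = "genotype", segment = "segment")
)

# sample_id/genotype/segment travel as extra columns in either dialect; they
# are not part of the MiAIRR or 10x core schema but both formats tolerate
# extra columns, and carrying them keeps round-trips lossless.
METADATA_COLUMNS <- c("sample_id", "genotype", "segment")

#' Read a V(D)J chain table
#'
#' Reads per-chain V(D)J annotations from an AIRR Rearrangement TSV or a
#' 10x-style \code{filtered_contig_annotations} CSV and normalizes them to
#' the package's chain-table layout. No rows are dropped: non-productive
#' chains are retained and removed later by [filter_productive()].
#'
#' @param path path to the input file.
#' @param dialect \code{"airr"} (tab-separated, MiAIRR column names) or
#'   \code{"tenx"} (comma-separated, \code{barcode}/\code{chain}/
#'   \code{v_gene}/... column names).
#' @param metadata optional data.frame with columns \code{sample_id},
#'   \code{genotype}, \code{segment}; joined on \code{sample_id} when the
#'   file lacks genotype/segment columns.
#' @return a \code{data.table} with columns \code{cell_id, sample_id,
#'   genotype, segment, locus, v_call, j_call, cdr3_nt, cdr3_aa,
#'   productive, umi_count, contig_id}.
#' @seealso [write_rearrangements()] for the inverse operation.
#' @export
read_rearrangements <- function(path, dialect = c("airr", "tenx"),
                                metadata = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_tcrgd("input file does not exist: %s", path)
  sep <- if (dialect == "airr") "\t" else ","
  raw <- data.table::fread(path, sep = sep, colClasses = list(
    character = intersect(c("cell_id", "barcode", "sequence_id", "contig_id"),
                          names(data.table::fread(path, sep = sep, nrows = 0)))
  ))
  map <- DIALECT_MAPS[[dialect]]
  required <- setdiff(unname(map), unname(map[METADATA_COLUMNS]))
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop_tcrgd("missing required %s column(s): %s", dialect,
               paste(missing, collapse = ", "), class = "tcrgd_format_error")
  }
  extra <- setdiff(names(raw), unname(map))
  if (length(extra) > 0) {
    tcrgd_log("DEBUG", "ignoring extra columns: ", paste(extra, collapse = ", "))
  }
  out <- data.table::data.table(
    cell_id = as.character(raw[[map["cell_id"]]]),
    sample_id = if (map["sample_id"] %in% names(raw))
      as.character(raw[[map["sample_id"]]]) else NA_character_,
    genotype = if (map["genotype"] %in% names(raw))
      as.character(raw[[map["genotype"]]]) else NA_character_,
    segment = if (map["segment"] %in% names(raw))
      as.character(raw[[map["segment"]]]) else NA_character_,
    locus = as.character(raw[[map["locus"]]]),
    v_call = as.character(raw[[map["v_call"]]]),
    j_call = as.character(raw[[map["j_call"]]]),
    cdr3_nt = toupper(as.character(raw[[map["cdr3_nt"]]])),
    cdr3_aa = toupper(as.character(raw[[map["cdr3_aa"]]])),
    productive = parse_productive(raw[[map["productive"]]]),
    umi_count = as.integer(raw[[map["umi_count"]]]),
    contig_id = as.character(raw[[map["contig_id"]]])
  )
  if (!is.null(metadata)) {
    metadata <- data.table::as.data.table(metadata)
    stopifnot(all(c("sample_id", "genotype", "segment") %in% names(metadata)))
    out[, c("genotype", "segment") := NULL]
    out <- merge(out, metadata[, c("sample_id", "genotype", "segment")],
                 by = "sample_id", all.x = TRUE, sort = FALSE)
    data.table::setcolorder(out, CHAIN_COLUMNS)
  }
  derived <- locus_from_v_call(out$v_call)
  bad <- which(is.na(derived) | derived != out$locus)
  if (length(bad) > 0) {
    stop_tcrgd("unsupported or inconsistent locus at row(s) %s (v_call %s)",
               paste(utils::head(bad, 5), collapse = ", "),
               paste(utils::head(out$v_call[bad], 5), collapse = ", "),
               class = "tcrgd_record_error")
  }
  validate_chain_table(out)
  out[]
}

# AIRR writes productive as "T"/"F"; 10x as "True"/"False"; accept logicals too.
parse_productive <- function(x) {
  if (is.logical(x)) return(x)
  x <- toupper(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("T", "TRUE")] <- TRUE
  out[x %in% c("F", "FALSE")] <- FALSE
  as.logical(out)
}

validate_chain_table <- function(x) {
  missing <- setdiff(CHAIN_COLUMNS, names(x))
  if (length(missing) > 0) {
    stop_tcrgd("chain table lacks column(s): %s",
               paste(missing, collapse = ", "))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(!x$locus %in% c("TRG", "TRD"))) {
    stop_tcrgd("chain table contains loci other than TRG/TRD")
  }
  if (any(x$umi_count < 0, na.rm = TRUE)) {
    stop_tcrgd("negative umi_count")
  }
  invisible(x)
}

#' Write a chain table
#'
#' Serializes a chain table back to disk in either dialect so that
#' \code{read_rearrangements(write_rearrangements(x))} reproduces \code{x}
#' field-for-field.
#'
#' @param records chain table as returned by [read_rearrangements()].
#' @param path output path.
#' @param dialect \code{"airr"} or \code{"tenx"}.
#' @return \code{path}, invisibly.
#' @export
write_rearrangements <- function(records, path, dialect = c("airr", "tenx")) {
  dialect <- match.arg(dialect)
  records <- data.table::as.data.table(records)
  validate_chain_table(records)
  map <- DIALECT_MAPS[[dialect]]
  out <- records[, CHAIN_COLUMNS, with = FALSE]
  if (dialect == "airr") {
    out$productive <- ifelse(out$productive, "T", "F")
  } else {
    out$productive <- ifelse(out$productive, "True", "False")
  }
  data.table::setnames(out, names(map), unname(map), skip_absent = FALSE)
  sep <- if (dialect == "airr") "\t" else ","
  data.table::fwrite(out, path, sep = sep)
  invisible(path)
}

#' Keep productive chains only
#'
#' Restricts a chain table to rows flagged productive (in-frame junction,
#' no stop codon). Productivity is taken from the annotation pipeline and
#' never inferred from sequence.
#'
#' @param records chain table.
#' @return the productive subset, original row order preserved.
#' @export
filter_productive <- function(records) {
  records <- data.table::as.data.table(records)
  validate_chain_table(records)
  if (nrow(records) > 0 && anyNA(records$productive)) {
    stop_tcrgd(paste0("productive flag missing for some records; ",
                      "annotate productivity upstream"))
  }
  out <- records[records$productive %in% TRUE]
  if (nrow(records) > 0 && nrow(out) == 0) {
    tcrgd_log("WARN", "no productive chains remain after filtering")
  }
  out[]
}

#' Resolve one gamma and one delta chain per cell
#'
#' Collapses a productive-filtered chain table to one row per cell barcode,
#' with at most one TRG and one TRD chain. When a barcode carries more than
#' one chain of a locus, the chain with the highest UMI count is kept (ties
#' broken by lexicographically smallest \code{contig_id}) and the cell is
#' flagged via \code{multi_chain_flag} so downstream analyses can exclude
#' it if desired.
#'
#' @param records productive-filtered chain table.
#' @param policy multi-chain resolution policy; only \code{"top_umi"}.
#' @return a paired-cell \code{data.table}, one row per barcode, with
#'   \code{gamma_*} and \code{delta_*} column blocks (NA when the locus is
#'   absent) and \code{multi_chain_flag}.
#' @export
pair_cells <- function(records, policy = c("top_umi")) {
  policy <- match.arg(policy)
  records <- data.table::as.data.table(records)
  validate_chain_table(records)
  if (nrow(records) == 0) return(empty_paired_table())
  dt <- data.table::copy(records)
  # deterministic resolution: highest umi, then smallest contig_id
  data.table::setorderv(dt, c("cell_id", "locus", "umi_count", "contig_id"),
                        order = c(1L, 1L, -1L, 1L))
  multi <- dt[, list(multi_chain_flag = any(table(locus) > 1L)),
              by = "cell_id"]
  top <- dt[, utils::head(.SD, 1L), by = c("cell_id", "locus")]
  wide <- data.table::dcast(
    top, cell_id + sample_id + genotype + segment ~ locus,
    value.var = c("v_call", "j_call", "cdr3_nt", "cdr3_aa", "umi_count",
                  "contig_id")
  )
  for (loc in c("TRG", "TRD")) {
    pref <- if (loc == "TRG") "gamma" else "delta"
    for (f in c("v_call", "j_call", "cdr3_nt", "cdr3_aa", "umi_count",
                "contig_id")) {
      src <- paste0(f, "_", loc)
      dst <- paste0(pref, "_", f)
      if (src %in% names(wide)) {
        data.table::setnames(wide, src, dst)
      } else {
        wide[[dst]] <- if (f == "umi_count") NA_integer_ else NA_character_
      }
    }
  }
  out <- merge(wide, multi, by = "cell_id", sort = TRUE)
  data.table::setcolorder(out, paired_table_columns())
  out[]
}

paired_table_columns <- function() {
  c("cell_id", "sample_id", "genotype", "segment",
    paste0("gamma_", c("v_call", "j_call", "cdr3_nt", "cdr3_aa", "umi_count",
                       "contig_id")),
    paste0("delta_", c("v_call", "j_call", "cdr3_nt", "cdr3_aa", "umi_count",
                       "contig_id")),
    "multi_chain_flag")
}

empty_paired_table <- function() {
  cols <- paired_table_columns()
  out <- data.table::as.data.table(
    stats::setNames(lapply(cols, function(cl) {
      if (grepl("umi_count$", cl)) integer(0)
      else if (cl == "multi_chain_flag") logical(0)
      else character(0)
    }), cols))
  out
}

#' Summarize chain assembly and pairing
#'
#' Counts cells, productive chains per locus, and fully paired cells.
#' The paired fraction is reported as a percentage of all cells, rounded
#' to one decimal.
#'
#' @param cells paired-cell table from [pair_cells()].
#' @return a one-row \code{data.table}: \code{n_cells},
#'   \code{n_productive_gamma}, \code{n_productive_delta}, \code{n_paired},
#'   \code{paired_fraction} (percent, NA when there are no cells).
#' @export
assembly_summary <- function(cells) {
  cells <- data.table::as.data.table(cells)
  n_cells <- nrow(cells)
  n_g <- sum(!is.na(cells$gamma_v_call))
  n_d <- sum(!is.na(cells$delta_v_call))
  n_paired <- sum(!is.na(cells$gamma_v_call) & !is.na(cells$delta_v_call))
  frac <- if (n_cells == 0) NA_real_ else round(100 * n_paired / n_cells, 1)
  data.table::data.table(
    n_cells = n_cells, n_productive_gamma = n_g, n_productive_delta = n_d,
    n_paired = n_paired, paired_fraction = frac
  )
}
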