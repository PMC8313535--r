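# End-to-end orchestration: chain tables -> reproducible report bundle.

#' Pipeline configuration
#'
#' @param inputs named list \code{sample_id -> list(path =, dialect =)}
#'   of chain tables, or a single chain \code{data.frame} under
#'   \code{chains} (already read).
#' @param chains optional in-memory chain table (alternative to
#'   \code{inputs}).
#' @param metadata optional sample metadata data.frame
#'   (\code{sample_id, genotype, segment}).
#' @param cluster_path optional cluster-assignment CSV
#'   (\code{cell_id, cluster_label}).
#' @param loci loci to analyze.
#' @param m,B,seed rarefaction defaults (see [rarefaction_spec()]);
#'   samples smaller than \code{m} have their diversity reported at
#'   \code{m = n} with a note rather than aborting the whole run when
#'   \code{allow_small = TRUE}.
#' @param allow_small permit samples with fewer than \code{m} chains.
#' @param out_dir output directory, created if needed.
#' @return config list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(inputs = NULL, chains = NULL, metadata = NULL,
                            cluster_path = NULL, loci = c("TRG", "TRD"),
                            m = 3500L, B = 50L, seed = 1L,
                            allow_small = FALSE, out_dir = "tcrgd_report") {
  if (is.null(inputs) && is.null(chains)) {
    stop_tcrgd("pipeline_config needs either inputs or chains")
  }
  structure(list(inputs = inputs, chains = chains, metadata = metadata,
                 cluster_path = cluster_path, loci = loci,
                 m = as.integer(m), B = as.integer(B),
                 seed = as.integer(seed), allow_small = allow_small,
                 out_dir = out_dir),
            class = "pipeline_config")
}

write_tsv <- function(x, path) data.table::fwrite(x, path, sep = "\t")

#' Run the full repertoire analysis pipeline
#'
#' read -> productive filter -> pairing -> assembly summary ->
#' clonotyping -> per-sample diversity (gamma, delta, paired) and D50 ->
#' usage tables and chi-squared tests -> pairwise overlap (and
#' cross-segment sharing when all three segments are present) ->
#' convergence reports -> cluster integration (when labels are given).
#' All outputs are TSV/JSON files under \code{config$out_dir}; the run
#' manifest records the seed, parameters and package version. Identical
#' inputs and seed reproduce every report file byte-for-byte (the
#' manifest's timestamp is the only volatile field). Any stage failure
#' removes partial outputs and aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory results (\code{summary},
#'   \code{clonotypes}, \code{diversity}, \code{d50}, \code{usage},
#'   \code{overlap}, \code{sharing}, \code{convergence},
#'   \code{integration}, \code{files}).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  stage <- "setup"
  emit <- function(x, name) {
    path <- file.path(config$out_dir, name)
    if (grepl("\\.json$", name)) {
      jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
    } else {
      write_tsv(x, path)
    }
    written <<- c(written, path)
    path
  }
  res <- tryCatch({
    stage <- "read"
    chains <- if (!is.null(config$chains)) {
      data.table::as.data.table(config$chains)
    } else {
      data.table::rbindlist(lapply(names(config$inputs), function(sid) {
        inp <- config$inputs[[sid]]
        read_rearrangements(inp$path, inp$dialect, metadata = config$metadata)
      }))
    }
    stage <- "filter_productive"
    chains <- filter_productive(chains)
    stage <- "pair_cells"
    cells <- pair_cells(chains)
    stage <- "assembly_summary"
    summ <- assembly_summary(cells)
    emit(summ, "assembly_summary.tsv")

    stage <- "clonotyping"
    sample_ids <- sort(unique(cells$sample_id))
    clonos <- list()
    for (loc in config$loci) {
      per_sample <- lapply(sample_ids, function(sid) {
        group_clonotypes(cells[cells$sample_id == sid], loc)
      })
      names(per_sample) <- sample_ids
      clonos[[loc]] <- per_sample
      pooled <- group_clonotypes(cells, loc)
      emit(clonotype_export_table(pooled),
           sprintf("clonotypes_%s.tsv", loc))
    }
    paired_by_sample <- lapply(sample_ids, function(sid) {
      group_paired_clonotypes(cells[cells$sample_id == sid])
    })
    names(paired_by_sample) <- sample_ids

    stage <- "diversity"
    div_rows <- list()
    d50_rows <- list()
    for (sid in sample_ids) {
      units <- c(as.list(config$loci), list("paired"))
      for (u in units) {
        ab <- if (identical(u, "paired")) {
          clonotype_abundance(paired_by_sample[[sid]])
        } else {
          clonotype_abundance(clonos[[u]][[sid]])
        }
        if (length(ab) == 0) next
        n <- sum(ab)
        m_eff <- config$m
        note <- ""
        if (m_eff > n) {
          if (!config$allow_small) {
            stop_tcrgd("interpolation point m = %d exceeds n = %d for sample %s (%s)",
                       config$m, n, sid, u)
          }
          m_eff <- n
          note <- sprintf("m reduced from %d to n", config$m)
        }
        for (q in c(0, 1)) {
          spec <- rarefaction_spec(q = q, m = m_eff, B = config$B,
                                   seed = derive_seed(config$seed,
                                                      length(div_rows) + 1L))
          est <- bootstrap_diversity(ab, spec)
          div_rows[[length(div_rows) + 1L]] <- data.table::data.table(
            sample_id = sid, unit = if (identical(u, "paired")) "paired" else u,
            q = q, m = m_eff, n = n, s_obs = length(ab),
            estimate = est$estimate, ci_low = est$ci_low,
            ci_high = est$ci_high, B = spec$B, seed = spec$seed, note = note)
        }
        dd <- d50(ab)
        d50_rows[[length(d50_rows) + 1L]] <- data.table::data.table(
          sample_id = sid, unit = if (identical(u, "paired")) "paired" else u,
          k = dd$k, normalized = dd$normalized, s_obs = dd$s_obs, n = dd$n)
      }
    }
    div_tab <- data.table::rbindlist(div_rows)
    d50_tab <- data.table::rbindlist(d50_rows)
    emit(div_tab, "diversity.tsv")
    emit(d50_tab, "d50.tsv")

    stage <- "usage"
    usage_out <- list()
    for (loc in config$loci) {
      ut <- gene_usage(cells, loc, level = "V")
      counts <- data.table::as.data.table(ut$counts, keep.rownames = "gene")
      emit(counts, sprintf("usage_%s.tsv", loc))
      usage_out[[loc]] <- ut
    }
    usage_tests <- list()
    if (length(sample_ids) >= 2) {
      for (loc in config$loci) {
        cm <- usage_out[[loc]]$counts
        pairs <- utils::combn(colnames(cm), 2, simplify = FALSE)
        for (pr in pairs) {
          tst <- suppressWarnings(usage_chisq(cm[, pr[1]], cm[, pr[2]]))
          usage_tests[[length(usage_tests) + 1L]] <- data.table::data.table(
            locus = loc, sample_a = pr[1], sample_b = pr[2],
            chi2 = tst$chi2, df = tst$df, p_value = tst$p_value)
        }
      }
      emit(data.table::rbindlist(usage_tests), "usage_tests.tsv")
    }

    stage <- "overlap"
    overlaps <- list()
    if (length(sample_ids) >= 2) {
      for (loc in config$loci) {
        pairs <- utils::combn(sample_ids, 2, simplify = FALSE)
        for (pr in pairs) {
          ov <- clonotype_overlap(clonos[[loc]][[pr[1]]]$key,
                                  clonos[[loc]][[pr[2]]]$key)
          ov$shared <- NULL  # keys omitted from the JSON summary
          overlaps[[paste(loc, pr[1], pr[2], sep = "|")]] <- ov
        }
      }
      emit(overlaps, "overlap.json")
    }
    sharing <- NULL
    segs <- unique(cells$segment)
    if (all(c("duodenum", "jejunum", "ileum") %in% segs)) {
      sharing <- list()
      for (loc in config$loci) {
        by_seg <- lapply(c("duodenum", "jejunum", "ileum"), function(sg) {
          group_clonotypes(cells[cells$segment == sg], loc)$key
        })
        names(by_seg) <- c("duodenum", "jejunum", "ileum")
        sharing[[loc]] <- cross_segment_sharing(by_seg)
      }
      emit(sharing, "cross_segment_sharing.json")
    }

    stage <- "convergence"
    conv <- list()
    for (loc in config$loci) {
      pooled <- group_clonotypes(cells, loc)
      conv[[loc]] <- convergence_report(pooled)
      emit(conv[[loc]], sprintf("convergence_%s.tsv", loc))
    }

    stage <- "integration"
    integration <- NULL
    if (!is.null(config$cluster_path)) {
      assignments <- data.table::fread(config$cluster_path,
                                       colClasses = list(character = "cell_id"))
      ann <- attach_clusters(cells, assignments)
      top_g <- group_clonotypes(cells, "TRG")
      if (nrow(top_g) > 0) {
        focal <- top_g$key[1]
        dist <- clonotype_cluster_distribution(ann, focal)
        profiles <- pairing_cluster_profiles(ann, focal)
        integration <- list(
          focal_gamma = focal,
          focal_distribution = list(counts = as.list(dist$counts),
                                    n_cells = dist$n_cells,
                                    n_unassigned = dist$n_unassigned),
          pairing_profiles = lapply(profiles, function(p) {
            list(pair_size = p$pair_size, counts = as.list(p$counts))
          }))
        emit(integration, "integration.json")
      }
    }

    stage <- "manifest"
    manifest <- list(
      package = "tcrgd",
      version = as.character(utils::packageVersion("tcrgd")),
      seed = config$seed, m = config$m, B = config$B,
      loci = config$loci,
      n_samples = length(sample_ids),
      timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)

    list(summary = summ, clonotypes = clonos, paired = paired_by_sample,
         diversity = div_tab, d50 = d50_tab, usage = usage_out,
         overlap = overlaps, sharing = sharing, convergence = conv,
         integration = integration, files = written)
  }, error = function(e) {
    unlink(written)
    stop_tcrgd("pipeline stage '%s' failed: %s", stage, conditionMessage(e),
               class = "tcrgd_pipeline_error")
  })
  invisible(res)
}
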