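# tcrgd — paired γδ T-cell receptor repertoire analysis

`tcrgd` is an R package for analysing paired single-cell γδ TCR
repertoires, of the kind produced by 10x-style single-cell V(D)J
sequencing of intestinal intraepithelial lymphocytes (IELs). It is aimed
at immunologists and computational biologists who have per-chain V(D)J
annotation tables (AIRR Rearrangement TSV or 10x
`filtered_contig_annotations` CSV) plus optional per-cell transcriptome
cluster labels, and want a reproducible route from those tables to
clonotypes, diversity estimates, gene-usage tests, sharing statistics
and clonotype–cluster integration.

## What it computes

* **Chain ingestion and pairing** — productive-chain filtering and
  per-barcode resolution to at most one TRG and one TRD chain (top-UMI
  policy, deterministic tie-break, multi-chain barcodes flagged).
* **Clonotyping** — a clonotype is the equivalence class
  (locus, V gene, J gene, CDR3 amino-acid sequence); alleles are
  stripped. The CDR3 nucleotide variants within each clonotype are
  partitioned, and clonotypes encoded by ≥ 2 distinct nucleotide
  sequences are reported as **convergent recombination** events.
* **Hill-number diversity** with rarefaction and extrapolation.
  Order *q* = 0 is species richness; *q* = 1 is the exponential of
  Shannon entropy, the "effective number of clones":
  *D¹ = exp(−Σᵢ pᵢ ln pᵢ)*. Interpolation to a reference size *m* uses
  exact hypergeometric expectations of without-replacement subsampling;
  extrapolation uses the Chao1 unseen-clone estimate
  *f̂₀ = ((n−1)/n) f₁²/(2f₂)* and an asymptotic entropy estimator.
  Confidence intervals come from a coverage-adjusted bootstrap: *n*
  chains are redrawn from an assemblage that reintroduces the estimated
  unseen clones, each replicate is re-interpolated at *m*, and the 95%
  CI is the point estimate ± 1.96 bootstrap SD.
* **Fixed-point comparison** — two samples bootstrapped at a common
  interpolation point (default *m* = 3500, *B* = 50) and compared with a
  two-sample t-test over the replicate sets (Welch by default).
* **D50** — the smallest number of top clones accounting for half of
  all chains, normalized by the number of unique clones.
* **V/J usage** — dense per-sample usage tables and Pearson chi-squared
  tests on raw chain counts (no continuity correction).
* **Sharing** — clonotype-set overlap between repertoires and the
  7-region Venn partition across duodenum/jejunum/ileum.
* **Integration** — joins per-cell cluster labels (computed by any
  external tool) to clonotypes: per-clonotype cluster distributions,
  per-δ-partner cluster profiles of a focal γ clone, and V-gene
  usage shifts within a cluster.
* **Synthetic data** — a generator with known ground truth (clone
  frequencies, convergent variants, γ–δ pairing table, cluster weights)
  emulating the structure of murine gut γδ IEL repertoires, so the whole
  pipeline is testable without any download.

## Worked example

```r
library(tcrgd)

cfg  <- sim_config(seed = 1, n_cells = 4000)   # KO vs WT ileum preset
sim  <- generate_repertoire(cfg)
cells <- pair_cells(filter_productive(sim$chains))
assembly_summary(cells)
#>    n_cells n_productive_gamma n_productive_delta n_paired paired_fraction
#> 1:    8000               6363               6432     4795            59.9

ko <- clonotype_abundance(group_clonotypes(cells[cells$sample_id == "KO_ileum"], "TRG"))
wt <- clonotype_abundance(group_clonotypes(cells[cells$sample_id == "WT_ileum"], "TRG"))
compare_diversity_at_point(ko, wt, rarefaction_spec(q = 1, m = 3000, B = 50, seed = 1))
#> mean diversity 88.16 vs 90.89; t = -5.232, p = 9.644e-07

d50(ko)
#> $k [1] 16        # 16 top clones hold half of the 3165 chains
#> $normalized [1] 0.0561

convergence_report(group_clonotypes(cells, "TRG"))[1]
#>                                key n_nt_variants dominant_variant_fraction is_convergent size
#> 1: TRG|TRGV7|TRGJ1|CASWAGYSSGFHKVF             3                 0.561              TRUE  615
```

Reading the output: the two simulated samples share the same generative
law, so the small diversity difference above is bootstrap-significant
but biologically trivial — the generator's preset pins a public
TRGV7/TRGJ1 clone at ~10% of γ chains (rank 1 above, 615 cells) encoded
by 3 distinct nucleotide sequences, i.e. a convergent clonotype.

End-to-end, with TSV/JSON reports and a run manifest:

```r
run_pipeline(pipeline_config(
  inputs = list(run1 = list(path = "chains_airr.tsv", dialect = "airr")),
  cluster_path = "clusters.csv", m = 3500, B = 50, seed = 1,
  out_dir = "report"))
```

A small command-line wrapper with `simulate` / `diversity` / `run`
subcommands ships in `inst/cli/tcrgd.R`.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the estimators,
the bootstrap construction, the synthetic-data model and the numerical
design choices in detail.
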