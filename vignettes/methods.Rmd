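---
title: "Methods: paired γδ TCR repertoire analysis with tcrgd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired γδ TCR repertoire analysis with tcrgd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrgd)
```

## Scope and model

`tcrgd` analyses paired single-cell γδ TCR repertoires. The observation
unit is a cell barcode carrying at most one resolved productive TRG
chain and one TRD chain; the inferential unit is the clonotype, defined
as the equivalence class (locus, V gene, J gene, CDR3 amino-acid
sequence). All diversity statistics operate on the abundance vector
$X_1, \dots, X_S$ of clone sizes within one sample and locus (or on
γ/δ *pairs* for the paired analysis), under the usual multinomial
sampling model: chains are draws from an underlying clone-frequency
distribution $p_1, \dots, p_S$.

Upstream steps — contig assembly, germline alignment, productivity
calling, transcriptome clustering — are out of scope; their outputs
(annotation tables, cluster labels) are inputs here.

## Chain handling

* **Productivity** is taken from the annotation pipeline's flag. A
  missing flag is an error, never an inference: productivity calling
  needs germline context this package does not have.
* **Multi-chain barcodes.** Droplet data occasionally yields more than
  one productive chain per locus per barcode (doublets, ambient mRNA).
  The resolution policy keeps the chain with the highest UMI count,
  breaking ties on the lexicographically smallest contig id so the
  result is order-independent, and flags the cell
  (`multi_chain_flag`) so downstream analyses can exclude it. This is a
  package convention; typical upstream pipelines do not document theirs.
* **Alleles.** V/J calls are stored verbatim (`TRGV7*02`), but
  clonotyping and usage tables strip the `*NN` allele suffix, because
  the clonotype rule and usage comparisons are defined at gene level.
  Allele-level grouping is available (`allele_level = TRUE`) for
  sensitivity analyses.

## Diversity estimators

Two Hill numbers are supported. Order $q = 0$ is species richness;
order $q = 1$ is the exponential of Shannon entropy,
$D^1 = \exp(-\sum_i p_i \ln p_i)$, the effective number of clones.
General $q$ is deliberately out of scope.

**Interpolation (rarefaction).** For a subsample of size $m \le n$
drawn without replacement,

$$\hat S(m) = \sum_i \left[1 - \binom{n - X_i}{m}\Big/\binom{n}{m}\right],$$

and for entropy the exact hypergeometric expectation is used: the
subsample count $J_i$ of clone $i$ is
$\mathrm{Hypergeom}(X_i, n - X_i, m)$, so

$$\hat H(m) = \sum_i \mathbb E\!\left[\frac{J_i}{m} \ln\frac{m}{J_i}\right],$$

evaluated clone-count by clone-count (clones with equal $X_i$ are
grouped, which makes the cost proportional to the number of *distinct*
count values times $m$). Both formulas are checked in the test suite
against exhaustive enumeration of all $\binom{n}{m}$ subsamples for
every abundance vector with $n \le 10$, and richness additionally
against `vegan::rarefy`. When the exact entropy work exceeds a budget
(default $5 \times 10^7$ hypergeometric terms) a seeded Monte-Carlo
mode with $\ge 1000$ without-replacement subsamples is used instead;
the two modes agree within Monte-Carlo error on overlapping inputs.

**Extrapolation.** The number of unseen clones is estimated by Chao1,
$\hat f_0 = \frac{n-1}{n} \frac{f_1^2}{2 f_2}$ (or
$\frac{n-1}{n} f_1 (f_1 - 1) / 2$ when $f_2 = 0$), giving

$$\hat S(n + m^*) = S_{obs} + \hat f_0\left[1 - \Big(1 -
\tfrac{f_1}{n \hat f_0 + f_1}\Big)^{m^*}\right].$$

With no singletons the sample is treated as complete. For $q = 1$ the
extrapolated entropy blends the plug-in value with an asymptotic
entropy estimator $\hat H_\infty$ (the harmonic-sum estimator with the
singleton tail correction governed by
$A = 2 f_2 / [(n-1) f_1 + 2 f_2]$), weighted $n : m^*$. $\hat H_\infty$
is floored at the plug-in entropy so curves are nondecreasing. The
reference analysis this package targets relies on interpolation;
extrapolation accuracy is secondary and is validated only qualitatively
(monotone, approaches the asymptote, moves toward the truth on
synthetic data).

**Coverage-adjusted bootstrap.** The resampling law the CIs are built
on reconstructs an assemblage containing both the observed clones, with
shrunk probabilities
$\hat p_i = \frac{X_i}{n}\big(1 - \lambda (1 - X_i/n)^n\big)$, and
$\lceil \hat f_0 \rceil$ unseen clones sharing the missing coverage
$1 - \hat C$, where
$\hat C = 1 - \frac{f_1}{n}\frac{(n-1) f_1}{(n-1) f_1 + 2 f_2}$ and
$\lambda$ is chosen so the observed clones carry total mass $\hat C$.
Each of the $B$ replicates (default 50, the convention of the
experiments this package mirrors) redraws $n$ chains multinomially from
this assemblage and re-evaluates the interpolated estimate at $m$; the
95% CI is the point estimate $\pm 1.96$ replicate SD. Degenerate
denominators (e.g. a single observed clone of singletons) fall back to
naive $X_i/n$ probabilities with a warning. A plain
without-replacement subsampling mode (`resampling = "subsample"`) is
available for sensitivity, since the upstream description of
"bootstrap" does not pin down the law.

**Fixed-point comparison.** Two samples are bootstrapped at a common
$m$ (default 3500) and their replicate sets compared with a two-sided
t-test. Welch's unequal-variance form is the default — it is the robust
choice when the two repertoires have different tail weight — with
Student's pooled test behind `var_equal = TRUE`. Both samples share the
spec's seed, so comparing a sample against itself returns identical
replicate sets and $p = 1$, which doubles as a determinism check.

**D50.** The smallest $k$ with
$\sum_{i \le k} X_{(i)} \ge n/2$ over the descending order statistics,
normalized by $S_{obs}$. "Comprise 50%" is read as *reaching at least*
half the chains, so exact halves need no rounding rule. Ties among
equal counts cannot change $k$.

## Usage, sharing, integration

Chi-squared tests are Pearson's on the raw $2 \times G$ chain-count
table, no continuity correction (the comparisons are multi-category);
genes with expected count below 1 are pooled into `other` with a
warning. Overlap reports all three sharing fractions — over the union
and over each repertoire — because "fraction shared" is ambiguous in
common usage; the union fraction is treated as the headline number.
Cross-segment sharing is the full 7-region Venn partition over
duodenum/jejunum/ileum, whose counts must (and are tested to) sum to
the union size.

Cluster integration consumes labels produced elsewhere. Proportions in
cluster distributions are over *assigned* cells carrying the clonotype
(matching how such figures are usually drawn); unassigned cells are
counted separately, never silently dropped.

## The synthetic-data generator

The generator emulates the structure of murine small-intestinal γδ IEL
repertoires so that every pipeline stage can be tested against planted
truth:

* γ V-gene usage ~50% TRGV7 (preset weights
  TRGV7 0.5, TRGV1/TRGV4/TRGV2/TRGV5/TRGV6 0.1 each);
* four co-dominant TRDV genes (TRDV2-2, TRDV5, TRDV6D-1, TRDV6D-2 at
  0.21 each, jointly 0.84) plus rare genes;
* heavy-tailed clone sizes (Zipf exponent 1 by default; lognormal and
  uniform laws available) with one public γ clone
  (TRGV7/TRGJ1, CASWAGYSSGFHKVF) pinned at 10% of chains;
* convergent recombination: each clone independently carries 2–3
  synonymous CDR3 nucleotide variants with probability
  `convergence_rate` (default 0.2), back-translated with uniformly
  random codon choices so variants are guaranteed to translate to the
  clonotype's amino-acid sequence; variant weights (0.7/0.3 or
  0.6/0.25/0.15) echo the ~70% dominant-variant fraction typical of
  public clones;
* pairing: each γ clone links to 1–3 δ partners with Dirichlet
  conditional weights (concentration 0.5 — strongly dominated by one
  partner, as observed for public γ chains); the true δ marginal is
  *induced* by this pairing and recorded in the truth record;
* ~60% of cells keep both chains (`paired_fraction_target`); the
  dropped chain is γ or δ with equal probability;
* nine transcriptome clusters whose labels are drawn per cell from the
  weight vector of the cell's γ/δ pairing (preset: each pairing prefers
  one cluster with weight 0.6), so pairing shapes the "transcriptome"
  as in the biology the package targets.

V and J genes are assigned to clones greedily against the target usage
weights in decreasing clone-frequency order, so realized chain-level
usage tracks the configured weights to within the largest clone
frequency — a plain independent assignment would leave usage dominated
by the random gene choice of a few large clones.

What the generator does **not** simulate: V(D)J recombination
mechanics, thymic selection, sequencing error, doublets, or any real
transcriptome. A green recovery test therefore establishes that the
pipeline's algebra is correct on data with this structure — not that
the biological conclusions of any particular experiment are right.

`calibrate_zipf_exponent(S, target_d1)` solves for the Zipf exponent
whose true exponential Shannon diversity equals a target, which is how
the acceptance suite builds worlds with true $D^1$ of exactly 250 and
150 (pool size $S = 400$, chosen so the resulting samples of 5000
chains have coverage above 0.99 — the regime in which a plug-in
estimate is expected within 5% of truth).

## Numerical choices and degenerate inputs

* All estimator seeds are explicit; derived seeds stay below $2^{31}$.
* Binomial-coefficient ratios are computed in log space (`lchoose`).
* `B = 1` is rejected (a replicate SD needs at least 2 values).
* An empty abundance vector is an error; a single-clone vector yields
  flat curves at 1 and complete coverage.
* Pipeline runs are byte-deterministic under fixed config and seed;
  the only volatile field is the manifest timestamp.
* Interpolation points beyond a sample's size abort the pipeline by
  default, naming the sample; `allow_small = TRUE` degrades $m$ to $n$
  with a note in the diversity table instead, for exploratory runs.

## Known limitations

* Hill numbers of general order, Simpson/Gini indices and
  repertoire-distance metrics (Morisita–Horn) are not provided.
* Convergent recombination is detected only within the CDR3 nucleotide
  string; V/J-segment nucleotide differences outside the junction are
  invisible in the input data. Whether multiple variants reflect
  independent rearrangements or expanded variant progenitors is not
  decidable from sequence alone, so the report exposes counts and lets
  the analyst interpret.
* Whether diversity "should" be computed on chains or cells coincides
  here because pairing resolves to one chain per locus per cell; data
  with unresolved multi-chain cells will differ slightly depending on
  upstream handling.
* The chi-squared usage test assumes independent chains; clonal
  expansion violates independence, so its p-values are descriptive,
  as is conventional in repertoire reports.
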