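---
title: "Ranking chromosomal duplication regions by intrinsic protein disorder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking chromosomal duplication regions by intrinsic protein disorder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the model

When a yeast culture meets a sudden, sustained heat shock, one of its fastest
evolutionary responses is segmental aneuploidy: duplicating a whole small
chromosome plus a couple of chromosomal fragments. `dupscan` implements a
biophysical account of *which* region gets duplicated. The working hypothesis
is that proteins with long intrinsically disordered regions are a liability at
high temperature, so the duplication that does the least damage — and dilutes
the disordered fraction of the proteome the most — is a region that is (a)
small enough to be affordable and (b) minimal in its content of long-disorder
proteins. The selection rule the package operationalises is deliberately
simple: *find a small enough chromosome with minimal protein disorder and
duplicate it, along with other fragments also depleted of disorder*.

The pipeline has five computational stages, each exposed as plain functions:

1. **Disorder calling** (`binarize()`, `call_protein()`, `disorder_calls()`).
   Per-residue predictor scores in $[0,1]$ are binarised at a cutoff and
   reduced to maximal-run statistics. A protein carries *long disorder* at
   threshold $T$ when it has $\ge T$ consecutive disordered residues;
   `%longT` of a protein set is the percentage of its proteins with that
   property. A protein is *completely disordered* when no 30-residue window
   is free of predicted disorder (equivalently, its longest fully ordered run
   is shorter than 30 residues).
2. **Chromosome composition** (`summarize_chromosomes()`), with a
   protein-resampling bootstrap for error bars.
3. **Fragment scan** (`enumerate_windows()`, `scan_percentile()`,
   `postdict()`, `disorder_delta()`). All continuous $k$-gene stretches
   within chromosomes are enumerated at step 1; a query region's `%longT` is
   ranked against every window of the same size; `postdict()` applies the
   selection rule under a gene budget.
4. **Term over-representation** (`expected_count()`, `hypergeom_pvalue()`,
   `bh_adjust()`, `term_enrichment()`, `composition_delta()`).
5. **Network comparison** (`build_graph()`, `largest_component()`,
   `node_features()`, `group_summary()`): degree, betweenness and average
   neighbor degree per protein, compared between chromosome groups.

A synthetic-genome generator (`synthetic_config()` and the `gen_*()`
functions) emulates every input with planted, parameterised structure, so the
whole pipeline is testable end to end without any external download.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| binarisation cutoff | 0.5 | score $\ge$ cutoff counts as disordered; 0.5 is the conventional operating point of IUPred-style predictors. The boundary is inclusive on both sides: score = cutoff is disordered, run length = $T$ is long. |
| run thresholds $T$ | 30, 50, 80 | residue run lengths defining "long" disorder; 30 is the focal statistic, the others are reported alongside. |
| bootstrap | 1000 reps, seed 42 | plain SD of `%longT` over resamples of the chromosome's proteins with replacement. The protein is the natural resampling unit because every downstream statistic counts proteins. |
| budget | caller-supplied | maximum gene count of the primary duplication; the workflow uses 160 genes, slightly above the planted 155-gene chromosome, mirroring a "small enough chromosome" constraint. |
| scan tie rule | inclusive $\le$ | a window counts as "as disorder-poor as the query" when its `%longT` is $\le$ the query's; the query's own window sits in numerator and denominator, so a minimal query gets a small but nonzero percentile. Windows are compared on integer flagged-protein counts, so ties are exact, never floating-point artifacts. |
| enrichment | upper tail, $q < 0.05$ | only over-representation is tested (exact hypergeometric, no normal approximation); depletion statements are made as composition deltas in percentage points, not as lower-tail tests. Terms without annotated background proteins are never tested; terms with zero observed members stay in the Benjamini–Hochberg correction but are hidden from reports by default. |
| betweenness scale | unnormalized | reported on the unordered-pair-count scale, which is the scale on which multi-thousand-node interaction networks are usually discussed; `normalized = TRUE` divides by $(n-1)(n-2)/2$. |

## What the generator emulates — and what it does not

Each synthetic protein's residues follow a two-state (ordered/disordered)
Markov chain. We parameterise it by the stationary disorder probability
$\pi$ and the lag-1 autocorrelation $\rho$ ("persistence"): the probability
of staying disordered is $\pi + \rho(1-\pi)$ and of staying ordered is
$(1-\pi) + \rho\pi$. This keeps the marginal disorder fraction and the run
lengths independently tunable; i.i.d. per-residue labels at realistic
disorder fractions almost never produce 30-residue runs, so a run-based
statistic needs run-length control in the generator. Note that a single
symmetric "keep state" probability could not do this: it would force
$\pi = 0.5$ regardless of the per-chromosome disorder level.

Defaults were fixed once by Monte Carlo before any downstream analysis:
$\pi = 0.15$, $\rho = 0.94$ gives roughly half of all proteins a
$\ge$30-residue disordered run — a realistic proteome-wide level for budding
yeast — and the planted chromosome's offset $\pi = 0.05$ drops that share to
roughly 20%, a gap wide enough that recovering the planted chromosome is a
fair test of the scan rather than of luck. The genome shape (16 chromosomes,
90–750 genes, lognormal protein lengths with mean 450 residues floored at
30) mimics the yeast nuclear genome; the interaction graph is Erdős–Rényi
with mean degree 12, the planted group's attachment probability scaled by
0.3 per planted endpoint; emitted scores are uniform on $[0.5, 1)$ for
disordered and $[0, 0.5)$ for ordered residues so that binarisation at 0.5
recovers the planted states exactly.

The generator does **not** emulate: non-uniform amino-acid composition or
any sequence–disorder coupling (scores are attached to positions, not
derived from residues); paralogy and the redundancy it creates (the
redundancy filter is exercised on constructed fixtures instead); hub-heavy
degree distributions of real interactomes; correlated or hierarchical
annotation terms beyond a single synthetic root; and any expression
response. Passing tests therefore demonstrate that the machinery is correct
and well calibrated, not that the biological conclusions transfer to any
particular real proteome — reanalysing the real system needs the actual
proteome, predictor outputs, interactome and annotations as inputs, which
the readers in `R/io_formats.R` accept in their standard formats.

## Numerical and procedural choices

* **Redundancy filter.** "100% pairwise identity, keeping the longer
  sequence" is implemented as exact-substring containment: identical
  sequences are the equal-length case, a length tie keeps the
  lexicographically smaller id, and candidates are visited longest-first so
  the survivor set is substring-free; output keeps input order. The filter
  is idempotent. Alignment-based identity thresholds below 100% are
  deliberately out of scope.
* **Gene coordinates.** Windows are defined on gene *order*, not base
  pairs; ordinals are 0-based per chromosome, assigned by ascending start
  with the protein id breaking ties. Strand is ignored throughout. Windows
  never span chromosomes; a chromosome with $n$ genes holds $n-k+1$
  windows of size $k$.
* **`postdict()` tie-breaks.** Primary region: lowest `%longT`, then fewer
  genes, then lexicographic label. Extra fragments: each requested size
  takes the minimum-`%longT` window outside the primary chromosome that
  does not overlap a previously chosen fragment, ties on (chromosome,
  start ordinal). These orders make the plan a deterministic function of
  its inputs.
* **Duplication delta.** Counting duplicated genes twice, the change in
  proteome `%long` has the closed form $(np + kq)/(n+k) - p$ for a proteome
  of $n$ genes at $p$ and a duplicated region of $k$ genes at $q$; the
  implementation is tested against that identity.
* **Short proteins.** A protein shorter than 30 residues cannot contain a
  fully ordered 30-residue window, so it is vacuously "completely
  disordered"; such calls carry a `short_protein` flag so reports can
  exclude them.
* **Standard statistical steps** ride on the stock implementations — exact
  hypergeometric tails via `stats::phyper`, Benjamini–Hochberg via
  `stats::p.adjust`, graph algorithms via `igraph` — and each is verified
  in the test suite against an independent brute-force oracle (exhaustive
  subset enumeration, the hand-written step-up recursion, all-simple-paths
  shortest-path counting).
* **Significance convention.** The FDR threshold is $q < 0.05$. One
  published description of this kind of analysis states the inequality the
  other way around; that reading is inconsistent with the correction
  procedure it cites, and the package follows the standard convention.

## Problem sizes used by the checks

The default test and acceptance runs use the default synthetic genome
(~5,900 genes, ~2.7M residues per seed) for the end-to-end recovery checks
over 20 seeds; brute-force oracle comparisons run on 100 random graphs of at
most 8 nodes, the full hypergeometric grid up to $N = 12$, and 1,000 random
label vectors; calibration uses 200 null selections of 150 genes and a
100-protein bootstrap fixture against the binomial closed form
$100\sqrt{p(1-p)/n}$. A scaled-down five-chromosome configuration backs the
fast unit tests.

## Known limitations

* The percentile convention for the scan (inclusive ties, query counted) is
  one of several defensible choices; with strict inequality the percentile
  of a uniquely minimal query would be $1/\text{windows}$ smaller.
* Betweenness "±" style comparisons between chromosome groups use
  SD/$\sqrt{n}$ as the standard error; centralities of proteins on one
  chromosome are not independent, so these bars understate uncertainty
  somewhat.
* The redundancy filter is quadratic in the worst case (every sequence
  checked against the concatenated survivors); at proteome scale (~6,000
  sequences) it runs in seconds, but it is not built for metagenome-scale
  inputs.
* Identifier spaces are taken verbatim: mapping interactome identifiers to
  proteome accessions is the caller's responsibility.
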