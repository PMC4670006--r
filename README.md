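# dupscan

Why does a heat-shocked yeast culture duplicate one particular chromosome
(plus two chromosomal fragments) and not another? `dupscan` implements, as a
tested R pipeline, a biophysical answer built on intrinsic protein disorder:
regions whose proteins are depleted of *long disordered regions* are the
cheapest to duplicate at high temperature, because duplicating them dilutes
the heat-labile disordered fraction of the proteome. The package is aimed at
computational biologists who want to re-run this style of analysis on their
own proteome, disorder predictions, interactome and annotations — or to
stress-test it end to end on the bundled synthetic-genome generator.

## What it computes

* **Long-disorder calls.** Per-residue predictor scores are binarised at a
  cutoff (default 0.5) and each protein is reduced to its maximal runs. A
  protein counts toward `%longT` when it has ≥ T consecutive disordered
  residues (T = 30, 50, 80); it is *completely disordered* when no
  30-residue window is free of disorder.
* **Chromosome composition.** `%longT` per chromosome with a
  protein-resampling bootstrap SE.
* **Fragment scan.** Every continuous k-gene stretch within a chromosome is
  enumerated and scored; a query region's percentile is the fraction of
  same-size windows genome-wide with `%longT` ≤ the query's.
* **Duplication selection** (`postdict`): among chromosomes fitting a gene
  budget, pick the one with minimal `%longT`; then pick extra fragments of
  requested sizes from other chromosomes, again minimising disorder. The
  proteome-wide effect of executing the plan is
  `Δ = (n·p + k·q)/(n + k) − p` percentage points for a proteome of `n`
  genes at `p` %long and a duplicated region of `k` genes at `q`.
* **Over-representation.** Expected class counts `K·n/N`, fold enrichment,
  exact hypergeometric upper-tail p-values `P[X ≥ k]`, Benjamini–Hochberg
  q-values, and composition deltas in percentage points.
* **Network comparison.** On the largest connected component of the
  interaction graph: degree, betweenness (unnormalized pair-count scale)
  and average neighbor degree per protein, summarised per chromosome as
  mean ± SE and median.
* **Synthetic data.** A seeded generator plants a low-disorder chromosome
  (two-state Markov disorder chain with tunable stationary probability and
  persistence), an enriched annotation term and a low-degree network group,
  and writes every input format the readers accept.

## Worked example

The `analysis/` scripts run the whole study on a synthetic genome
(16 chromosomes, ~5,900 genes, planted structure on `chr03`):

```sh
Rscript analysis/01_simulate.R 1     # write results/synthetic/
Rscript analysis/02_disorder.R
Rscript analysis/03_scan.R
Rscript analysis/04_enrichment.R
Rscript analysis/05_network.R
```

which prints, among other things:

```
proteome-wide %long30/50/80: 48.5 / 20.9 / 4.6
lowest %long30: chr03 at 22.6% (n = 155)

duplication plan (budget 160 genes, T = 30):
  primary: chr03 (155 genes, %long = 22.6)
  extra:   chr14[86..115) (29 genes, %long = 13.8)
  extra:   chr10[210..274) (64 genes, %long = 31.2)
fragment scan: chr03[0..155) k=155 T=30
  1 of 3549 windows have as little disorder (percentile 0.03%)
executing the plan would shift proteome %long30 by -0.99 pp

planted term T:PLANTED ranks 1 of 42 (q = 8.09e-35)
lowest mean degree: chr03 (3.9 +/- 0.2; planted group chr03)
```

Reading: the planted low-disorder chromosome is the unique 155-gene region
with minimal long-disorder content genome-wide (percentile 0.03% of all
same-size fragments), the selection rule recovers it from the budget alone,
executing the duplication would dilute proteome-wide `%long30` by about one
percentage point, the planted annotation term tops the enrichment table, and
the planted group has the lowest mean interaction degree. The same functions
accept real inputs: a proteome FASTA (`read_fasta` + `dedup_proteome`),
IUPred-style score tables (`read_disorder_scores`), a gene map
(`read_genome_map`, TSV or GFF3), a tab-delimited interaction list
(`read_edges`) and GAF/OBO annotations (`read_annotations`).

## Package layout

`R/` implementation (readers, disorder metrics, fragment scan, enrichment,
network features, synthetic generator, pipeline driver `run_pipeline()`);
`analysis/` numbered workflow scripts; `tests/testthat/` unit, property and
acceptance suites with independent brute-force oracles;
`vignettes/dupscan-methods.Rmd` the methods notes (model, parameters,
generator scope, numerical choices, limitations).
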