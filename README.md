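# scTransition

Critical-transition (tipping-point) analysis for single-cell RNA-seq time
courses, in R.

## The problem

When a cell population moves between two attractor states — for example
heart muscle cells maturing from a neonatal to an adult expression program —
the intermediate is not a third stable state but an unstable transition.
Marker genes are ambiguous there, because both programs are partially
active. What does change, characteristically, is correlation structure: as
the old attractor loses its grip, cells fluctuate more independently of one
another (cell–cell correlation drops) while genes fluctuate more coherently
along the destabilizing direction (gene–gene correlation rises).

The transition index summarizes this as

    I_C(t) = ⟨ |R(g_i, g_j)| ⟩ / ⟨ |R(S_k, S_l)| ⟩

where the numerator is the mean absolute Pearson correlation over all
unordered gene pairs at time t and the denominator the mean (absolute)
Pearson correlation over all unordered cell pairs. I_C peaks at the critical
transition time point.

`scTransition` implements the full quantitative pipeline around that
statistic:

- **Quality filtering and normalization** — minimum-detected-genes and
  two-sided log10-UMI outlier cell filters; gene prevalence filter (≥ 10
  cells); mitochondrial gene exclusion; TPM-like normalization
  `ln(1 + count/total × 10,000)`; an RLE batch diagnostic on housekeeping
  genes.
- **Transition metrics** — per-time-point cell–cell and gene–gene Pearson
  matrices, I_C(t), trend summaries.
- **Marker detection** — two-sided Wilcoxon rank-sum tests with
  detection-fraction (`min.pct = 0.2`) and log-fold-change (0.2; 0.58 for
  block comparisons) filters and Benjamini–Hochberg q-values.
- **Stage-specific TF bifurcation** — per-cell products of one early-stage
  TF and one late-stage TF ("TF values"); elevated when both programs are
  half-on, i.e. at the transition.
- **Cluster matching** — Jaccard similarity of cluster signature-gene sets
  across datasets, with best-match reporting.
- **Ligand–receptor communication** — CellPhoneDB-style interaction scoring
  (mean of sender-cluster ligand and receiver-cluster receptor expression)
  with a cluster-label permutation null, top-20 ranking by mean expression,
  and between-condition delta classification at ±0.4.
- **Synthetic data** — a negative-binomial two-attractor UMI time-course
  generator with a broadened latent-state distribution at the transition, so
  every statistic has a parameter-recovery test against known truth.

## Worked example

```r
library(scTransition)

sim    <- simulate_time_course(sim_config(seed = 1))
pp     <- preprocess(sim$counts, gene_annotation = sim$genes, min_genes = 98)
series <- transition_index(split_by_time(pp$normalized, sim$cells))
print(as.data.frame(series)[, 1:6], digits = 3)
#>   time_point n_cells n_genes mean_cell_cell mean_abs_gene_gene    ic
#> 1         t0     189     160          0.720             0.0918 0.128
#> 2         t1     189     160          0.268             0.0685 0.255
#> 3         t2     190     160          0.250             0.3116 1.246
#> 4         t3     190     160          0.260             0.0663 0.255
#> 5         t4     194     160          0.718             0.0931 0.130
correlation_trend_summary(series)$ic$extremum
#> [1] "t2"
```

The generator plants its transition at the middle time point (index 2 of 5):
cell–cell correlation is lowest there (0.250 vs ~0.72 at the stable
endpoints), mean absolute gene–gene correlation is highest (0.31 vs ~0.07),
and I_C peaks at 1.25 — an order of magnitude above the stable time points —
recovering the planted tipping point. (`min_genes = 98` scales the
paper-scale 500-detected-genes floor to the ~200-gene synthetic world; see
the methods vignette.)

## Command line

```sh
inst/scripts/sctransition simulate --seed 1 --out-dir sim
inst/scripts/sctransition transition-index --matrix sim/matrix.mtx \
    --annotation sim/cells.tsv --out series.csv
inst/scripts/sctransition run-all --seed 1 --out-dir run
```

Subcommands: `simulate`, `preprocess`, `transition-index`, `markers`,
`tf-pairs`, `match-clusters`, `lr-delta`, `run-all`.

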