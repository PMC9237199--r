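---
title: "Detecting critical transitions in single-cell time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting critical transitions in single-cell time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scTransition)
```

## The model

A maturing cell population is treated as moving between two attractors of a
gene-regulatory dynamical system: an early program (call it A) and a late
program (B), mutually antagonistic. At stable times, each cell sits near one
attractor; expression fluctuations are dominated by cell-autonomous noise,
so cells resemble one another (high cell–cell correlation) while genes
fluctuate largely independently (low gene–gene correlation). Approaching a
critical transition, the restoring force of the old attractor weakens:
cells spread out along the unstable direction, so cell–cell correlation
falls, while genes co-vary along that direction, so gene–gene correlation
rises. The transition index condenses this:

$$I_C(t) = \frac{\langle |R(g_i, g_j)| \rangle}{\langle |R(S^k, S^l)| \rangle}$$

with Pearson correlations computed on natural-log TPM-like expression, the
numerator averaged over all unordered distinct gene pairs and the
denominator over all unordered distinct cell pairs at time $t$. $I_C$ peaks
at the tipping point.

Two further read-outs corroborate a transition. Per-cell products of one
early-stage and one late-stage transcription factor's expression ("TF
values") are near zero at stable times (one factor is off) and maximal when
both programs are half-active, which for a latent state $s \in [0,1]$ means
the product term $s(1-s)$ peaks at $s = 0.5$. And ligand–receptor
communication between clusters is scored as the mean of the sender cluster's
ligand and the receiver cluster's receptor expression, tested against a
cluster-label permutation null, with condition contrasts classified by a
±0.4 shift of the per-pair mean expression.

## Numerical conventions

- **Denominator absolute value.** The defining ratio is stated in the
  literature with the denominator written without absolute bars but
  described in words as an absolute value. We take absolute values in both
  numerator and denominator by default; `signed_cell_corr = TRUE` reproduces
  the literal signed denominator. On log-normalized expression negative
  cell–cell correlations are rare, so the two agree in practice, but the
  choice is explicit and recorded in the output.
- **Common gene universe.** $I_C(t)$ values are only comparable across time
  points if computed over one gene set; we use the intersection of genes
  present at all time points, restricted to genes with nonzero variance at
  every time point. Excluded genes and zero-variance cells are counted and
  reported — Pearson is undefined for constant vectors and silent NaN
  propagation is forbidden.
- **Normalization pseudocount.** The source procedure says only
  "transformed to natural logarithm"; zero counts force a convention. We use
  $\ln(1 + x)$, the convention of the single-cell framework the procedure
  derives from, recorded in the `pseudocount_convention` field. This yields
  the per-cell invariant $\sum_g (e^{v_{gc}} - 1) = 10{,}000$, which the
  tests assert to $10^{-6}$.
- **Wilcoxon rank-sum.** Exact enumeration of all rank assignments when
  $n_a + n_b \le 12$ with no ties; otherwise the normal approximation with
  midrank tie correction and continuity correction. Benjamini–Hochberg
  q-values are computed over the genes actually tested within each
  contrast, mirroring the cited framework (a known deviation risk relative
  to correcting over all genes; the `tested` column makes the universe
  explicit).
- **Log fold change** is natural-log on the de-logged mean scale,
  $\ln(\overline{e^x - 1} + 1)$ differences, so the 0.2 and 0.58 thresholds
  carry their conventional meaning.
- **Permutation p-values** use the plain fraction of permuted statistics at
  or above the observed one, with one shared set of label permutations per
  call (as CellPhoneDB does), making p-values marginally uniform but
  correlated across pairs. Seeds make every run reproducible.
- **Ties in best-match reporting** (cluster similarity, trend extrema) are
  reported as ties, never broken silently.

## Key tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_genes` | 500 | minimum detected genes per cell (inclusive) |
| `umi_sd` | 2 | half-width of the log10-total-UMI outlier band |
| `min_cells` | 10 | minimum cells a gene must be detected in (inclusive) |
| `size_factor` | 10,000 | scale of the per-cell count fraction |
| `min_pct` | 0.2 | detection fraction required in either group |
| `logfc_threshold` | 0.2 | marker pre-filter on \|lnFC\| |
| `block_logfc` | 0.58 | additional \|lnFC\| filter for block comparisons |
| `q_threshold` | 0.05 | BH significance level |
| `detection_floor` | 0.1 | in-cluster detection floor for LR scoring |
| `top_n` | 20 | LR pairs retained per condition |
| `lr_threshold` | 0.4 | delta classification half-width |

The filters are applied in a fixed, documented order — cells first (both
cell criteria evaluated on the input matrix before any removal), then
mitochondrial exclusion and gene prevalence on the surviving cells. Order
invariance is deliberately *not* claimed; the order is part of the contract
and tested.

## What the synthetic generator emulates — and what it does not

`simulate_time_course()` draws, for each cell at time $t$, a latent state
$s_c \sim \mathrm{Beta}(a_t, b_t)$ whose mean interpolates
$0.05 \to 0.5 \to 0.95$ across time points, with a tight concentration
(`stable_beta = 30`) at stable times and a broad symmetric
$\mathrm{Beta}(0.8, 0.8)$ at the transition time point (default index 2
of 5). Program-A genes have mean $\mu(1 - s_c)$, program-B genes
$\mu s_c$ ($\mu$ = `base_mean` = 50), housekeeping genes $\mu$, and 37
mitochondrial genes $0.05\mu$; means are multiplied by per-cell×gene
log-normal noise (sd 0.3) and a log-normal library factor (sigma 0.3), and
counts are drawn $\mathrm{NB}(\text{mean}, \text{size}=2)$, with a Poisson
limit at infinite size. Defaults give 200 cells per time point and a
160-gene post-QC universe (60 + 60 program + 40 housekeeping).

This emulates: UMI over-dispersion, library-size variation, antagonistic
programs, a broadened state distribution at the tipping point, and
low-level mitochondrial background. It deliberately does **not** emulate:
batch or chip effects, doublets, ambient RNA, gene-length or
capture-efficiency biases, or more than two attractors. A green recovery
test therefore establishes that the statistics recover a planted two-
attractor transition under realistic count noise — not that they are robust
to artifacts the generator does not contain.

`simulate_condition_pair()` builds the communication fixture: a sender
("CM") and a receiver ("NCM") cluster under two conditions, each
ligand expressed only in the sender and each receptor only in the receiver
(cluster-exclusive by construction — partial off-home expression near the
10% detection floor makes combination significance flip between conditions
and is exactly the instability the fixture must not have), background genes
exchangeable between conditions, and a stated fold multiplying chosen
ligand means in the second condition.

## Design choices where the design was open

- **QC floor on synthetic data.** The 500-detected-genes floor presumes a
  ~20,000-gene transcriptome; the synthetic universe has ~200 genes, so
  applying it literally removes every cell. Synthetic-world runs scale the
  floor to half the gene universe (98 by default); real-data paths keep
  500. No other threshold is rescaled.
- **Gene set for gene–gene correlation.** Whether the original analysis
  used all genes or a variable subset is unstated; default is all post-QC
  genes common to all time points, overridable via `gene_set`.
- **TF selection for the bifurcation panel** applies only the stated
  p < 0.05 rank-sum criterion between the terminal stages (no pct/logFC
  pre-filters), configurable.
- **TF values** are products of normalized log expression (the matrix the
  rest of the pipeline uses), not raw counts; "expressed" means a value
  greater than zero (count ≥ 1). The per-time bifurcation report exposes
  mean, median and upper decile of pooled TF values plus co-expression and
  exclusive-expression fractions, rather than committing to a single
  unstated summary.
- **Signature sets** for cluster matching take positive (identity) markers
  passing all filters, capped at the top 100 by q-value; the cap is
  configurable since the original work states none.
- **LR pairs selected in only one condition** are kept in the delta table
  with the missing side counted as 0 and flagged, since the contrast panel
  displays such pairs.
- **Null-calibration denominator.** The marker-calibration property counts
  significant genes over all genes in a contrast; over tested genes only,
  the pre-filter's selection of extreme genes under the null inflates the
  ratio — a property of the pre-filter, not of the test.

## Degenerate inputs and edge behavior

Empty filter results, all-zero cells at normalization, fewer than two
usable cells or genes after zero-variance exclusion, empty signature sets,
a missing ligand or receptor gene, `n_perm = 0`, and identical condition
labels all raise named errors early. Boundary cases are inclusive where the
stated thresholds say "minimally"/"at least": exactly 500 detected genes is
kept, detection in exactly 10 cells is kept, a cell exactly at
mean ± 2 sd of log10 UMI is kept.

## Known limitations

- $I_C$ is a descriptive index; no significance test for its peak is
  provided (none exists in the source procedure).
- Permutation p-values share permutations within a call, so they are
  correlated across pairs; family-wise corrections across pairs are out of
  scope.
- The marker module's BH universe (tested genes per contrast) follows the
  cited framework and is not a family-wise guarantee over all genes.
- Cluster matching uses marker-set overlap only; it cannot distinguish
  clusters whose identity genes coincide.
- Sampling-time labels must be supplied with their total order; nothing is
  inferred from label strings.
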