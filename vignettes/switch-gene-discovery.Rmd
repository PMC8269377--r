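---
title: "Switch-gene discovery by co-expression network cartography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Switch-gene discovery by co-expression network cartography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchflow)
```

## The method

Switch genes are candidate drivers of a transition between biological states
— here, between a healthy and a disease transcriptome. They are defined
purely topologically, on a gene co-expression network built from case and
control samples pooled together:

1. **Pre-processing.** Genes that are unexpressed (mean linear expression
   below a percentile of all gene means, default 10) or constant are removed.
2. **Filtering.** Per-gene Welch *t*-tests on log2 values compare cases with
   controls; Benjamini–Hochberg (BH) adjustment controls the false discovery
   rate. A linear fold-change cutoff is scanned over a band (default 1.5–4 in
   steps of 0.1) and the smallest cutoff whose selected set (|signed fold
   change| above the cutoff *and* q below `fdr_alpha`) contains a target
   number of genes (default 1000–2000) is kept.
3. **Network.** Pearson correlations between all pairs of selected genes
   (log2 scale, all samples) define an undirected signed network: an edge is
   kept when |r| is at least `corr_threshold` (default 0.7). Anti-correlation
   is as much a connection as correlation.
4. **Communities.** Gene expression profiles (z-scored) are clustered by
   k-means for each k in a range (default 2–10), each with seeded restarts,
   keeping the lowest sum of squared errors (SSE) per k; the number of
   communities is picked from the scree of minimal SSEs.
5. **Cartography.** Every node gets three coordinates:
   * within-module degree z-score `Zg = (kappa - mean_module) / sd_module`,
     where `kappa` is the number of edges into the node's own community;
   * clusterphobic coefficient `Kpi = 1 - (kappa / k)^2`, near 1 when most
     links leave the community;
   * average Pearson correlation coefficient (APCC): the mean correlation
     between the node and its network neighbours.
   Nodes with `Zg > 5` are hubs. By APCC, nodes are date hubs (0 ≤ APCC <
   0.5), party hubs (APCC ≥ 0.5) or fight-club hubs (APCC < 0). The
   `(Kpi, Zg)` plane is divided into seven regions R1–R7 (non-hub boundaries
   at Kpi = 0.05, 0.62, 0.80; hub boundaries at 0.30, 0.75).
6. **Switch genes** are the fight-club nodes that are not hubs of their own
   community and connect mostly outside it:
   `Zg < 2.5`, `Kpi > 0.8`, `APCC < 0` — region R4 of the plane.

Downstream, the package re-runs the pipeline per sex with fixed per-stratum
fold-change cutoffs, computes Welch/BH contrast tables (male cases vs
controls, female cases vs controls, male vs female cases) with the
signed-ratio fold-change convention, decomposes overlaps between gene sets
from different runs, tests switch lists for over-representation in gene-set
collections (upper-tail hypergeometric with BH), extracts minimum connected
subnetworks in regulator–target tables, and ranks transcription factors or
chemicals by degree and betweenness centrality.

## Tunable parameters

All thresholds live in `swim_config()`:

| parameter | default | meaning |
|---|---|---|
| `fc_min`, `fc_max` | 1.5, 4 | linear fold-change scan band |
| `target_gene_min/max` | 1000, 2000 | target size of the filtered set |
| `fdr_alpha` | 0.05 | BH q threshold in filtering |
| `corr_threshold` | 0.7 | minimum \|r\| for an edge |
| `k_min`, `k_max` | 2, 10 | community counts tried |
| `kmeans_replicates` | 20 | seeded restarts per k |
| `hub_zg` | 5 | hub threshold on Zg |
| `switch_zg`, `switch_kpi` | 2.5, 0.8 | switch thresholds |
| `apcc_party` | 0.5 | date/party APCC boundary |
| `low_expr_percentile` | 10 | pre-processing percentile |
| `fc_fixed` | unset | fixed cutoff bypassing the scan |

Several of these are not dictated by the method's description and are the
package's own documented choices: the test statistic (Welch on log2 values),
the FDR procedure (BH), the 0.1 scan granularity with a smallest-passing-
cutoff tie-break, the fixed `corr_threshold` of 0.7 (with
`select_corr_threshold()` offering a density-bounded alternative that scans
0.50–0.95 for edge density ≤ 0.05), the 10% scree elbow tolerance, the
`Kpi = 1 - (kappa/k)^2` functional form, the 0.5 date/party boundary, and
the standard seven-region boundaries of the cartography plane, of which only
R4's role is pinned by the method. Degenerate cases are made total by
convention: a module with zero internal-degree spread gives `Zg = 0`
(the node is typical of its module); isolated nodes get `Kpi = 0`,
`APCC = 0` and hub class `none`; a t-test on constant data falls back to
p = 1 when the means agree and 0 when they differ; undefined elbow
(no drop below tolerance) selects `k_max`.

Two thresholds deliberately coexist: hubs require `Zg > 5` while switch genes
require `Zg < 2.5`, leaving an intermediate band of nodes that are neither.
Both are exposed in the configuration rather than reconciled.

## What the simulator emulates

`generate_dataset(sim_config())` plants ground truth for every downstream
claim. Per module *m*, sample *j*:

* a global module factor `f_m ~ N(0,1)` and a smooth within-module gradient
  `c_{m,i}` (AR(1) across gene positions, autocorrelation 0.9) generate the
  `i`-th regular gene as `baseline + alpha f_m + beta c_{m,i} + noise`, with
  `alpha^2 + beta^2 = 0.8` (the adjacent-gene correlation) split 75/25
  between factor and gradient, and noise sd 0.45. The gradient gives modules
  the banded, partly sparse topology of real co-expression blocks rather
  than a clique — distant same-module genes share only the global factor —
  so that node removal can actually lengthen paths in the robustness
  analysis.
* planted switch genes load negatively and strongly (squared loading 0.95)
  on their own module's factor: their neighbours anti-correlate (negative
  APCC), k-means places them outside the module whose genes they connect to
  (high Kpi, low Zg), and they act as block-wide shortcuts.
* differential genes (60% of each module's regular genes, plus every switch
  gene) receive a case-only additive log2 shift. Directions are
  module-coherent (co-expressed genes are co-regulated), with switch genes
  shifted against their module. Magnitudes are uniform over the 1.5–4×
  band for regular genes and over a narrower 2.2–2.8× mid-band for switch
  genes, so the planted switch genes reliably survive the 1.5 fold-change
  filter — the method's stated premise.
* per-patient response heterogeneity: the shift of gene *g* in case *j* is
  `d_g (1 + 0.5 z_{gj})`. Besides being realistic for heterogeneous
  cohorts, this keeps the case/control shift from acting as a global latent
  factor; without it, unrelated differential genes in different modules
  acquire spurious correlations near the edge threshold and chance
  cross-module bridge edges dominate the robustness curves.
* sex effects: six non-differential genes get a sex main effect (3×), the
  first an XIST-like gene with extreme female-biased expression (30×),
  exercising the sex-contrast path. Sexes alternate within cases and
  controls.

The simulator does **not** emulate probe-level microarray noise, batch
effects, missing values, unbalanced designs, or correlated noise between
modules. Passing tests therefore demonstrate that the implementation
recovers the structure the method presumes when that structure is present;
they say nothing about robustness to normalization artifacts or confounding
in real cohorts.

## Study conditions used by the tests and the acceptance script

Simulated datasets are 4 modules × 60 genes × 60 samples (30 cases, 30
controls). Pipeline runs on them use `sim_run_config()`: identical to the
defaults except the filtering scan targets 100–200 genes, the same retained
fraction the 1000–2000 window represents on a genome-wide array, scaled to
240 genes. Recovery of the 8 planted switch genes is scored over 20
simulation seeds (recall and precision of the detected list), the robustness
comparison contrasts switch-targeted with random node removal at 20% of
nodes (random averaged over 10 shuffles, step 0.1), and false-discovery
control is checked on 1000-gene null matrices. The null FDR fraction is
typically far below the nominal 0.05 because the fraction counts BH-adjusted
q-values, not raw p-values.

## Known limitations

* Correlation-thresholded networks at |r| ≥ 0.7 are nearly disconnected
  between modules; the average shortest path is measured within the largest
  connected component and can jump when removal changes which component is
  largest. The robustness comparison is therefore reported as a mean over
  seeds.
* The per-gene Welch test does not share variance information across genes;
  moderated statistics, paired designs and covariate adjustment are out of
  scope.
* Expression scale is declared by the caller, never sniffed; linear input is
  log2-transformed with a +1 offset for tests and correlations.
* The enrichment module is a local stand-in for web-service analyses: a
  standard upper-tail hypergeometric over-representation test against a
  user-supplied collection, with the measured background (genes surviving
  pre-processing) as the recommended universe. No claim is made of matching
  any external service's statistics.
* The command-line wrapper (`inst/cli/switchflow.R`) is a thin veneer over
  the exported functions; the functions themselves are the supported
  interface.
```{r}
d <- generate_dataset(sim_config(seed = 1))
res <- run_pipeline(d$expr, d$pheno, sim_run_config(seed = 1),
                    robustness = FALSE)
res
```
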