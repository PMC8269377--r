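# switchflow

Switch-gene discovery in gene co-expression networks.

In diseases such as amyotrophic lateral sclerosis, the transition from a
healthy to a pathological transcriptome is thought to be driven by a small
set of **switch genes**: genes that are not hubs inside their own
co-expression community, whose links point mostly *outside* that community,
and whose expression is *anti-correlated* with their interaction partners.
`switchflow` implements the full discovery pipeline for case/control
expression matrices (microarray or RNA-seq, linear or log2 scale) and is
aimed at transcriptomics researchers who want a scripted, reproducible,
testable version of this analysis — including sex-stratified reruns,
contrast tables, over-representation analysis, and regulator ranking.

## The method in brief

From a gene × sample matrix and a case/control phenotype table:

1. drop unexpressed and constant genes;
2. per-gene Welch *t*-tests (log2 scale) with Benjamini–Hochberg FDR; scan
   linear fold-change cutoffs over [1.5, 4] and keep the smallest cutoff
   selecting a target number of genes (1000–2000 at genome scale);
3. build the signed Pearson co-expression network over the selected genes
   (edge iff |r| ≥ 0.7, cases and controls pooled);
4. find communities by replicated k-means on z-scored profiles, choosing k
   from the scree of minimal SSE values;
5. place every node on the heat cartography plane:

   * `Zg` — within-module degree z-score,
     `Zg_i = (κ_i − ⟨κ⟩_module) / sd(κ)_module`;
   * `Kπ` — clusterphobic coefficient, `Kπ_i = 1 − (κ_i / k_i)²`;
   * `APCC` — average Pearson correlation between node *i* and its network
     neighbours;

   hubs have `Zg > 5`; fight-club hubs have `APCC < 0`;
6. extract **switch genes**: `Zg < 2.5`, `Kπ > 0.8`, `APCC < 0`
   (region R4 of the plane).

The package also computes network robustness curves (average shortest path
under targeted vs random node removal), biclustering orders for switch-gene
heat maps, per-sex pipeline runs with fixed fold-change overrides
(e.g. 1.5 for males, 2.5 for females), Welch/BH sex contrasts with the
signed-ratio fold-change convention, exact Venn-style set overlaps,
hypergeometric over-representation analysis against GMT collections, minimum
connected subnetworks in regulator→target tables, and degree/betweenness
ranking of transcription factors or chemicals.

A synthetic-data generator (`generate_dataset()`) plants modular
co-expression structure, switch genes, differential effects and sex effects
with full ground truth, so every stage of the pipeline is testable.

## Worked example

```r
library(switchflow)

d <- generate_dataset(sim_config(seed = 1))   # 4 modules x 60 genes, 30+30 samples
d$expr
#> expression_matrix: 240 genes x 60 samples (log2 scale)

res <- run_pipeline(d$expr, d$pheno, sim_run_config(seed = 1))
res
#> pipeline_result: 123 genes selected at fold change 1.5, 4 modules (k-means),
#>   8 switch genes: gene_0001, gene_0002, gene_0122, gene_0121, gene_0182, gene_0062, gene_0061, gene_0181

planted <- d$truth$gene[d$truth$is_switch]
mean(planted %in% res$switch_genes)   # recall
#> [1] 1
mean(res$switch_genes %in% planted)   # precision
#> [1] 1

head(subset(res$cartography, is_switch,
            select = c(gene, module, degree, internal_degree, zg, kpi, apcc)))
#>         gene module degree internal_degree        zg       kpi       apcc
#> 1  gene_0001      1     33               1 -1.060660 0.9990817 -0.7370038
#> 2  gene_0002      1     33               1 -1.060660 0.9990817 -0.7323876
#> 36 gene_0061      3     11               1 -2.061764 0.9917355 -0.5954457
#> 37 gene_0062      3     12               1 -2.061764 0.9930556 -0.6051469
#> 62 gene_0121      1     27               1 -1.060660 0.9986283 -0.6948813
#> 63 gene_0122      1     34               1 -1.060660 0.9991349 -0.7254428
```

Reading the cartography rows: each detected switch gene has almost all of
its links outside its assigned community (`Kπ` near 1), a below-average
internal degree (`Zg < 2.5`), and negative average co-expression with its
neighbours (`APCC < 0`) — the three-part topological signature the pipeline
selects for. Here all 8 planted switch genes are recovered with no false
positives.

Sex-stratified analysis with the fixed per-sex cutoffs:

```r
strat <- stratify_and_run(d$expr, d$pheno, sim_run_config(seed = 1),
                          fc_override = c(M = 1.5, F = 2.5))
strat$M$fc_cutoff   # 1.5
strat$F$fc_cutoff   # 2.5
```

## Command-line use

```sh
Rscript inst/cli/switchflow.R simulate --seed 1 --out sim
Rscript inst/cli/switchflow.R run --expr sim/expression.tsv \
    --pheno sim/phenotypes.tsv --scale log2 --seed 1 --out out
Rscript inst/cli/switchflow.R run --expr sim/expression.tsv \
    --pheno sim/phenotypes.tsv --stratify-by sex --fc-override M=1.5,F=2.5 \
    --out out_by_sex
```

See `vignettes/switch-gene-discovery.Rmd` for the model, the simulator's
assumptions, and every numerical convention.
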