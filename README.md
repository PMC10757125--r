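# pononet

Differential co-expression network analysis of treatment response, with
prognostic evaluation of the resulting gene modules.

## The problem

In a cohort treated with the same drug, some patients respond and some do
not. Differential *expression* finds genes whose level differs between the
two groups; differential *co-expression* finds gene **pairs** whose
coordination differs — tightly correlated in one clinical state, uncoupled
or anti-correlated in the other. Such rewiring marks regulatory programs
active in only one state, and the highly connected genes of the rewired
networks are candidate response biomarkers. `pononet` is for
transcriptomics / systems-biology analysts who have a log2 expression
matrix with response vs. nonresponse labels (optionally two cohorts), and
who want the full chain from differential expression to prognostic
scoring of network modules, with every stage testable against planted
ground truth.

## The method

1. **Differential expression.** Per gene, an empirical-Bayes moderated
   t-test: posterior variance
   `s̃²_g = (d₀s₀² + d·s²_g)/(d₀ + d)` with the prior `(d₀, s₀²)`
   estimated from the marginal distribution of the gene variances;
   Benjamini–Hochberg FDR control; DEG calls at adjusted p < 0.05 and
   fold change ≥ 1.5. Two cohorts are intersected to a mutual DEG
   universe.
2. **Pair classification.** For every DEG pair, Pearson correlations
   r_resp and r_non within each phenotype. A pair is differentially
   co-expressed when a four-way pattern holds at threshold τ = 0.7
   (`PO`: positive in response / none in nonresponse; `NO`: negative /
   none; `OP`, `ON`: the mirror classes) **and** the relative-difference
   ratio `|(r_resp − r_non)/r_resp| ≥ 1` (zero denominators guarded).
3. **Networks and hubs.** `PO∪NO` edges form the response network
   (PONO), `OP∪ON` the nonresponse network (OPON). Hub modules are the
   genes ranking high on both degree and (Brandes) betweenness
   centrality, truncated to five genes by default; exportable as
   SIF/GraphML.
4. **Regulators and enrichment.** TF→target tables overlay regulators on
   each network (ranked by in-network coverage); hypergeometric
   over-representation against a user GMT with the measured genes as
   universe.
5. **Prognosis.** For a survival cohort: joint Cox fit on the module
   genes (Efron ties), per-sample prognostic index `PI = Σ βg·xg`,
   median split into low/high risk, Kaplan–Meier curves, log-rank test,
   and the high-vs-low hazard ratio with 95% CI.

A synthetic-data module (`simulate_expression()`, `simulate_survival()`,
`simulate_tf_table()`, `simulate_study()`) plants mean-shift DEGs,
compound-symmetry correlation blocks switched on in one condition, and
exponential survival driven by module genes — so recovery, calibration
and null behaviour are all measurable.

## Worked example

The one-command demo generates the emulated two-cohort study (53 samples
at 9/44 response/nonresponse, 26 at 13/13, 2000 genes), writes it to
disk, and runs the whole pipeline:

```r
library(pononet)
summary <- run_demo(seed = 7)
#> Synthetic study demo
#>   DEGs datasetA: 51 up, 52 down
#>   DEGs datasetB: 53 up, 54 down
#>   mutual DEGs: 100
#>   network PONO: 9 genes, 9 edges
#>   network OPON: 5 genes, 8 edges
#>   module PONO: G00003, G00001, G00004, G00005, G00002
#>   module OPON: G00009, G00010, G00006, G00008, G00007
#>   top TFs PONO: TF_M1
#>   top TFs OPON: TF_M2
#>   prognosis PONO: HR = 2.66, log-rank p = 2.8e-09
#>   prognosis OPON: HR = 1.40, log-rank p = 0.041
```

Reading the output: both cohorts recover ≈ 50 up- and 50 down-regulated
planted DEGs and all 100 mutual DEGs; the classified pairs assemble into
a response network and a nonresponse network whose 5-gene hub modules are
exactly the planted blocks (`G00001–G00005` and `G00006–G00010`); the
planted master regulators rank first in each network; and the response
module — the only one with planted survival signal — separates risk
groups sharply (HR 2.66), while the nonresponse module behaves as the
built-in negative control. Individual stages are ordinary functions on
data frames (`diff_expression()`, `condition_correlations()`,
`build_differential_edges()`, `assemble_networks()`, `rank_hubs()`,
`evaluate_prognosis()`, ...) returning tibbles or tidy-able objects, with
`autoplot()` methods for Kaplan–Meier curves and module correlation
heatmaps.

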