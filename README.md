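# CADregulome

Integrative promoter-regulome analysis for coronary artery disease (CAD)
biomarker pathways.

Serum biomarkers of CAD — interleukins, coagulation factors, adhesion
molecules, heat-shock proteins and others — are differentially regulated
across seven pathophysiological pathways (inflammation, coagulation, cell
adhesion, obesity, oxidative stress, stress, renal function). This package
asks the upstream question: which transcription factors (TFs) could drive
that joint regulation? It implements the full pipeline from promoter
sequence to regulatory network, for bioinformaticians who want a
transparent, testable version of an analysis usually delegated to
proprietary promoter-scanning services:

1. **Matrix scoring and scanning** (`scoringMatrix`, `scanPromoter`).
   A position frequency matrix *f(b, i)* is weighted by its per-position
   conservation vector

   *ci(i) = (100 / ln 4) (Σ_b f(b, i) ln f(b, i) + ln 4)*,

   0 for a uniform position and 100 for an invariant one. A promoter
   window *w* scores the matrix similarity

   *mss(w) = Σ_i ci(i) f(w_i, i) / Σ_i ci(i) f_max(i)*,

   and the core similarity *css* is the same ratio restricted to the most
   conserved contiguous window (default 4 positions). Both strands are
   scanned; hits are windows with *css* ≥ `cssMin` and *mss* ≥ `mssMin`,
   reported in forward 0-based half-open coordinates.
2. **Regulome set algebra** (`tfTotals`, `pathwayCounts`, `coreTFs`,
   `groupBySignature`). Hits become a TF × gene `BindingCountMatrix`;
   per-TF, per-family and per-pathway totals identify *core* regulators
   (binding every biomarker, or at least one biomarker of every pathway),
   pathway-specific regulators, and *combinatorial* groups of TFs sharing
   a pathway signature.
3. **Expression evidence** (`quantileNormalize`, `welchTTest`,
   `differentialExpression`, `expressedTfFilter`). Two-group microarray
   data are quantile normalized and tested gene-by-gene with Welch's
   *t*; predicted TFs are split into expressed / not significant / not
   assayed. Protein biomarker panels contribute case/control fold changes
   (`foldChange`).
4. **Network modules** (`buildRegulomeNetwork`, `extractModules`).
   A typed TF–biomarker graph with binding-count `regulates` edges and
   Jaccard-weighted `co_regulates` / `co_targeted` edges yields connected
   biomarker modules that span multiple pathways, each annotated with its
   dominant regulators.
5. **Synthetic data with ground truth** (`generatePwmLibrary`,
   `generatePromoters`, `generateExpression`, `generateProteinLevels`).
   Fully seeded generators plant exact consensus occurrences (counts,
   positions and strands recorded) in rejection-sampled motif-free
   background, plant differential expression shifts and protein fold
   changes, so every stage of the pipeline can be validated against known
   truth.

The package also ships `coreTfBindingCounts()`: a curated 5 × 31
binding-site count matrix for the five core CAD regulators PPARG, EGR1,
ETV1, KLF7 and ESRRA across the 31-biomarker panel of `cadPathways()`.

## Worked example

```r
library(CADregulome)

fx <- coreTfBindingCounts()
fx$matrix
#> BindingCountMatrix: 5 TFs x 31 genes, 218 binding sites

tfTotals(fx$matrix)
#> PPARG  EGR1  ETV1  KLF7 ESRRA
#>    76    52    42    25    23

pathwayCounts(fx$matrix, fx$pathways)["EGR1", ]
#>   inflammation  coagulation  cell_adhesion  obesity  oxidative_stress
#>             10           21              7        3                 2
#>   stress  renal_function
#>        8               1

coreTFs(fx$matrix, fx$pathways, mode = "pathway")
#> [1] "EGR1"
```

PPARG contributes the most binding sites overall (76), but only EGR1 has
at least one predicted site in a biomarker of *every* pathway, making it
the sole pathway-mode core regulator of this matrix; the others miss one
or two pathways (e.g. PPARG has no site in the renal-function marker
CST3). The ETV1 row sums to 42 while its narrative total is 43;
`fx$totalDiscrepancies` keeps that difference visible.

Building the network and its modules:

```r
net <- buildRegulomeNetwork(fx$matrix, fx$pathways, familyOf = fx$familyOf)
net
#> RegulomeNetwork: 36 nodes (5 TFs, 31 biomarkers), 336 edges
#>   regulates     82
#>   co_regulates  9
#>   co_targeted   245

mods <- extractModules(net)
mods[[1]]$pathways
#> [1] "cell_adhesion" "coagulation" "inflammation" "obesity"
#> [5] "oxidative_stress" "renal_function" "stress"
mods[[1]]$regulators
#> [1] "EGR1" "ETV1" "PPARG"
```

With five broadly binding TFs the 31 biomarkers collapse into a single
module spanning all seven pathways, regulated by EGR1, ETV1 and PPARG —
the "risk module" reading of the data: biomarkers from different pathways
are co-regulated by a small core of shared TFs.

A full run from files (promoter FASTA, JASPAR-style matrices with a
metadata TSV, GMT pathways, expression TSV) is orchestrated by
`runPipeline(pipelineConfig(...))`; see the methods vignette
(`vignettes/cad-regulome-methods.Rmd`) for the model, parameter and
design discussion.

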