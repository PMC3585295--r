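---
title: "Methods: promoter regulome analysis of CAD biomarker pathways"
author: "CADregulome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter regulome analysis of CAD biomarker pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CADregulome)
```

# The problem

Coronary artery disease is accompanied by coordinated changes in serum
biomarkers drawn from seven pathophysiological pathways: inflammation,
coagulation, cell adhesion, obesity, oxidative stress, stress and renal
function. If the same transcription factors (TFs) bind the promoters of
biomarkers across several pathways, those TFs are candidate *core
regulators* whose differential expression could shift many pathways at
once. CADregulome implements that reasoning as a reproducible pipeline:
score TF matrices against promoter sequences, count predicted binding
sites, intersect the TF sets across pathway-grouped biomarkers, confirm
which predicted TFs are differentially expressed, and assemble the
TF–biomarker network whose connected biomarker groups form multi-pathway
"risk modules".

# Scoring model

A TF is represented by a position frequency matrix (PFM) over A, C, G, T.
From the per-position frequencies $f(b,i)$ we derive the **conservation
vector**

$$ci(i) = \frac{100}{\ln 4}\Big(\sum_b f(b,i)\,\ln f(b,i) + \ln 4\Big),
\qquad 0 \ln 0 \equiv 0 .$$

$ci$ is a rescaled information content: 0 at a uniform position, 100 at an
invariant one. A window $w$ of the matrix length scores the
**matrix similarity**

$$\mathrm{mss}(w) \;=\;
\frac{\sum_i ci(i)\, f(w_i, i)}{\sum_i ci(i)\, f_{\max}(i)} \in [0,1],$$

which reaches 1 exactly when the window carries a maximum-frequency base at
every position with positive conservation — mismatches at conserved
positions cost most, mismatches at degenerate positions cost little. The
**core similarity** is the same ratio restricted to the contiguous window
of (by default) 4 positions maximizing summed conservation, with ties
broken leftmost for determinism. Scanning slides the window over the
forward strand and the reverse complement; reverse-strand hits are mapped
back to forward 0-based half-open coordinates. A hit requires
`css >= cssMin` *and* `mss >= mssMin`.

Numerical choices worth stating:

* The per-window numerator and denominator are accumulated position by
  position in the same order, so a consensus window scores exactly 1.0 in
  floating point — threshold-1.0 scans are exact, not tolerance-based.
* Ambiguous bases (`N`) contribute zero to the numerator: a window
  containing `N` can never reach score 1. Characters outside
  `{A,C,G,T,N}` are rejected rather than skipped.
* A matrix whose conservation vector is identically zero (fully uniform)
  accepts every window with score 1: the "match $f_{\max}$ wherever
  $ci>0$" condition is vacuous. Such matrices carry no information and
  the convention keeps the score's attainment characterisation exact.
* No pseudocounts are added by default; the generators control zeros
  explicitly. A `pseudocount` argument exists for empirical matrices with
  sampling zeros.
* Every window position on each strand is scored independently; all
  passing windows are counted. Binding-site counting conventionally counts
  each match, and overlap suppression loses the multiplicity that the
  downstream count matrix is built on. An optional
  `mergeOverlappingHits()` mode collapses overlapping same-TF hits to the
  best-scoring one for users who prefer non-redundant counts.

# Regulome aggregation

Hits are tallied into a TF × gene `BindingCountMatrix`. On top of it:

* `tfTotals()` / `aggregateFamilyCounts()` — row sums and family-level
  sums (families conserve the grand total).
* `pathwayCounts()` — sums over each pathway's gene columns. A gene
  belonging to several pathways counts in each of them; the row-sum
  conservation property holds exactly when the pathways partition the
  genes, as they do for the built-in 31-biomarker panel.
* `coreTFs()` — two nested definitions are exposed because both are used
  in practice: mode `"gene"` (a site in *every* biomarker promoter; the
  strict reading) and mode `"pathway"` (a site in at least one biomarker
  of every pathway; the reading under which a small set of broadly
  binding TFs emerges). Gene-mode cores are always a subset of
  pathway-mode cores. On the curated five-TF matrix only EGR1 satisfies
  the pathway-mode definition — the counts themselves do not support a
  stronger claim for the other four, and the package reports what the
  arithmetic supports.
* `groupBySignature()` — partitions TFs by identical pathway signature
  (the set of pathways where the TF has at least one site), the
  "combinatorial regulators". TFs with empty signatures are kept in an
  explicit `"(none)"` group so threshold effects remain observable.
* `filterByEvidence()` — retains matrices with more than one experimental
  evidence record (`minEvidence = 2` by default), the conventional
  pre-filter before counting.

# Expression stage

Arrays are **quantile normalized**: each column's sorted values are
replaced by the mean of sorted values across columns; tied entries receive
the mean of the reference values at the ranks the tie occupies, so ties
stay tied and the transform is idempotent (to 1e-9) on tie-free data.
Differential expression uses **Welch's t** (unequal variances,
Satterthwaite degrees of freedom, two-sided p from the t distribution) —
the safer default when nothing is known about group variances; a pooled
test adds an assumption the data may not meet. Expression values are
log2-transformed before testing by default (`log2Transform`), since
intensity distributions are multiplicative; the flag exists because
testing on the linear scale is a defensible alternative. No
multiple-testing correction is applied by default — the expressed-TF
filter is an evidence screen, not a discovery claim — but
Benjamini–Hochberg adjustment is available (`bhCorrection = TRUE`) and
then drives the significance flag. Predicted TFs absent from the array
are reported as "not assayed", never silently classified. Protein panels
contribute the case/control **fold change** of group means; the log2
value is reported alongside since "fold change" is scale-ambiguous in
common usage.

The significance convention is p < alpha (default 0.05); descriptions of
this analysis sometimes render the significance condition with an
inverted inequality sign, which is internally contradictory, and the
package follows the only consistent reading.

# Network and modules

All edges derive from the pipeline's own matrices — no external
interaction database is queried, so the network is fully reproducible
from the inputs:

* `regulates` (TF → biomarker): one edge per count-matrix cell at or above
  `minCount`, weighted by the count.
* `co_regulates` (TF – TF) and `co_targeted` (biomarker – biomarker):
  Jaccard similarity of target sets / regulator sets, thresholded at
  `jaccardMin` (default 0.3 — no principled external value exists, and
  0.3 separates planted co-regulation from background sharing in the
  synthetic configurations). Two empty sets have Jaccard 0 by convention
  and never form an edge.

**Modules** are connected components of the biomarker-side graph in which
two biomarkers are linked by a `co_targeted` edge or a shared regulating
TF. Connected components, rather than community detection, keep the
definition deterministic and oracle-checkable; a modularity-based variant
would introduce resolution parameters without changing the qualitative
finding. Each module reports the pathways of its members and the TFs
regulating at least half of them; modules are ordered by size, then by
their lexicographically smallest member. Export formats are GraphML (via
igraph) and a flat TSV that also serializes node rows so isolated nodes
survive a round trip.

# Synthetic data and what it shows

The generators stand in for three data sources the pipeline would
normally consume — a proprietary matrix library, a two-group microarray
experiment, and a case/control serum panel:

* `generatePwmLibrary()` — matrices with a unique strict consensus,
  round-robin family assignment, evidence counts in {0..3}. Consensus
  strings are resampled until none is a palindrome or contained in
  another consensus (or its reverse complement), so a planted consensus
  can only produce a perfect hit for its own matrix. Default `sharpness`
  0.9 yields strongly informative matrices resembling curated PWMs of
  well-characterised TFs.
* `generatePromoters()` — backgrounds at a configurable GC content
  (default 0.5) are rejection-sampled until no window reaches perfect
  matrix similarity for any library matrix; exact consensus occurrences
  (strand chosen by a fair coin) are spliced at uniformly drawn
  non-overlapping offsets, and the assembled promoter is verified by a
  full scan at thresholds 1.0 before being accepted. Planted occurrences
  are exact consensus strings by design: recovery at thresholds 1.0 is
  then exact and threshold-free, separating scanner correctness from
  threshold calibration. Default promoter length 500 bp reflects a
  typical proximal-promoter window.
* `generateExpression()` — lognormal baselines (log2-scale mean 8, sd 2,
  typical of intensity arrays), per-sample noise sd 0.5 on the log2
  scale, group sizes 10 + 10 emulating a small whole-blood case/control
  comparison; planted genes are shifted by `effect × noiseSd` log2 units
  in cases. `generateProteinLevels()` plants multiplicative fold changes
  with lognormal subject noise (CV 0.25) at serum-panel sample sizes
  (413 + 413 by default).

Every generator is a pure function of its arguments including the seed.
What the passing tests show — and what they do not: exact recovery of
planted counts demonstrates that the scanner and tally are correct, not
that real promoters yield clean counts; real binding sites are degenerate
matches below score 1.0, backgrounds have dinucleotide and repeat
structure the uniform model lacks, and real matrix libraries contain
similar, overlapping motifs. The statistical calibration under the null
generator shows the Welch test keeps its nominal size on lognormal data;
it does not certify power on arrays with correlated probes. Discovery
counts from a proprietary matrix library and a specific cohort (e.g. how
many TFs pass an evidence filter, or how many are differentially
expressed) are properties of those resources and are not reproduced here.

# Problem sizes and runtime choices

The validation suites use desk-scale configurations chosen to exercise
every code path with exact oracles: exhaustive window enumeration at
matrix lengths 4–6 over 100 random promoter/threshold cases; planted
recovery for a 20-TF × 31-biomarker study at 450 bp promoters; null
calibration with 1000 genes at 10 + 10 samples. These sizes make the
brute-force oracles exact references while keeping the whole suite and
the acceptance script each under a minute of compute on a single core.

# Curated counts

`coreTfBindingCounts()` encodes the reported per-promoter binding-site
counts of the five core CAD regulators across the 31-biomarker panel, as
enumerated (PPARG 76, EGR1 52, KLF7 25, ESRRA 23). The ETV1 enumeration
sums to 42 against a narrative total of 43; the matrix stores the
per-promoter integers verbatim and exposes the difference via
`totalDiscrepancies` rather than adjusting either number. Biomarker
symbols follow HGNC conventions with common biomarker labels where
symbol usage is inconsistent in the source material (the heat-shock
proteins are kept as HSP27/HSP60/HSP70; plasminogen is PLG; PAI1 and
SPLA2 keep their assay names).

# Known limitations

* The scoring scheme models single-motif matches; cooperative or spaced
  dimeric sites are out of scope.
* Pathway counts treat all promoters equally; no weighting by promoter
  length or conservation across species.
* The network's Jaccard edges measure co-occurrence in the binding-count
  matrix, not physical interaction.
* `runPipeline()` is single-threaded; the scan is vectorized per
  (promoter, matrix) pair and scales linearly in both.
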