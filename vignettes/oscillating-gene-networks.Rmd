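---
title: "Methods: cross-species networks of ultradian and circadian gene sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species networks of ultradian and circadian gene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harmonet)
```

`harmonet` packages the bespoke computational stages of a multi-layered
analysis of genes oscillating with 8-h, 12-h and 24-h periods in mammals:
how their chromosomal clustering is conserved between two species, whether
they are preferentially wired to a reference circadian subnetwork, and
whether the proteins they encode differ in predicted stability. This
vignette explains each method, the assumptions behind it, the parameters
that matter, and the choices made where the methodology was genuinely open.

## Period classes

Rhythmic transcripts are classified by oscillation period into `P24`
(24 ± 4 h, circadian), `P12` (12 ± 2 h) and `P8` (8 ± 1 h, the two
ultradian harmonics); anything else is `NONE`. The "±" windows are treated
as **closed intervals**, so a transcript at exactly 9 h is classified `P8`
rather than silently dropped; open or half-open windows would exclude
boundary periods for no biological reason. Classification happens upstream
of this package in real studies (rhythm detection on time-course arrays is
out of scope); `classify_period()` exists so synthetic gene sets are
labelled by the same rule real sets would be.

## Homolog resolution

Orthology resources return one-to-many and many-to-many candidate
relations. `resolve_homologs()` ranks each query's candidates
lexicographically by a fixed priority cascade — confidence score, GOC
score, target %ID, query %ID, dN/dS — and then assigns greedily. Points the
cascade definition leaves open, and the choices made:

* **dN/dS direction.** Only "dN/dS ratio" is listed as a criterion, with no
  direction. The default ranks candidates by closeness of dN/dS to zero,
  i.e. prefers pairs under stronger purifying selection, the standard
  reading for ortholog quality; `prefer_low_dnds = FALSE` inverts this.
* **Missing scores** rank below any present value at their cascade level —
  an absent GOC score should not beat a measured one.
* **Conflict serialization.** When two queries prefer the same target,
  queries are processed in ascending query-id order and a claimed target
  makes later queries fall through to their next candidate. This is
  deterministic, order-insensitive to input shuffling, and keeps the map
  injective in both directions. Whether the original analysis enforced
  global one-to-one or merely per-query best is not stated; both are
  supported (`one_to_one` flag), one-to-one being the default because the
  downstream network relabelling requires an injective map.
* **Full ties** break by smallest target id, so resolution never depends on
  row order.
* Genes with no surviving candidate are **reported unmapped, never
  imputed** — the manual rescue of unmatched genes that a human analyst
  performs has no algorithmic counterpart.

## Co-localization networks, intersection and conservation

For a gene set, genes are nodes and an edge joins two genes on the same
chromosome, so each chromosome contributes a clique. **Isolate removal** —
dropping genes alone on their chromosome — is applied after *every*
transformation (build, homology relabelling, intersection), because the
published network statistics are explicitly reported "after isolate nodes
removal"; statistics always describe the pruned graph.

The species-2 network is relabelled to species-1 ids through the homology
map (unmapped genes drop with their edges) and intersected with the
species-1 network keeping only nodes and edges present in both. Two genes
count as co-localized in the intersection when they share *some* chromosome
in each species — the chromosomes need not correspond. Because an edge set
defined by "same chromosome in both species" is the intersection of two
partitions, every component of every emitted network is a clique; the
constructor asserts `edges = sum C(size, 2)` on every run.

The **conservation score** is

```
round_half_up(100 * intersection nodes / species-1 network nodes)
```

No formula is stated alongside the published percentages, but this ratio
reproduces all three reported values (33/51 → 65%, 45/199 → 23%,
103/1827 → 6%), so it is adopted and documented as derived. Rounding is
half-up to an integer percent. A gene assigned to two chromosomes, or
gene/chromosome rows duplicated, are input errors rather than silently
resolved; unknown gene ids in a set are skipped with a warning and counted.

## Randomized connectivity test

`connectivity_test()` asks whether a focal gene set has more interactions
with a designated subnetwork than random gene sets of the same size. The
null is a **node-label randomization against a fixed interaction
reference**: random sets are drawn uniformly without replacement from the
reference nodes outside the focal set, and each draw is scored by the same
cross-interaction count as the observed set. The interaction structure is
never rewired (no degree-preserving null); this mirrors the description of
the original procedure ("random sets of genes of matching size") and keeps
the null exactly exchangeable with the target set under no enrichment.

Numerical conventions:

* Ids in both sets are removed from the target side before counting —
  self-interactions of the focal set would otherwise inflate its apparent
  connectivity to anything.
* Interaction records collapse to unique pairs by default; databases often
  report the same pair from several experiments, and published counts may
  be record counts, so `count_records = TRUE` preserves multiplicity
  (round-tripped through the MITAB writer).
* The null SD uses the n − 1 denominator; `z = (observed − mean) / SD`,
  with `z = Inf` / `z = 0` sentinels when the null is degenerate.
* The empirical p-value uses the pseudo-count form
  `(1 + #{null ≥ observed}) / (n_iter + 1)`, so it is never zero and is
  honest about Monte-Carlo resolution (with 100 iterations the smallest
  attainable p is 1/101).
* `exhaustive_null()` enumerates every k-subset (lexicographically) and is
  the oracle the Monte-Carlo null is tested against on small universes.

## Energy-feature statistics

Per-protein tables carry 18 FoldX energy terms plus the residue count.
`descriptive_table()` reports mean ± SD (n − 1) per group.
"Kruskal–Wallis with residue number as covariate" has no single standard
definition — the Kruskal–Wallis test admits no covariate. The
interpretation implemented is **rank residualization**: the pooled feature
values are rank-transformed, regressed on the rank-transformed residue
number by least squares, and the tie-corrected Kruskal–Wallis test runs on
the residuals. A constant covariate (or testing the covariate itself)
reduces exactly to the unadjusted test, and `adjust_for_residues = FALSE`
disables the adjustment entirely; the flag exists precisely because this is
an interpretation, not a published algorithm. Dunn's post hoc test uses the
usual tie-corrected pooled-rank variance and two-sided normal p-values,
adjusted by **Benjamini–Hochberg within each feature across the pairwise
family** (the FDR family is not stated in the source methodology; per
feature across group pairs is the narrowest family consistent with how the
contrasts are reported, and the method/scope are configurable). All tests
are two-sided. Spearman matrices are tie-aware, with two-sided p-values
from the t approximation; pairs involving a constant feature are reported
as missing rather than zero.

## What the synthetic generator emulates — and what it does not

The generator exists because every external resource of the original study
(expression arrays, orthology tables, interaction snapshots, structure-based
energies) is either restricted, unpublished or out of scope. Its defaults
are fixed at the study conditions: a 21-chromosome species-1 genome against
a 24-chromosome species-2 genome, gene-set sizes 56 / 205 / 2054 for
P8 / P12 / P24, and energy-feature laws taken from the published per-group
means and SDs (`default_energy_params()`), with the non-oscillating control
sized to match the oscillating total (its true size is unpublished).

* **Conservation is planted per chromosome block.** With probability
  `conservation_rho` a species-1 chromosome's genes map onto one common
  species-2 chromosome; otherwise each gene disperses to its own unique
  chromosome label. This block-level construction is the one mechanism
  under which the pairwise co-localization probability *and* the expected
  node-level conservation score both equal `conservation_rho`, which makes
  the parameter recoverable end to end without bias. A per-gene migration
  model would decouple the two. The `scatter = "uniform"` option instead
  scatters displaced genes uniformly over species-2 chromosomes, adding the
  chance co-localization background real genomes have — at the cost of a
  small upward bias in recovered conservation that shrinks as the
  species-2 chromosome count grows.
* **The planted-true homolog candidate always carries the strictly best
  confidence score**; decoy scores are randomized below it. This makes
  cascade recovery verifiable (the resolved map can be compared to the
  planted truth), but it means the synthetic data never exercise the case
  where the true ortholog loses on confidence — the lower cascade keys are
  exercised by dedicated unit fixtures instead.
* **The interaction graph is Erdős–Rényi** with cross-set edges between the
  focal set and the target subnetwork drawn at
  `min(1, p · (1 + enrichment_delta))`. Real interactomes are heavy-tailed;
  a null calibrated on an ER graph says nothing about degree-driven
  confounding in real data (which the set-resampling null does not correct
  for either). The target subnetwork's size is a free parameter
  (`target_set_size`, default 100) because the size of the reference
  circadian gene network it stands in for is not published.
* **Energy features are sampled independently** per protein from the group
  law. The correlation structure visible in real energy terms is an
  *output* of the analysis, not a generative assumption here — so passing
  correlation-matrix code on synthetic data shows only mechanics, not
  recovery of real correlation patterns. Residue number is rounded and
  floored at 30 residues.
* **Seeding**: one master seed, split per sub-generator by fixed offsets,
  so any stage can be regenerated independently and the whole pipeline is
  byte-reproducible (the run manifest records MD5 hashes of every output;
  hash equality across re-runs is the regression test).

Consequently, passing tests demonstrate that the algorithms are correct and
calibrated under known generative conditions; they do not demonstrate that
real mouse–human data would show any particular conservation level or
connectivity excess.

## Numerical choices and degenerate inputs

* Conservation rounding: half-up (`floor(x + 0.5)`), matching the reported
  integer percentages.
* A KW test on values identical across groups returns `H = 0, p = 1`
  rather than the 0/0 the tie-corrected formula produces.
* Dunn z with a zero pooled variance (all values tied) returns 0 with
  p = 1.
* Spearman ρ of ±1 gets p = 0 rather than the NaN of the t approximation.
* Empty gene sets, empty intersections and zero-node networks are
  legitimate results everywhere except as the conservation denominator,
  which is an error (the score is undefined).
* The conservation arithmetic (`conservation_percent()`) is exposed
  separately from the network object so published node counts can be fed
  through the exact production code path.

## Problem sizes used in the test suite

The suite calibrates stochastic properties at sizes chosen to keep
binomial/Monte-Carlo standard errors informative: conservation recovery
uses 20 chromosomes × 10 genes over 50 seeds per rho (3-SE criterion);
enrichment monotonicity uses a 200-node graph over a δ grid of
{0, 1, 2, 4, 8} with 20 seeds each (Spearman ρ > 0.9); the null
calibration of the adjusted KW test uses 1000 replicates of 3 × 10
observations (type-I ≤ 0.07 at α = 0.05); and contrast-direction recovery
uses the published group sizes 56 / 205 / 2054 over 100 replicates. These
sizes are the package's own calibration conditions and are stated here so
they can be scaled up by anyone wanting tighter error bars.
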