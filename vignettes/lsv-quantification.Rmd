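---
title: "Splicegraphs, LSV quantification and AS modules: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splicegraphs, LSV quantification and AS modules: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsvquant)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic-data tests do and do not demonstrate
about real data.

## The splicegraph and LSVs

A gene is modelled as a **splicegraph**: non-overlapping exons as vertices,
and two kinds of edges — splice junctions and retained introns.  All
coordinates are stored 0-based half-open on the forward genomic strand
(GFF3's 1-based inclusive intervals are converted at the boundary); a
junction's `start` is the first excised base and its `end` the first base of
the acceptor exon.  Storing everything in forward-genomic orientation and
resolving "source"/"target" by strand only at LSV definition keeps interval
arithmetic free of strand special cases.

Parsing a GFF3 merges every transcript's exons into maximal regions and
carves out a **retained intron** wherever one transcript's junction interval
lies strictly inside a region covered by another transcript's exon; the
spanning exon is split so every junction starts and ends in different exons.

A **local splicing variation (LSV)** is the split at one reference exon into
its outgoing (source) or incoming (target) non-simplified edges; only splits
with at least two edges are kept, and each edge can therefore appear in at
most two LSVs gene-wide.

### De novo elements and the builder filters

Unannotated junctions observed in split alignments are assigned to genes by
priority: (1) a gene already containing the junction, then (2) a gene with
both junction coordinates within 400 bp of an exon, then (3) a gene whose
boundaries contain the junction; ties break by distance to the gene-boundary
midpoint and then lexicographic gene id, for determinism.  An accepted
junction endpoint extends the nearest exon by at most 400 bp — the same
window as the gene-assignment rule, so one proximity scale governs both —
and otherwise creates a minimal de novo exon.  Introns overlapped by new
exon boundaries are split; because intron coverage is averaged over the
original intronic region, each fragment simply inherits that average.

Acceptance of a de novo element requires, in at least one build group, that
at least `min_experiments` experiments each show `reads >= 5` and
`nonzero positions >= 3`; annotated elements use the laxer `(3, 2)`.  The
asymmetry is deliberate (stronger evidence for unannotated structure); the
specific numbers are package defaults, configurable per run, not values with
an external source.  `min_experiments` defaults to half the group, rounded
up.  Annotated-but-unobserved junctions are retained in the graph rather
than pruned: removing annotation on absence of coverage would make LSV
identity depend on sequencing depth.

### Simplifier

After the build, each edge's raw read rate is compared, within every build
group, to the summed rate of the edges of each LSV that contains it.  An
edge is flagged *simplified* — kept in the graph, excluded from LSV
definition — only when its ratio is below the threshold in **every** group
for **both** of its LSVs.  A group in which an LSV has no reads at all
abstains (counts as "low"): absence of usage evidence should not protect an
edge from simplification.  With threshold 0 the operation is the identity,
and raising the threshold can only add flags (monotonicity), both covered by
property tests.

## Coverage model

Junction coverage is per *position*: a read of length `L` supports a
junction at the read offset where its alignment splits, giving `L − 1`
possible positions.  The nominal `L` is configuration (default 100), not
inferred per read, so `num_positions` is stable across experiments.  For
introns, the exon/intron boundary acts as a zero-length junction (`L − 1`
junction-like placements) and reads starting inside the intron add one raw
position per genomic offset; the raw positions are then aggregated into
`L − 1` contiguous bins whose sizes differ by at most one, each bin carrying
the mean of its members.  This makes intron and junction coverage
commensurable and lets intron coverage be computed once and re-used across
rebuilds with different intron boundaries.

Two corrections precede quantification.  **Outlier masking**: positions with
zero coverage are masked; for each nonzero position a Poisson rate is
estimated from the *other* nonzero positions and the position is masked when
its right-tail probability falls below `alpha = 1e-7` (one simultaneous
pass; masking is anti-monotone in `alpha`).  This is the package's only
read-stack correction.  **Bootstrap**: each of `M = 30` replicates sums `n`
draws with replacement from the `n` unmasked counts; when the unbiased
sample variance falls below the mean (underdispersion relative to Poisson)
the draw is replaced by Poisson sampling around the observed total.  `M =
30` keeps desk-scale runs fast and is configurable; the unbiased variance
estimator is a documented choice, made once.

Per-experiment coverage round-trips losslessly through a versioned text SJ
container with an explicit end marker, so builds from SJ are bit-identical
to builds from alignments and truncation is detected rather than silently
absorbed.

## PSI, dPSI

Within one LSV with `J` edges, reads are multinomial across edges; each
edge's marginal is `r_j ~ Binomial(Σ r, Ψ_j)` with the generalized Jeffreys
prior `Beta(1/J, 1 − 1/J)`, chosen because real inclusion levels concentrate
near 0 and 1.  The posterior is conjugate:
`Ψ_j | r ~ Beta(1/J + r_j, 1 − 1/J + Σ_{j'≠j} r_{j'})`.  Edge-wise marginal
Betas (not a joint Dirichlet) are used per bootstrap replicate; since all
edges share the same read total, the posterior means still sum to one
exactly.  Group quantification sums read rates across the experiments that
pass the quantifiability thresholds (`reads >= 10` and `positions >= 3` per
LSV — deliberately stricter than the builder filters) per bootstrap
replicate, and averages the replicate densities.

Densities are discretized to `B = 40` bins on `[0, 1]` — fine enough that
the 20% changing and 5% non-changing thresholds are 8 and 2 bins wide —
and dPSI lives on the `2B − 1 = 79`-point grid of bin-index differences.
The independence distribution is the discrete cross-correlation of the two
group densities; the posterior multiplies it by a mixture prior and
renormalizes.  The prior has three symmetric components: a spike
(`Beta(5000, 5000)` on `(ΔΨ+1)/2`, ~95% of mass within |ΔΨ| < 0.02), a
centered component (`Beta(50, 50)`, ~95% within |ΔΨ| < 0.20), and a uniform
slab, with weights (0.25, 0.50, 0.25).  The component count and roles are
the model; these widths and weights are package defaults reported in output
metadata, not empirical claims.  The default significance rule for reported
dPSI events is `P(|ΔΨ| > 0.2) >= 0.95`; `--show-all` disables the filter.

## Heterogeneous groups (HET)

When samples are not replicates, pooling reads hides between-sample
variability.  Instead each experiment is quantified alone and the two groups
are compared per edge under the null that per-experiment Ψ values share a
distribution, using four statistics: Welch's t, Mann-Whitney U, TNOM and
InfoScore.

* **Mann-Whitney** uses an exact null for up to 64 total observations and a
  normal approximation with tie and continuity correction beyond.  The
  exact null conditions on the observed value multiset: a dynamic program
  over tie groups counts, for every attainable U, the number of the
  `C(n, n1)` label assignments realizing it, so tied data get exact
  p values too.
* **TNOM** is the minimum number of misclassified labels over all single
  thresholds (both orientations); **InfoScore** is the best-threshold
  mutual information between side and label, in bits.  Thresholds never
  split equal values.  Both nulls are computed by an absorbing lattice-path
  DP over label arrangements; the tests verify exact rational agreement
  with exhaustive enumeration for all group sizes with `n1 + n2 <= 12`.
* Measurement uncertainty enters by sampling: `n_rep = 30` times, one Ψ per
  experiment is drawn from its discretized posterior, each statistic's p is
  computed, and the nearest-rank 95th percentile across repetitions is
  reported (`p_quantile`).  Because these quantiles are conservative rather
  than calibrated, the p value at the posterior means (`p_mean`) is emitted
  alongside; downstream flags use `p_quantile`, the conservative variant.
  `n_rep` and the quantile rule are package defaults — the procedure needs
  *a* repetition count and *a* quantile estimator, and both are stated.
  Group medians of the posterior means and their difference accompany every
  edge.

## Modulizer

Module analysis first **decomplexifies** the graph: edges whose group-median
E[Ψ] stays below 5% in every group are removed from consideration (the
underlying graph is untouched).  **Modules** are maximal runs of edges whose
spanned exon gaps overlap — single entry, single exit, at least two edges;
boundary exons may be shared between adjacent modules but edges may not, so
modules partition the alternative regions at the edge level.  The definition
is not recursive; nested structure is expressed through the event list
instead.

Within a module, pattern matching emits binary events: IR (intron plus the
matching junction), alternative 3'/5' splice sites (junction pairs sharing
one side), cassette exons, tandem cassettes (complete inclusion chain over
two or more skipped exons), multi-exon skipping (any inclusion path), and
mutually exclusive exons; alternative first/last exons arise from two
terminal exons converging on a shared exon, with their *putative* variants
(pAFE/pALE) when a terminal exon is unannotated — "nearby" for de novo
junctions reuses the builder's 400 bp window.  Putative splice sites
(pA3SS/pA5SS) are cassettes whose one inclusion junction was simplified away
while the adjacent retained intron keeps a group-median E[Ψ] of at least 5%
in some group — the same threshold as decomplexification, reused rather
than invented.  On the minus strand, 3'/5' and first/last labels flip.  A
module matching nothing yields a single "other" event.  The taxonomy is
table-driven (`AS_EVENT_TYPES`), so extending or re-reading a pattern set is
a configuration change.

Module labels are event-type multisets with a redundancy rule: every tandem
cassette implies a multi-exon-skipping event, and every putative splice site
implies an intron-retention event, so the redundant type is added to the
label only when its count exceeds the overlapped type's count.

Events are flagged **changing** when some edge has |difference of group
medians| ≥ 0.20 and every requested statistic has p < 0.05, and
**non-changing** when every edge has |Δmedian| ≤ 0.05, within-group IQR ≤
0.10, and all p ≥ 0.05; the threshold structure makes the two flags mutually
exclusive for any valid configuration.  Because source- and target-side
quantifications of the same physical event need not agree, both LSV
references are carried on every event.

## Evaluation statistics

`rr_curve()` implements the reproducibility ratio: RR(n) is the fraction of
the top n events of one ranked list found among the top n of a second list
from a disjoint sample split, with overlapping LSVs (sharing a junction)
collapsed to the first-ranked representative.  Within this package, HET
output ranks by `p_quantile` ascending then |Δmedian| descending, and dPSI
output by `P(|ΔΨ| > 0.2)` descending — a ranking must be fixed to be
reproducible, and this one is documented.  `iir()` is the intra/inter
significant-event ratio (missing when the inter count is zero).  Event
labels follow the TP/TN/FP/FN conjunctions on (tool ΔΨ, tool p, true ΔΨ)
maxima over event edges with everything else Ambiguous; gene labels take the
worst case in the order FP > FN > TP > TN.

## The synthetic generator, and what the tests show

`toy_gene_*()` archetypes plant one event type each; the 20-gene panel (5
CE, 3 IR, 2 each of MXE, A3SS, A5SS, TCE, AFE, ALE) is the fixture for
structural exactness.  `simulate_sample()` works at coverage level: each
edge's read total is Poisson around `depth ×` its relative isoform
abundance, spread uniformly over read positions; between-sample
heterogeneity draws each sample's inclusion from a Beta with mean at the
true Ψ and variance `dispersion² · μ(1−μ)`.  The calibration and power
studies run at the conditions the tests state: null groups at dispersion
0.05, 10 experiments per group, depth 100; planted changes of ΔΨ = 0.4 at
the same size; PSI recovery at depth 200 (sizes chosen as representative
desk-scale conditions and fixed once).  `write_sam()` realizes simulated
junction coverage as split-CIGAR reads so the alignment-parsing path is
exercised against the same ground truth.

Passing these tests shows the machinery is correct under the generator's
assumptions — uniform positional coverage, independent edges, no sequence
errors, no positional bias, no multimapping, no fragment-length effects.
Real libraries violate all of these to some degree; the positional outlier
mask absorbs some of it, but accuracy numbers from the synthetic panel
should be read as upper bounds on real-data behaviour, not estimates of it.

## Numerical choices and degenerate inputs

* Welch's t on two zero-variance groups returns p = 1 for equal means and
  p = 0 otherwise, so constant posteriors behave sensibly.
* All-zero coverage masks every position and yields zero bootstrap rates;
  an LSV with no passing experiment is reported unquantifiable, not an
  error.
* `psi_posterior()` refuses `J < 2` (not an LSV) and negative reads.
* The dPSI posterior raises an error if prior × data has zero mass
  (degenerate prior), rather than renormalizing noise.
* Exact-null DP counts are doubles; up to `n = 64` the relative error is
  bounded by machine epsilon times the path count, far below any p-value
  tolerance used.
* Ties in gene assignment and in event ordering are broken
  deterministically (coordinates, then identifiers); every stochastic step
  takes an explicit seed, and pipeline functions seed once and draw
  sub-seeds, so whole runs are bit-reproducible.

## Known limitations

Transcript-level isoform reconstruction, alternative polyadenylation,
multimapping resolution, covariate/batch correction and visualization are
out of scope.  Multi-group joint models are not implemented; multi-group
workflows are expressed as sets of pairwise comparisons ("consistently
changing" = changing in every required comparison).  The simplifier and
decomplexifier operate on group aggregates and will not protect an edge used
only in a rare sub-population of samples.
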