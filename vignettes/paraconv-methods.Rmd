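---
title: "Detecting gene conversion between duplicated genes: models and methods"
author: "paraconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gene conversion between duplicated genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paraconv)
```

# The problem

Recently duplicated genes exchange sequence by gene conversion: a
nonreciprocal, copy-and-paste transfer between similar sequences at the same
or a linked locus. Repeated conversion homogenises the duplicates (concerted
evolution); regions that resist conversion stand out as islands of
divergence and are candidates for selection maintaining differentiated
copies; and rare conversion of a diverged region can build chimeric
haplotypes that carry one paralog's 5' end and the other's 3' end, abruptly
injecting large amounts of variation into the recipient locus.

`paraconv` analyses this situation for a pair of paralogs sequenced as
phased haplotypes in several diverged populations. The expected input is an
alignment of all haplotypes of both paralogs across populations, tagged with
(population, paralog) labels (`GroupedAlignment`), plus an optional coding
annotation (`CodingMap`). A forward simulator with known conversion tracts
makes every stage testable end to end without any external data.

# Polymorphism and divergence statistics

Within a (population, paralog) group, `piByClass()` reports nucleotide
diversity as the mean pairwise proportion of differences per comparable site
(Nei's estimator; no small-sample scaling), partitioned into synonymous,
nonsynonymous and silent (synonymous + noncoding) classes using
Nei–Gojobori site counting, together with class-specific segregating-site
counts and Tajima's D from the standard constants. Columns with gaps in any
group member are excluded listwise from site counts; `N` is missing data and
never counts as a difference. A segregating coding column is classed
synonymous when every codon observed at its codon position translates to the
same amino acid — a deliberate simplification for codons carrying multiple
polymorphisms, which are rare at these diversities.

Between groups, `divergenceBetweenGroups()` computes Nei–Gojobori (1986)
synonymous/nonsynonymous divergence: per-codon site counts averaged over the
two sequences, multi-difference codons averaged over all minimal mutational
pathways with equal weight (pathways through stop codons excluded, mutations
to stops counted as nonsynonymous), and Jukes–Cantor correction
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$, which errors at saturation
($p \ge 3/4$) rather than returning an imaginary number. The default
`fixed_only` mode mirrors "fixed divergence" tables: each group is reduced
to its consensus with within-group polymorphic sites masked, so segregating
variation contributes nothing. `mean_pairwise` averages raw counts over all
between-group pairs instead.

`slidingDxy()` profiles between-group divergence in windows (defaults 60 bp
window, 12 bp step for the paralog-pair profile; 50/10 is conventional for
more slowly evolving comparisons). Windows are emitted only while they fit
entirely inside the alignment — no ragged final window, matching the
plotted-profile convention — and a window with no comparable sites is `NA`,
never silently zero. `columnEntropy()` gives the per-column Shannon
conservation measure for protein alignments.

# The conversion scan

The scan follows the logic of Sawyer's permutation statistic. Within one
population (conversion is only biologically possible within a genome, hence
within a population), the alignment of both paralogs' haplotypes is
projected onto its polymorphic columns (`projectPolymorphic()`); columns
containing gaps are dropped — a gap column can break a fragment but never
support one. For every within-population pair of sequences, candidate
fragments are maximal runs of consecutive polymorphic sites at which the two
sequences agree (`pairFragments()`, mismatch penalty `g = 0`; with `g > 0`
maximal scoring segments are found by the Ruzzo–Tompa algorithm). A
fragment's score is its number of supporting sites; fragments with fewer
than two sites are noise and discarded.

Significance comes from column permutations (`permutationPvalues()`):
shuffling the order of polymorphic columns preserves every pair's
match/mismatch multiset while destroying physical contiguity, which is
exactly the signal of a conversion tract. The null statistic is the maximum
fragment score over *all* allowed pairs, so the reported
`sim_p = (1 + \#\{\text{perm max} \ge \text{score}\})/(n_{perm} + 1)` is a
global, family-wise-valid p-value without a separate Bonferroni step, and
the `(1+x)/(1+N)` form keeps it valid under ties. For projections of at most
eight columns an exhaustive mode enumerates all column orders. Note a
structural property inherited from the statistic: a pair identical at every
polymorphic site ties every permutation and can never be significant on its
own — near-identical allele pairs inflate the null rather than the signal.

Significant fragments are classed inter- or intra-paralog from their labels
and merged into overlap-connected clusters per (population, category)
(`classifyAndCluster()`); the cluster count is the reported minimum number
of conversion events. Numeric parity with any particular external scanner is
not promised; the scan's agreed outputs are calibrated significance and
event counts.

# Conversion signatures

`sharedParalogSites()` emits columns where both paralogs of one population
share a state that is absent from every sequence of every other population —
the most conservative reading of "shared within, absent across", chosen so
that incomplete lineage sorting of old variants produces as few false calls
as possible. `classHaplotypes()` delimits allele classes (for example
"donor-like" vs "recipient-like" haplotypes of a converted paralog) by
single-linkage clustering on pairwise differences in a region, cut at an
explicit difference threshold; because such classes are conventionally
delimited by eye from a tree figure, the threshold is an exposed parameter
rather than a guessed constant. `donorProfile()` contrasts windowed divergence of a focal
class against its own orthologs (same paralog, other population) and
against the co-resident other paralog; windows where the class is closer to
the other paralog by more than `call_threshold` (default 0.05
differences/site, roughly twice the within-population diversity of the
study system) are flagged as putatively converted, and a breakpoint is
called at the midpoint between flanking above-threshold windows of opposite
sign. Breakpoint resolution is therefore limited to about one window.

# Partitioned parsimony

`fitchScore()` implements Fitch parsimony with site-pattern compression;
gaps and `N` are missing data (any state), not a fifth state, so
pseudogene-style indels never add spurious steps. `searchMP()` uses
random-addition starting trees with nearest-neighbour-interchange (NNI)
hill climbing. NNI rather than SPR/TBR is a deliberate simplification:
at the ~20-tip scale of a two-paralog, four-population dataset it reliably
finds the optimum (verified against exhaustive topology enumeration in the
tests) at a fraction of the cost. All distinct topologies attaining the best
score — including equal-score NNI neighbours of the local optima — are
returned, because tied most-parsimonious trees are themselves part of the
chimera evidence. `bootstrapConsensus()` resamples columns, reruns a reduced
search per replicate, and reports the 50% majority-rule consensus rooted on
the outgroup with bipartition frequencies as supports; 1000 replicates is
the default (supports at this problem size stabilise well before that), with
the count configurable upward. `partitionIncongruence()` quantifies the
chimera signature: the same focal tips placed with their own paralog's clade
in one gene partition and with the donor paralog's clade in the other, plus
the Robinson–Foulds distance between the partition trees. Clade attachment
is operationalised as the smaller mean nodal distance to the two defined
clades, which is deterministic and robust to rooting.

# The simulator

`simulateDataset()` is a forward simulator designed so that every analysis
stage can be validated against known truth:

* substitution is Jukes–Cantor-like (uniform rate, uniform replacement), so
  divergence expectations are closed-form and match the JC correction used
  in the analysis;
* an ancestral gene is duplicated at `duplication_height` (default 0.125
  expected substitutions/site, giving ~0.25 between paralogs — the
  magnitude of paralog synonymous divergence in the motivating system);
  population splits default to 0.03 and 0.015, an order of magnitude
  shallower, as observed between conspecific populations;
* conversion events arrive as a Poisson number per branch, copy a
  geometric-length tract (mean 150 bp, in the tens-to-hundreds range
  expected for gene conversion), choose the donor with probability
  `donor_bias` for paralog 1 (default 0.5; directional transfer is modelled
  by setting it near 1), and are rejected when the tract overlaps a
  configured divergence island or when local donor–recipient divergence
  exceeds `meps_divergence_cutoff` (default 0.25, just above the ~20%
  threshold reported to suppress homologous conversion);
* tip haplotypes are drawn on a star genealogy with per-lineage mutation
  `theta_within/2`. The default `theta_within = 0.04` matches the
  within-population diversity of the conversion-affected focal paralogs in
  the motivating system (synonymous diversity of a few to several percent),
  which is the regime in which the scan is meant to operate;
* planted events (`forced_events`) are applied deterministically — either on
  a named branch or, for chimera scenarios, by copying a tract from a
  contemporary donor haplotype into chosen recipient haplotypes after tip
  sampling — and are recorded in the truth table together with all accepted
  stochastic events. Pseudogenization is carried only as an annotation flag,
  never as alignment gaps, so the scan's input remains fully alignable.

What the simulator does *not* emulate is worth stating. The star genealogy
produces an excess of singletons, so simulated groups have negative Tajima's
D on average (neutral-equilibrium D is checked against a separate Kingman
coalescent oracle, `simulateCoalescent()`); there is no recombination within
populations, no selection (so simulated ka/ks is ~1, unlike the strongly
constrained real genes), no indels, and no rate heterogeneity. Passing tests
therefore demonstrate the correctness and calibration of the statistics
under a clean neutral model, not robustness to every feature of real data.
Because π is a proportion of observed differences, its finite-sites
expectation for divergence θ is the JC transform
$\tfrac{3}{4}(1 - e^{-4\theta/3})$ (≈ 0.0389 for θ = 0.04), and the
theta-recovery checks compare against that value, not θ itself.

# Numerical and design choices

* Coordinates are 1-based inclusive everywhere; conversions to other
  conventions happen only at file boundaries.
* Consensus ties break lexicographically (A < C < G < T), for determinism
  across platforms.
* `ka/ks` is undefined (`NA`, printed `-`) when `ks = 0`; Tajima's D is a
  flagged `NA`, never a silent zero, when `S = 0` or `n < 4`.
* All randomness flows from a single integer seed per entry point; scans,
  searches, bootstraps and simulations are bit-reproducible given the seed.
* Default problem sizes for the stochastic validation runs (500 null
  datasets and 100 recovery replicates at 499 permutations; 2000 coalescent
  replicates) were chosen as the smallest sizes at which the binomial /
  sampling error of the checked quantity is comfortably below the decision
  band.
* The permutation null is implemented for the default `g = 0` scan; a
  positive mismatch penalty changes only the fragment enumeration.

# Known limitations

The scan's power collapses when within-group diversity is very low (the
null maximum is then set by near-identical allele pairs) or when conversion
is old enough that post-conversion substitutions fragment the matching run
— both are properties of the underlying statistic, not of this
implementation. Breakpoints are window-resolution estimates, not model-based
inferences. The parsimony machinery is aimed at the small, closely related
haplotype sets it is used on here; it is not a general-purpose phylogenetics
replacement.
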