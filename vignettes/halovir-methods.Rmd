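---
title: "Methods: virome community analysis for a disturbed hypersaline estuary"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virome community analysis for a disturbed hypersaline estuary}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

halovir implements the analysis chain used to characterise viral communities
in a two-site hypersaline estuary sampled over thirteen months under pulse
disturbances (a freshwater inundation and two winter freeze events): ensemble
virus-call consensus, vOTU dereplication, breadth-filtered abundance,
majority-rule taxonomy, permutation-based community statistics, k-medoid
temporal clustering with model selection, and virus-host network filtering.
This vignette records the models, the tunable parameters, and the design
choices made where the procedure was genuinely open.

## Ensemble consensus

Virus predictions from several tools (four by default) are concatenated.
Exact duplicate sequences collapse to one record; name-variants produced by
provirus-trimming tools (base name plus a `||start-end` suffix) collapse to
the *shortest* variant, with the supporting-predictor set the union over
variants. A contig passes when it is strictly longer than `min_length`
(default 10,000 bp) and called by at least `min_tools` (default 2) distinct
predictors. Both bounds are read literally: a 10,000 bp contig fails, two
calls from one predictor count once. The vote is evaluated after
name-collapsing, i.e. on the union of supporters across variants, which is
the natural reading of "concatenate, deduplicate, then filter"; ties among
equally short variants break lexicographically so the output is a pure
function of the call set.

## vOTU dereplication at 95% ANI / 85% AF

Pairwise ANI is computed by a k-mer-seeded ungapped block aligner: exact
15-mer matches seed diagonals, seeds on a diagonal are merged (gaps up to
200 bp) and extended under an X-drop rule (match +1, mismatch -2, drop 30);
blocks shorter than 100 bp are discarded. ANI is the match fraction over all
retained block columns; the aligned fraction (AF) is the unioned block
footprint divided by the length of the *shorter* sequence — the standard
dereplication convention, since the threshold's denominator is not otherwise
determined. Both strands are seeded because assembly strand is arbitrary.
The test suite holds this implementation to within ±0.005 ANI of a full
dynamic-programming alignment on kilobase-scale pairs.

Clustering is greedy and centroid-based: contigs sorted by length descending
(ties by id); each contig joins the eligible representative (ANI ≥ 0.95 and
AF ≥ 0.85) with the highest ANI, earlier-founded on ties, else founds a new
vOTU. The longest member is therefore always the representative, and the
partition is deterministic. vOTUs are named after their representative's
base contig name so annotation and host tables can reference them stably.

## Detection and abundance

A vOTU is *detected* in a sample when the coverage breadth of its
representative — the fraction of positions covered by at least one read,
computed from merged 0-based half-open intervals — is strictly greater than
0.75. "Coverage" is read as breadth rather than mean depth, the standard
viromics detection criterion. Counts are summed over all member contigs of
a vOTU (the aggregation rule is not dictated by the procedure; summation
preserves total reads) and normalised to reads per kbp of representative per
million sample reads. The detection-filtered matrix feeds the community
statistics; the unfiltered count matrix feeds the temporal pipeline, which
deliberately keeps sub-threshold counts.

## Majority-rule taxonomy

Ranks are walked realm → family; a label is assigned when strictly more than
50% of the genes *annotated at that rank* agree (unannotated genes do not
dilute the vote), and the first rank without a strict majority — and all
deeper ranks — become "Unknown &lt;deepest assigned ancestor&gt;". Votes are
taken on the representative's genes by default (`pool_genes = TRUE` pools
all members; whether the vote should span members is not determined by the
procedure, so it is exposed as configuration). Source environment uses the
same strict majority over environment-labelled genes with a fixed
four-category vocabulary.

## Community statistics

All statistics are implemented from their defining formulas so that they can
be verified against independent oracles:

* Shannon diversity in nats, Pielou evenness H/ln S, Chao1
  S + F1(F1−1)/(2(F2+1)) (integer counts only).
* The community distance is Euclidean on centred log-ratio (CLR) transformed
  relative abundances; the CLR pseudocount defaults to half the smallest
  nonzero value (standard compositional practice; the choice is not
  dictated). Bray-Curtis is available as an alternative.
* NMDS minimises Kruskal stress-1 by alternating isotonic regression of
  configuration distances on dissimilarity ranks with Guttman-transform
  majorization; 20 restarts from classical scaling plus seeded jitter,
  best restart reported. Stress is non-increasing across iterations within
  a restart by construction.
* ANOSIM R uses mid-ranked distances; PERMANOVA uses the Gower
  decomposition of squared distances into total and within-group sums.
  P-values enumerate all distinct relabelings exhaustively when there are
  at most 10,000 of them, otherwise use random permutations with the
  add-one rule (p is never reported as 0); the permutation count (default
  9,999) and seed are always recorded.
* bioenv standardises the environmental variables, searches all non-empty
  subsets up to a size cap (with a combinatorial guard above 20 variables),
  and reports the subset whose Euclidean distances maximise the Spearman
  correlation with the community distances.
* The paired Wilcoxon signed-rank test drops zero differences, uses
  mid-ranks, and computes the exact two-sided p for n ≤ 25 by dynamic-
  programming convolution over all 2^n sign assignments (a normal
  approximation with tie correction above).

## Temporal clustering

Counts are divided by median-of-ratios size factors (computed over features
positive in every sample, falling back to per-sample positive-feature
medians, normalised to geometric mean 1), log(1+x) transformed, linearly
detrended per feature over the sample index, and standardised to Z-profiles;
profiles constant after detrending are dropped. The upstream study cites a
count-normalisation package without parameters, so this normalise/detrend/
scale chain is a documented stand-in with each sub-step inspectable, not a
reproduction of any specific code.

PAM k-medoids (greedy BUILD, best-improvement SWAP, objective provably
non-increasing per swap) partitions the profiles on Euclidean distances.
Model selection scans k over 1..20 for both PAM and Ward-linkage
hierarchical partitions, computes within-cluster sums of squared distances,
and takes as the elbow region the last k whose marginal SSE drop still
exceeds 5% of the curve's total range, plus its neighbours, from both
curves. The raw maximum of the second difference was rejected as the region
locator because any hierarchically structured community places it at k = 2
regardless of the true number of dynamic groups; the flattening point
matches the narrative logic of "the steepest declines end here, compare
silhouettes of the bracketing k". Average silhouette then picks the final k
among the candidates.

Cluster profiles report the mean Z trajectory per cluster and
viral-family / AMG-pathway totals Z-scored across clusters, with absences
flagged.

## Virus-host network

MAG quality is classed strictly (high: completion > 90 and contamination
< 5; medium: > 50 and < 10; else fail). Host predictions are filtered to
pairs of clustered vOTUs and passing MAGs — predictions against reference
genomes outside the MAG set are dropped and counted — with duplicate pairs
collapsed to the best score. The order-level summary counts MAGs and vOTUs
per host order and lists viruses linked to more than one order (flagging
phylum/class spans). The exclusion of viral contigs from MAGs prior to host
prediction is treated as a documented precondition on the MAG table, not a
step implemented here.

## The synthetic study-design generator

The generator emulates the inputs of the real survey with known ground
truth: 2 sites × 8 dates, one low-salinity freshwater pulse per site (the
last date, salinity forced below 32 ppt), two consecutive post-freeze winter
dates, and 40 planted vOTUs in 5 temporal clusters by default. Choices a
practitioner should know:

* Abiotic variables are drawn from site-specific normal distributions whose
  means/SDs are taken from the published two-site monitoring table (the
  non-pulse salinity means 70.1/47.7 ppt with pulse means 2.57/16.05 ppt
  reproduce the 61.7/43.7 ppt site means, hence the 17.9 ppt contrast, in
  expectation); the parameters are recorded in the written file header.
* Ancestor sequences are i.i.d. uniform over ACGT; members mutate from the
  ancestor at rate 0.02 (sibling identity ≈ 0.96, coherent at the 0.95
  threshold), and a tenth of ancestors derive from another ancestor at rate
  0.2 to exercise near-threshold separation. No codon or genome
  architecture is simulated; taxonomy lives in the annotation table.
* Temporal archetypes are disjoint *active windows* (baseline 0.8, active
  20.8) rather than overlapping smooth bumps: bloom-and-decline windows are
  the shape of the real dynamic groups (pre-freeze, post-freeze, pulse), and
  disjointness makes the planted number of groups well defined. The
  pulse-responsive cluster is boosted ×4 in the pulse sample while other
  clusters are suppressed ×0.4 (freshwater homogenisation); the
  freeze-responsive cluster is boosted ×4 in the post-freeze samples.
* Counts are negative binomial with dispersion 0.3 (over-Poisson noise
  typical of metagenomic counts) around abundance × length(kbp) ×
  depth(millions). Planted absences receive depth-scaled low-level
  background counts (mean 8 per 10 M reads) because read mapping almost
  never yields exact zeros; this also keeps the median-of-ratios size
  factors in their valid regime (most features non-differential per
  sample). Detection stays truthful because background breadth never
  exceeds 0.6.
* Predictor sensitivities (0.90–0.95) and false-positive rates (0.02–0.05)
  give realistic ensemble behaviour; 15% of calls report trimmed variants
  to exercise the retain-shortest rule.

What passing recovery tests show — and what they do not: the generator
plants substitution-only divergence (no indels or rearrangements), cleanly
separated dynamic groups, and honest per-contig counts (no multi-mapping
ambiguity). Recovery at ARI ≥ 0.95 (vOTUs) and ≥ 0.9 (temporal clusters)
therefore demonstrates correctness of the pipeline's logic under its own
assumptions, not performance on real assemblies, where strain mosaicism,
chimeras, and mapping ambiguity degrade all of these steps.

## Problem sizes and numerical choices

Tests and the acceptance script run desk-scale problems chosen to exercise
every code path while keeping the full suite in minutes: 24–40 planted
vOTUs of 10–12 kb, 16 samples, 20 seeds for the temporal-recovery sweep,
500 simulations for permutation-test calibration (nominal 0.05 within two
Monte-Carlo standard deviations), and oracle comparisons on 1.2–3 kb
sequences where full dynamic programming is cheap. Degenerate inputs
(all-zero vectors, single groups, empty FASTA, k > n) raise errors rather
than guessing; tie-breaks (shortest-variant, equal-ANI representatives,
equal silhouettes) are all lexicographic/earliest so that every stage is a
deterministic function of its inputs and the recorded seed.

## Known limitations

The sequencing-scale results of the motivating survey (tens of thousands of
vOTUs, ANOSIM R on real communities, NMDS stress of real ordinations)
require the deposited raw reads and are outside desk scale; this package
demonstrates the machinery on synthetic fixtures. The ANI engine targets
the substitution-dominated divergence regime of dereplication; highly
rearranged or indel-rich pairs are better served by dedicated aligners.
Multi-mapping reads are not modelled; the abundance aggregation rule would
need revisiting for real BAM-derived counts.
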