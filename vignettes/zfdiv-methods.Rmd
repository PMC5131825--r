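---
title: "Methods behind zfdiv: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind zfdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfdiv)
```

`zfdiv` measures the functional diversity of C2H2 zinc-finger transcription
factors along four axes — genomic binding sites, DNA-binding motifs,
protein–protein interactions, and transcriptional response — and compares
those axes with each other. This vignette documents the statistical models
behind each stage, the parameters that matter, the design choices made where
the methodology was genuinely open, and what the synthetic validation does
and does not demonstrate.

## Peak sets

**Replicate merging.** ChIP-seq summits from biological replicates lying
within 50 bp of each other (the `distance` parameter) are collapsed by
single-linkage: the relation "within 50 bp" is applied transitively per
chromosome, so a chain of summits 40 bp apart merges into one peak even
though its ends are more than 50 bp apart. The merged score is the sum of
the constituent scores; the merged summit is the score-weighted mean of the
constituent summit coordinates, rounded to the nearest integer with ties
toward the lower coordinate; the merged interval is re-centred on the
merged summit with the widest constituent width. Merging is idempotent,
which the tests assert.

**Jaccard similarity.** Binding similarity between two experiments is the
base-pair Jaccard — intersection over union of covered bases after each set
is internally merged (the bedtools convention), not a peak-count Jaccard;
base-pair weighting is insensitive to how a long enriched region happens to
be split into peaks. At the protein level the entry is the maximum over all
replicate-pair combinations, which treats replicates as noisy draws of one
underlying site set. `pair_fraction()` reports the fraction of
distinct-protein pairs at or above a threshold (default τ = 0.2).

**Replicate specificity.** An experiment with at least one replicate is
"specific" when, ranking all other experiments by Jaccard, the top-ranked
one belongs to the same protein. An exact rank tie is resolved in the
replicate's favour for peaks (ties there mean disjoint-from-everything
degenerate sets) but against the bait for AP-MS profiles, where a tie
signals a shared contaminant; both choices are warned about or documented in
the function help.

**Composite background.** Experiment-specific ChIP backgrounds are modelled
as a non-negative mixture of candidate input tracks on fixed-width genome
bins: weights minimise ‖Aw − y‖₂ subject to w ≥ 0, solved by the
Lawson–Hanson active-set algorithm (via `pracma::lsqnonneg`). Tracks are
library-size normalised before fitting (each column scaled to unit sum) and
the fitted composite is rescaled to the target library size; fitting on
proportions rather than raw counts keeps deeply sequenced inputs from
dominating on depth alone. The bin size (default 1 kb in the binning
helper's sense — callers supply the binned counts) and the normalisation
are exposed because the original pipeline's exact construction is not
public; the NNLS solution itself is checked in the tests against a grid
search over the weight space.

## Motifs

**Scanning.** Motifs are position weight matrices over A/C/G/T. Scores are
per-position log₂ odds against the background with a pseudocount ε = 0.01
added to both matrix and background (log base and ε are conventional
choices; results are insensitive to ε well below the column probabilities).
Both strands are scanned; ties break to the leftmost position, then the +
strand, making scans deterministic. Windows containing N score −∞.

**Dinucleotide-shuffled null.** The null for motif evaluation preserves
sequence composition at the dinucleotide level exactly: the
Altschul–Erickson algorithm walks a random Eulerian path through the
dinucleotide multigraph, conserving all 16 dinucleotide counts, the length,
and the first and last base. Runs of non-ACGT characters are held fixed and
the intervening segments shuffled independently. One shuffle is paired with
each real sequence (a paired design) rather than pooling shuffles; pairing
keeps per-sequence composition matched, which is the point of the null.

**AUROC.** The discriminability of a motif for a protein's binding sites is
the AUROC of best-hit scores, real versus shuffled, over the ±250 bp around
the summits of the top 500 peaks by score (both `n_top` and `flank` are
parameters; the synthetic worlds use the same rule at smaller n). The AUROC
is computed from the Mann–Whitney rank statistic with ties contributing ½,
which the tests verify against exhaustive pair counting. Best-score-per-
sequence (rather than pooling all positions) is used because the question
is whether the *peak* is distinguishable, not each position.

**Central window and affinity cutoff.** The half-width of the region around
summits where hits concentrate is chosen from the grid 10, 20, …, `flank`
bp by minimising a one-sided binomial p-value of the observed fraction of
best-hit centres within ±w against the uniform expectation w/flank; ties go
to the smallest w, and if no candidate survives a Bonferroni-corrected 0.05
the full flank is returned with a `significant = FALSE` flag. The
log-odds cutoff for hit calling is then chosen over a grid of observed
best-score quantiles to maximise enrichment = (hit fraction in the top 20%
of peaks by score) / (hit fraction in the rest), subject to at least 5% of
peaks containing a hit; ties go to the higher (more stringent) cutoff. The
top fraction of 0.2 and the 5% floor are package choices exposed as
arguments — the upstream description names the objective but not these
constants.

## Genomic context

Feature fold-enrichment histograms signed summit-to-nearest-feature
distances and divides, bin-wise, by the same histogram for random points
drawn uniformly on the same chromosomes with matched counts (densities are
compared, so count mismatches cancel); bins with zero random mass are
reported as `NA` rather than infinite. Histone fold-change is the mean
track signal over ±1 kb windows around summits relative to the genome-wide
mean, reported as log₁₀.

ERE enrichment tests whether more top peaks overlap a repeat class than
expected at random. The background probability is the class's genomic
coverage after dilating every instance by half the median peak width on
each side — a closed-form stand-in for "probability a random peak overlaps
the class" that is accurate while coverage is small. When dilated coverage
exceeds 20% the binomial approximation degrades, and the test switches to a
within-chromosome permutation null (length-preserving peak shuffles, 1000
permutations by default, add-one p-values).

SNP depletion compares the SNP count inside a protein's motif-hit territory
(union of hits) with the count in the ±20 bp flank territory (union of
flanks minus any motif base of the same protein, so a base is never counted
twice) by a one-sided binomial test with success probability
motif_bp / (motif_bp + flank_bp); BH correction across proteins at
FDR 0.025, plus a pooled test on the summed counts. Zero total SNPs yields
p = 1 with a warning rather than an error. Unioned (not per-hit)
territories were chosen because overlapping hits would otherwise double-
count flank bases.

## AP-MS interactions

Preys whose summed counts vary little across baits are ubiquitous
contaminants; the filter drops preys with coefficient of variation below
0.5 (exposed as `min_cv`). Interaction strength is an odds ratio: with
pseudocount α = 1 and P preys, the bait-level probability is
q = (c + α)/(T + αP) and the background probability for pair (i, j) is the
analogous proportion over all baits *other than i* where the pair is not
significant. The leave-one-out background is a deliberate choice: it keeps
a bait's own counts out of its own background, which makes log odds ratios
invariant (as α → 0) to rescaling a single bait's library — a property the
tests check. Significance calls come from SAINTexpress AvgP scores at
cutoff 1 when available; otherwise a documented fallback calls a pair
significant when its summed count is ≥5 and at least twice the prey's
proportional expectation. A prey significant in every other bait falls back
to negative-control baits for its background; with no controls anywhere
that is an error, since no background information exists.

The expression-response test compares induced-minus-control changes of
genes with a bound promoter (within 10 kb of the TSS on real data) against
all other genes with a two-sided Wilcoxon rank-sum test, BH-corrected
across baits at FDR 0.01, reporting the direction as the sign of the median
difference.

## Diversity estimation

Any of the similarity measures can be converted to a distance
(1 − similarity; 1 − Pearson on log odds-ratio vectors for PPI profiles;
1 − fractional alignment identity for sequences; the motif distance is
1 − the best mean per-column Pearson correlation over relative offsets with
≥4 aligned columns and both orientations). PAM (k-medoids) clusters the
distance matrix: BUILD greedily seeds k medoids, SWAP applies the best
single medoid exchange until none improves, and all ties break to the
lowest index so results are deterministic. Because SWAP is a local search,
small instances (≤2000 candidate medoid sets, e.g. n = 20 at k = 2) are
instead solved exactly by enumeration — cheap, and it makes the tiny-case
behaviour provably optimal. Partition quality is the mean silhouette
s(i) = (b − a)/max(a, b), with members of singleton clusters scored 0
(Rousseeuw's convention). The estimated number of distinct profiles is the
largest k whose silhouette is at least 95% of the maximum over k ∈ 2…k_max
(k_max defaults to min(n − 1, 100)); an all-zero silhouette profile (e.g. a
zero distance matrix) is flagged degenerate and returns k_max. An
average-linkage hierarchical variant is provided as a robustness check.
Cross-parameter correlation vectorises the upper triangles of two or more
similarity matrices over shared entity pairs (optionally a subset, e.g.
paralog pairs) and reports pairwise Pearson correlations with listwise
missing-value handling.

## Neutral codon evolution

Each base of each simulated domain accrues a Poisson(rate × years) number
of substitution events applied sequentially, each replacing the base with
one of the other three uniformly. The defaults are a mammalian neutral rate
of 2.2 × 10⁻⁹ substitutions/site/year over 2 × 10⁷ years on 23-codon
domains (the canonical C2H2-ZF repeat span; the length is exposed, and
`neutral_evo_sensitivity()` sweeps 21–28 codons). Two closed forms anchor
the simulation: the fraction of sites with ≥1 event is 1 − e^(−rt), and the
fraction of sites whose base differs at the end follows the 4-state chain
with back-mutation, (3/4)(1 − e^(−4rt/3)); the tests require agreement with
both within Monte-Carlo error. A transition/transversion-biased model was
deliberately left out: the quantity of interest is a back-of-envelope
survival estimate, and the uniform model is the assumption under which the
closed forms hold. Note the per-residue change fraction is independent of
domain length by construction — only the per-domain stop-accrual fraction
moves with the length sweep.

## The synthetic world

`sim_world()` generates every input with planted ground truth:

* **Genome** — first-order Markov chain over A/C/G/T (a 4×4 transition
  matrix); sufficient for dinucleotide-level realism, which is exactly what
  the shuffle null cares about; higher-order structure is not modelled.
* **Binding** — proteins are assigned to clusters; sites come from three
  disjoint pools (global, per-cluster, private) sized so the expected
  base-pair Jaccard matches the configured within-cluster (default 0.5) and
  between-cluster (default 0.02) targets, exactly so when jitter and
  dropout are off. Replicates are jittered copies of the truth: summit
  noise round(N(0, 10 bp)) and dropout probability 0.1 — no replicate noise
  model is published, so these are package defaults chosen to look like
  well-behaved ChIP replicates. Each cluster carries one sharp planted PWM
  (dominant base 0.85); an instance drawn from it is written into the
  genome at 70% of summits. Proteins of one cluster share their PWM, which
  mirrors how paralogous zinc-finger proteins share motifs.
* **Annotations** — non-overlapping ERE instances per class, TSS points,
  DHS intervals; a fraction (0.3) of each cluster's sites is relocated into
  its preferred ERE class, giving the enrichment tests true signal. SNPs
  are Bernoulli per base (density 0.005/bp) thinned by the depletion factor
  (default 0.3) inside planted motif occurrences; all synthetic SNPs are
  treated as common.
* **AP-MS** — planted bait–prey modules with Poisson counts (mean 30,
  modulated per pair by a log-normal factor with SD 0.8 so every bait keeps
  an individual profile that its replicates share); ubiquitous contaminant
  preys at mean 20 per replicate in every bait including negative controls;
  background mean 0.2 elsewhere. The contaminant mean matters: the CV
  filter's 0.5 threshold separates cleanly only when contaminants are
  reasonably abundant — a Poisson mean near 4 summed counts sits exactly at
  CV 0.5 and cannot be reliably separated by any calibration.
* **Expression** — one gene per TSS, baseline N(8, 1) on the log scale,
  condition noise SD 0.5, and a +1 shift of bound-promoter genes in the
  matching induction. The bound-promoter radius used by `sim_world()` is
  500 bp rather than the 10 kb used on real data: at desk-scale genome
  sizes a 10 kb radius would mark every gene bound, leaving no comparison
  group; 500 bp keeps the bound fraction near 25% at the synthetic gene
  spacing.

Passing the planted-recovery tests demonstrates that each statistic detects
the structure it is designed to detect at realistic effect sizes, and that
the estimators are calibrated under their nulls. It does not demonstrate
performance on real data: real peak sets have width and score
distributions, repeat families, chromatin confounders and batch structure
that the generator does not emulate, and real AP-MS backgrounds are not
Poisson. The generator's role is correctness and power verification, not
benchmarking.

## Numerical choices and problem sizes

All coordinates are 0-based half-open everywhere, including on disk (BED
column 7 stores the summit as an offset from the interval start, the MACS
convention). Determinism: every stochastic function takes a seed;
`sim_world()` derives fixed per-stage offsets from the config seed, so one
seed pins the whole world. Degenerate inputs are defined rather than
accidental: empty∪empty Jaccard is 0, zero-SNP depletion tests give p = 1
with a warning, zero-random-mass enrichment bins are `NA`, and all-zero
distance matrices return the degenerate-flagged k_max.

The shipped tests run the study's procedures at reduced problem sizes
chosen to exercise the same code paths with comfortable statistical margins:
synthetic genomes of 0.1–0.6 Mb over 2 chromosomes, 6–12 proteins in 2–3
clusters with 60–150 sites each, 50-seed recovery batches, 300–500-run null
calibrations, and 10⁵ domains (6.9 M bases) for the neutral-evolution
figures. On one CPU the full suite completes in under two minutes.

## Known limitations

* The ERE binomial background treats peaks as randomly placed given only
  chromosome and length; regional biases (GC, mappability) are not
  modelled — the permutation branch mitigates, within chromosomes only.
* The odds-ratio formula is a principled reconstruction of a published
  idea whose exact algebra is not public; α and the significance fallback
  are exposed so alternative conventions can be swapped in.
* PAM above the exact-enumeration limit is a local search; different
  implementations can land in different local optima on hard instances.
* The motif distance (best-offset column correlation) is a documented
  package choice; no particular published metric is being reproduced.
* `sequence_identity_distance()` uses default global-alignment scoring;
  for distant homologs a substitution-matrix-aware distance would be
  preferable.
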