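# zfdiv

Multiparameter functional-diversity analysis of C2H2 zinc-finger (C2H2-ZF)
transcription factors.

C2H2-ZF proteins are the largest class of human transcription factors, and
their functional diversity spans several weakly coupled axes: where they
bind the genome (ChIP-seq peak sets), what sequence they prefer (PWM
motifs), which cofactors they recruit (AP-MS protein–protein interactions),
and how target genes respond when they are induced (expression). `zfdiv`
implements the quantitative machinery needed to measure diversity along each
axis and to compare the axes with each other, together with a synthetic-data
generator that plants known structure into every input so the whole pipeline
can be validated end to end without any external downloads.

## What it computes

* **Peak-set analysis** — replicate summits within 50 bp are merged into
  single peaks (score = sum of constituent scores, summit = score-weighted
  mean coordinate); pairwise binding similarity is the base-pair Jaccard
  `J(A, B) = |A ∩ B| / |A ∪ B|` over covered bases, maximised over
  replicate pairs; replicate specificity asks whether an experiment's
  nearest neighbour by Jaccard is its own replicate. Composite ChIP
  backgrounds are fit by Lawson–Hanson non-negative least squares on binned
  counts.
* **Motif evaluation** — log₂-odds PWM scanning on both strands; paired
  dinucleotide-preserving shuffles (Altschul–Erickson) as a
  composition-matched null; AUROC of real vs shuffled peak sequences from
  the Mann–Whitney statistic; a binomial search for the most centrally
  enriched window around summits; an affinity-score cutoff maximising the
  enrichment of motif-containing peaks among high-score peaks; hit calling.
* **Genomic context** — fold-enrichment of binding sites around TSS/DHS
  relative to random points; log₁₀ histone fold-change around sites;
  fraction of top peaks overlapping each endogenous-retroelement (ERE)
  class, with one-sided binomial/permutation enrichment tests (BH FDR);
  depletion of common SNPs inside motif hits versus ±20 bp flanks
  (one-sided binomial, BH FDR, plus a pooled test).
* **AP-MS interactions** — coefficient-of-variation filtering of
  ubiquitous preys; spectral-count odds ratios against the background
  probability of seeing a prey in non-interacting baits; replicate profile
  specificity by Pearson correlation; activator/repressor classification of
  baits from curated prey annotations; a Wilcoxon test for coherent
  expression response of bound-promoter genes (±10 kb of the TSS).
* **Diversity estimation** — PAM (k-medoids) clustering of any distance
  matrix; mean silhouette values; the estimated number of distinct profiles
  as the largest k retaining ≥95% of the maximum silhouette;
  cross-parameter Pearson correlation of similarity measures over entity
  pairs.
* **Neutral evolution** — a Monte-Carlo simulation of unselected C2H2-ZF
  coding sequence: every base accrues Poisson(rate × years) substitutions
  (uniform to the other three bases), and the simulation reports the
  fraction of amino-acid residues changed and the fraction of domains
  acquiring an in-frame stop.

## Worked example

```r
library(zfdiv)

cfg   <- sim_world_config(seed = 42)   # 12 proteins, 3 planted clusters
world <- sim_world(cfg)

sim <- jaccard_matrix(world$binding$peaks)
sim
#> <zf_similarity> 12 x 12, value_kind = jaccard
#>        ZNF001 ZNF002 ZNF003 ZNF004 ZNF005 ...
#> ZNF001  1.000  0.421  0.421  0.415  0.029
#> ZNF002  0.421  1.000  0.394  0.388  0.032
#> ...

pair_fraction(sim, 0.2)
#> [1] 0.2727273
replicate_specificity(world$binding$peaks)$fraction
#> [1] 1

estimate_profile_count(similarity_to_distance(sim))
#> <zf_profile> estimated number of profiles: 3 (max silhouette 0.386)

simulate_neutral_evolution(seed = 1)
#> <zf_neutral_evo> r*t = 0.044 substitutions/site
#>   AA residues changed: 9.41% (SE 0.019%)
#>   domains with a stop: 11.48% (SE 0.101%)
```

The generator planted three binding clusters (within-cluster Jaccard target
0.5, between-cluster 0.02); the similarity matrix shows exactly that block
structure, and the 95%-of-max silhouette rule recovers the planted cluster
count of 3. The neutral-evolution run says that after 20 My at the default
mammalian neutral rate, ~9.4% of residues in an unselected 23-codon
zinc-finger domain change and ~11.5% of domains pick up a stop codon —
i.e., unselected domains survive largely intact for tens of millions of
years.

Most results are tibbles, and fitted/summary objects come with
`tidy()`/`glance()` and `autoplot()` methods:

```r
library(ggplot2)
autoplot(sim)                                          # similarity heat map
autoplot(estimate_profile_count(similarity_to_distance(sim)))  # silhouette profile
```

`run_pipeline(cfg, out_dir = "out")` executes every stage on a synthetic
world and writes FASTA/BED/MEME/TSV outputs plus a JSON manifest with the
seed, parameters and output checksums.

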