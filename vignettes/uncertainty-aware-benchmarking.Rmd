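---
title: "Uncertainty-aware benchmarking of mRNA–lncRNA classifiers: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-aware benchmarking of mRNA-lncRNA classifiers: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncentropy)
```

# The problem

Coding-potential classifiers assign each transcript a probability of being
protein-coding, and different tools frequently disagree — especially for
lncRNAs, whose sequences are heterogeneous and whose annotations churn
between database releases. Aggregate metrics (accuracy, F1) hide *where*
tools disagree and *why*. This package implements an uncertainty-aware
benchmarking analysis: it decomposes the uncertainty of a classifier
ensemble per transcript, stratifies transcripts into low- and high-entropy
groups, tests which genomic features (classical sequence/ORF features,
transposable-element content, non-B DNA motifs) associate with each group,
and quantifies global feature contributions with probability-space Shapley
attributions from random-forest models.

# The uncertainty decomposition

For a transcript scored by $M$ tools with oriented coding probabilities
$p_1, \dots, p_M$:

* mean coding probability $\bar p = \frac1M \sum_m p_m$;
* predictive entropy $H_{pred} = -[\bar p \log_2 \bar p +
  (1-\bar p)\log_2(1-\bar p)]$, in bits, with $0\log_2 0 := 0$; it is 0 at
  $\bar p \in \{0, 1\}$ and 1 at $\bar p = 0.5$;
* expected entropy $H_{exp} = \frac1M \sum_m H(p_m)$, the mean of the
  individual tools' entropies;
* disagreement $I_{dis} = H_{pred} - H_{exp}$, the mutual-information
  component of ensemble uncertainty.

$I_{dis} \ge 0$ by concavity of the binary entropy (Jensen), it is 0 iff
all tools report the same probability, and it reaches 1 bit when confident
tools split evenly ($H_{pred} = 1$, $H_{exp} = 0$). The decomposition
separates *shared* uncertainty (all tools unsure: high $H_{exp}$) from
*disagreement* (tools individually confident but contradictory: high
$I_{dis}$).

```{r}
ensemble_profile(rbind(consensus = c(0.5, 0.5, 0.5, 0.5),
                       split = c(1, 1, 0, 0)))
```

Tools whose positive class is the lncRNA class are first reoriented
(`orient_scores()`): $p_{coding} = 1 - p_{raw}$, with the decision
threshold mirrored alongside. A score exactly at the threshold labels the
transcript coding; the convention is arbitrary and documented here because
upstream tools do not state one. Transcripts not scored by every tool are
excluded (`exclude_incomplete()`) before any ensemble statistic.

## Stratification

Within each reference class, transcripts below the 10th percentile of
$H_{pred}$ form the *low-entropy* group; transcripts above both the 90th
percentile of $H_{pred}$ and the 90th percentile of $I_{dis}$ form the
*high-entropy* group; everything else is intermediate. Two numerical
choices matter:

* **Percentile convention.** Percentiles interpolate linearly over order
  statistics (index $q(N-1)$, zero-based — `stats::quantile()` type 7).
  This is the convention under which the bottom-decile rule applied to the
  published class sizes (66,376 protein-coding and 45,276 lncRNA) yields
  exactly the published low-entropy group sizes (6,638 and 4,528), which is
  how the convention was pinned down.
* **Strict inequalities.** Both group rules use strict `<` / `>`, so a
  transcript exactly at a threshold is intermediate.

## Agreement and performance

`agreement_category()` classifies each transcript as unanimously correct,
discordant, or unanimously incorrect against the reference label, flagging
near-consensus cases (one or two dissenting tools). `evaluate_predictions()`
reports balanced accuracy (mean of per-class recalls) and macro-averaged
precision/recall/F1 — the right summary under the cohort's class imbalance.
A class never predicted gets precision 0 and is flagged rather than
silently dropped.

# Cohort construction

The benchmark set is built to minimize label noise and train/test leakage:

1. **Label stability**: only transcripts present in two annotation releases
   with the same protein-coding/lncRNA biotype in both
   (`intersect_releases()`); biotypes outside the two classes are excluded.
2. **Redundancy reduction**: from each sequence cluster (CD-HIT `.clstr`
   format) the longest member is kept, ties broken by lexicographically
   smallest id (`select_cluster_representatives()`). Clustering itself is
   external; only its output format is consumed.
3. **Balanced folds** (`make_fold_splits()`): both classes are partitioned
   into $k = 5$ folds after a seeded shuffle (remainders to lowest-index
   folds). Training on fold $i$ uses the other $k-1$ minority partitions
   plus an equal-size seeded sample of majority transcripts drawn outside
   fold $i$'s majority partition — so training is exactly class-balanced.
   The test set is the held-out minority partition plus every majority
   transcript not sampled for training, preserving the cohort's imbalance.
   Each transcript belongs to exactly one fold's *strict held-out*
   partition, and all out-of-fold statistics use only that fold's
   prediction, so every transcript is evaluated exactly once.

The test-set definition deserves a note: with a 5-fold split of the
majority class alone, per-fold test sets would hold only 20% of coding
transcripts, but balanced training necessarily leaves a large unsampled
majority remainder; assigning that remainder to the test set is the only
reading that reproduces the published per-fold totals (72,896 training,
39,368 test from class counts 66,703/45,561), and it is what
`make_fold_splits()` implements.

# Feature extraction

## Repeat features (`parse_repeatmasker_out()` and friends)

RepeatMasker `.out` files are parsed with 1-based inclusive query
coordinates preserved. Overlapping hits on a transcript are resolved
greedily by Smith–Waterman score (ties: longer span, then smaller begin):
a candidate fully covered by accepted spans is dropped; a partial overlap
is trimmed to its largest single uncovered segment. The published analyses
resolve overlaps "by alignment scores and annotation quality" without
printing the exact rule; the trim/drop rule here is this package's
codification, isolated behind `resolve_overlaps()` (idempotent,
overlap-free output) so it can be swapped. Fragments sharing the
RepeatMasker ID column aggregate into elements (summed length, fragment
count, class from the highest-scoring fragment).

Transcript-level features follow a fixed, versioned schema
(`repeat_feature_schema()`): total/per-class counts and coverage
fractions, presence flags, per-family counts, fragmentation and inter-hit
gap statistics, the longest repeat-free stretch (flanks included), per-kb
normalized counts, and length-weighted mean divergence. The upstream
analysis catalogs 170 curated features; the exact enumeration is not
public, so this package implements the named feature groups and exposes
the schema as machine-readable metadata instead of chasing a count.

## Non-B DNA features (`intersect_motifs()`, `compute_nbd_features()`)

Motif calls (A-phased, direct, inverted and mirror repeats, short tandem
repeats, Z-DNA, triplex, G-quadruplex) arrive as BED intervals (0-based
half-open) and are assigned to every gene body they overlap by at least
1 bp, clipped to the gene for length statistics; a call can serve several
genes, and strand is ignored. Overlapping calls are deliberately *not*
resolved — a locus can support several non-B structures — so total
coverage can exceed 1. Triplex motifs are their own type and are not
double-counted as mirror repeats. Per-type presence/count/length/gap
statistics plus global diversity, count and coverage follow the fixed
schema in `nbd_feature_schema()`.

# Enrichment analysis

`preprocess_features()` drops constant and all-missing features and
expands categoricals to one indicator per level (no reference level — the
tests are symmetric in levels). Continuous features are then clustered
(`cluster_features()`) on the distance $d = 1 - |\rho_{Spearman}|$; the
absolute value treats anti-correlated features as equally redundant, a
choice the source analysis leaves open. Ward linkage is applied to this
precomputed distance (Ward's Euclidean assumption is knowingly stretched,
as in the source analysis); the cut height maximizes the mean silhouette
width over 25 evenly spaced heights between the smallest and largest merge
heights, ties resolved toward fewer clusters. One representative per
cluster is kept — the largest absolute effect size by default, a seeded
random member for the attribution stage, with user-forced winners (e.g.
transcript length) taking precedence.

Tests are matched to feature kind: Mann–Whitney U with the centered
Vargha–Delaney effect $cVDA = A - 0.5 \in [-0.5, 0.5]$ for continuous
features ($A$ computed by the rank-sum identity; exact null distribution
when $n_x n_y \le 400$ without ties, otherwise normal approximation with
tie correction and no continuity correction), and chi-squared (no
continuity correction, one formula across table shapes) with Cramér's V
and the odds ratio (Haldane +0.5 only when a cell is zero) for
indicators. P-values are BH-adjusted *within each comparison family*
(low-vs-high; lncRNA-vs-coding within low; within high) — the family
structure is not stated upstream, and per-comparison adjustment is the
conservative reading. Significance: adjusted $p < 0.01$. Non-negligible
effect: $|cVDA|$ or $V > 0.1$ by default (a figure-legend convention);
the stricter 0.15 used in some summaries is a config alternative.

# Global importance

One random forest per fold is trained on the representative features plus
indicators, on that fold's balanced training ids only. Forest
hyperparameters are not stated upstream; defaults here are 500 trees,
$\sqrt p$ feature subsampling, minimum leaf 1, all seeded and exposed in
`forest_config()`. The decision threshold defaults to 0.5 with optional
per-fold Youden-J recalibration on training out-of-bag votes (the source
analysis reports a recalibrated threshold of 0.548 on its data).

Attributions (`explain_forest()`) are exact path-dependent tree Shapley
values, computed in compiled code over the forest's own structure: each
tree contributes its leaf vote (1 = coding), node covers come from routing
the bootstrap in-bag training rows down each tree, and the polynomial-time
path algorithm yields each feature's Shapley value under the tree's
conditional expectations. Because the forest probability is the mean leaf
vote, attributions are in probability units and satisfy
$\text{baseline} + \sum_i \phi_i = f(x)$ exactly; the package enforces
this to $10^{-6}$ and the test suite cross-checks the implementation
against brute-force Shapley enumeration on small trees. Explanations are
only ever computed on a fold's strict held-out transcripts (fold hygiene),
pooled into mean-|SHAP| global importance with per-fold spread
(`summarize_importance()`), and viewable per transcript as a top-10 +
aggregated-remainder waterfall (`top_contributions()`). An interventional
(background-data) mode is deliberately not offered: the path-dependent
form matches the probability-space contract above and keeps the
attribution self-contained.

`embed_2d()` provides the 2-D t-SNE used for visual inspection of the
feature space: exact (dense) affinities, perplexity 30 and 1000 iterations
by default, deterministic given a seed. It is inspection plumbing, not a
statistic; no geometric property of the embedding is asserted anywhere.

# The synthetic cohort generator

`simulate_cohort()` generates, from one master seed (each artifact derives
its own stream, so artifacts are independently reproducible):

* **Predictions**: transcript $t$ carries a latent signal
  $s_t = (2c_t - 1)\,\kappa\,u_t$ with $u_t \sim U(0.3, 1)$ for core
  transcripts and $u_t \sim U(0, 0.1)$ for a *boundary* subpopulation;
  tool $m$ reports $p_{tm} = \mathrm{logistic}(\lambda_m s_t +
  \varepsilon)$, $\varepsilon \sim N(0, \sigma_m^2)$. This is the minimal
  model producing both a calibrated consensus and boundary-driven
  disagreement; boundary transcripts get near-zero signal rather than
  flipped labels, which reproduces the qualitative observation that
  high-entropy transcripts sit at the class boundary.
* **Features**: redundant continuous blocks (one latent per block,
  per-feature noise sd 0.2, class shift per block) to exercise clustering
  and representative selection; Bernoulli categoricals with class rates.
* **Annotations**: two release tables with a biotype-churn fraction;
  CD-HIT-dialect clusters of near-duplicates; RepeatMasker-format repeat
  hits (presence rates 0.3 for coding and 0.7 for lncRNA, the reported
  real-data presence rates; 1–3 elements per transcript, some written as
  two fragments sharing an ID); non-B DNA motif BED calls within per-gene
  bounds; random-sequence FASTA. Every planted annotation's summary
  statistics are recorded as ground truth and must round-trip exactly
  through the parsers and feature extractors.

Defaults (600 coding + 400 lncRNA, 8 tools, boundary fraction 0.15,
signal scale 4, tool gains 0.8–1.2, tool noise 1, churn 0.05) were chosen
once as a desk-scale cohort with realistic tool accuracies (~0.9 balanced
accuracy) and are not tuned per analysis. What the generator does *not*
emulate: realistic nucleotide composition (sequences are uniform random),
the idiosyncrasies of specific published tools, correlated tool errors
beyond the shared latent signal, and genome-scale class imbalance. Tests
passing on this cohort therefore validate the *analysis machinery* —
formulas, rules, round-trips, calibration — not claims about real
transcriptomes.

# Problem sizes and determinism

The test suite and analysis scripts run at deliberately desk-scale sizes,
chosen as the smallest sizes at which each property is sharply testable:
Monte-Carlo checks of the entropy decomposition use $10^5$ random
ensembles; null calibration of the enrichment pipeline uses 100 seeded
replicates at 100 + 100 transcripts; effect-size recovery uses 2,000 per
group; attribution checks use forests of 300–500 trees on hundreds of
transcripts. Every random draw flows from an explicit seed; identical
configurations produce byte-identical outputs, which the pipeline
manifest (md5 per output) makes checkable.

# Known limitations

* The overlap-resolution rule and the exact 170/178-feature catalogs are
  this package's codifications of procedures whose full specifications are
  not public; both sit behind single functions with versioned schemas.
* Ward linkage on a non-Euclidean correlation distance is a pragmatic
  convention, not a theoretically clean choice.
* Path-dependent Shapley values condition on the tree's own cover
  distribution; with strongly correlated features, attributions split
  credit in proportion to how often the forest uses each copy.
* The generator's tools err independently given the latent signal; real
  tool families (shared features, shared training sets) show correlated
  errors, which would raise $H_{exp}$ relative to $I_{dis}$.
* Per-tool threshold recalibration beyond Youden-J, and regression
  modeling of entropy on features, are out of scope.
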