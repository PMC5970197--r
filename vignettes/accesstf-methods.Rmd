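---
title: "Predicting bound TF motifs from chromatin accessibility and ranking factors with TFScore"
author: "AccessTF authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting bound TF motifs from chromatin accessibility and ranking factors with TFScore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AccessTF)
```

## The problem

Accessible chromatin regions mapped by DNase-seq are created by
transcription factors bound at sequence motifs, but a genome-wide motif
scan (e.g. FIMO against a PWM library) produces vastly more matches
than are actually occupied in any given cell state. This package
addresses two linked questions:

1. **Which motif matches are bound in vivo?** Answered per motif with a
   posterior binding probability, without arbitrary cut-offs on motif
   quality or accessibility.
2. **Which transcription factors matter for a biological transition**
   (the motivating system is tamoxifen-induced Src transformation of
   MCF-10A breast epithelial cells)? Answered with TFScore, an additive
   rubric over four orthogonal lines of evidence.

## The binding model

Each motif match $i$ carries four observables:

* $f_i = (\mathrm{FIMO\ score}_i - 10)/10$, clamped into $[0,1]$ — raw
  scores below 10 or above 20 occur, and the model's feature range is
  the unit interval;
* $d_i = 1/(1 + \mathrm{TSS\ dist}_i/1000)$ — proximity of the motif
  midpoint to the nearest annotated TSS, 1 at the TSS, 0.5 at 1 kb;
* $c_i$ — mean per-base conservation (e.g. placental-mammal PhastCons)
  over the motif, uncovered bases defaulting to 0;
* $n_i$ — the *smaller* of the DNase-seq tag counts in the 200 bp
  immediately upstream and downstream of the motif. Taking the minimum
  of the two flanks is deliberate: motifs at the edge of an accessible
  region have tags on one side only and are rarely bound, so a
  symmetric-evidence statistic suppresses those false positives.

The binding state $b_i$ is hidden. The prior is logistic in the motif
features,

$$\log\frac{y_i}{1-y_i} = \beta_0 + \beta_1 f_i + \beta_2 d_i + \beta_3 c_i,
\qquad y_i = P(b_i = 1),$$

and the tag count is emitted from one of two negative-binomial
components,

$$P(n_i \mid b_i = k) = \binom{n_i + K_k - 1}{n_i}(1-r_k)^{K_k} r_k^{n_i},
\qquad k \in \{0, 1\},$$

with mean $K_k r_k/(1-r_k)$. The NB's overdispersion is essential:
empirical window tag counts have variance far above their mean in both
the bound and unbound populations. All four logistic coefficients are
estimated, including the conservation term $\beta_3$.

### Fitting

`fitAccessTF()` runs EM. Initialization follows the tag counts: motifs
in the top 5% of $n$ start as bound (responsibility 1), the rest as
unbound; ties at the cutoff are all included, and an all-equal count
vector is rejected as degenerate. The E step computes
responsibilities in log space (component likelihoods floored at
1e-300; if both underflow, the prior is returned for that motif). The
M step solves two weighted maximum-likelihood problems with standard
tools: a fractional-response logistic fit (`glm.fit`, quasi-binomial)
for the $\beta$s, and an L-BFGS-B optimization over
$(\log K, \mathrm{logit}\, r)$ for each NB component, started from
weighted method-of-moments estimates (with a Nelder-Mead polish if the
line search stalls, and a guarantee never to return a point worse than
its start, preserving the M-step contract). Convergence is declared
when the relative change in observed-data log-likelihood falls below
`tol` (default 1e-6, `maxIter` 500); the trajectory is checked to be
non-decreasing at every iteration and the fitter aborts if it ever
drops beyond numerical tolerance. After convergence the components are
relabelled if needed so "bound" is the high-mean one. Prediction on
new motifs (`predictPosterior()`) is a single E-step pass.

The model is fitted per motif set (one PWM or one factor family) and
per time point; training uses a random 10,000-motif sample with a
disjoint 10,000-motif sample held out for evaluation
(`splitTrainTest()`), scaled down proportionally for smaller inputs.

Hard "bound" calls use a stringent posterior cutoff, default
$\gamma \ge 0.99$; the cutoff is configurable everywhere it appears and
is a reporting convenience, not part of the model.

## Evaluation

Truth labels come from ChIP-seq: a motif overlapping a peak by at
least 1 bp is a positive (`labelByPeakOverlap()`; the minimum overlap
is configurable). `rocAUC()` uses the rank-statistic (Mann-Whitney)
formulation with ties counted one half, so it is invariant under
monotone transforms of the scores. `prAUC()` uses the step-curve
convention — precision summed over recall increments at each distinct
threshold, no interpolation — because PR interpolation conventions
change the number and the choice must be stated for comparability.
`posteriorBinSummary()` bins motifs by predicted probability and
summarizes an independent signal (ChIP read density in the 400 nt
around each motif) per bin, the standard check that predicted
probabilities track measured binding.

## Expression analysis

Differential expression over the 0–24 h course uses a deliberately
simple, replicate-consistent rule: a gene is called when both
biological replicates change more than 1.5-fold, in the same
direction, at one or more time points (`selectDEGenes()`). Fold
changes are **replicate-paired** — replicate $r$ at time $t$ against
replicate $r$ at time 0. This choice (over dividing by the baseline
mean) matters for the FDR estimator below: with a shared baseline the
two replicate fold-change columns of a time point are positively
correlated even under the null, and the permutation null is then
miscalibrated.

`permutationFDR()` estimates the false discovery rate of this rule by
randomizing fold-change values across genes and re-applying the rule.
The randomization reassigns each replicate's *whole trajectory* (its
fold changes at every time point) to a random gene, independently for
the two replicates. This destroys exactly what the rule tests —
agreement between replicates — while preserving each replicate's
across-time dependence (every time point shares the same baseline
sample, so a gene's fold changes are correlated over time under the
null). Permuting each (time, replicate) column independently instead
breaks that across-time dependence and, on simulated null matrices,
overstates the permuted selection count by ~20–40%; the trajectory
scheme measures within a few percent of 1. The study-scale replicate
count is 100,000 permutations; a few hundred reproduce the estimate
within Monte-Carlo error and are used in tests and the pipeline.

Selected genes are clustered by K-means (k = 4, 50 restarts, seeded)
on per-gene profiles: replicate means per time point on the log2
scale, mean-centred and scaled to unit variance. Cluster coherence is
reported as the median pairwise Pearson correlation of member
profiles, with 0.7 the working threshold for "coherent".
`consistentResponseFraction()` computes the fraction of genes
responding in the same direction (beyond 2-fold by default) in *all*
knockdown conditions, against a null that permutes each condition's
column independently.

## TFScore

TFScore is an additive rubric over four criteria; the final score is
the plain sum and factors are ranked by it (ties broken
alphabetically so output is deterministic).

1. **Accessibility gain** (0–5 points at 6 h plus 0–5 at 24 h). For
   each accessible motif (posterior call in at least one time point),
   the flanking read density is summarized as RPM over both 200-nt
   flanks; per PWM the statistic is
   $\sum_i \mathrm{RPM}_{t,i}/\mathrm{RPM}_{0,i}$. The 6 h bins are
   0–600 → +0, then +1 to 1000, +2 to 1500, +3 to 3000, +4 to 5000,
   +5 above. The published 24 h bins are internally inconsistent (the
   +1 bin overlaps the +2 bin as printed), so the default rubric keeps
   the 6 h structure rescaled to the stated first 24 h bin: 2000 /
   4000 / 6000 / 9000 / 15,000. Every edge is configurable through
   `defaultRubric()`, and all bins are closed on their upper edge. A
   motif with zero baseline RPM contributes $\mathrm{RPM}_t/\epsilon$
   with $\epsilon$ the RPM of one read in the baseline library —
   dropping newly opened sites would discard exactly the most
   interesting motifs.
2. **Cluster enrichment** (0–5). Accessible motifs are assigned to the
   nearest expressed gene's TSS within 100 kb (20 kb available via
   `maxDistance`). Per DE cluster, a one-sided Fisher exact test
   compares motif-carrying fractions in the cluster versus expressed
   non-DE genes; the best cluster's $-\log_{10} P$ is binned at
   8 / 11 / 14 / 17 / 20. Using the best (not a combined) cluster is a
   documented choice: the criterion asks whether the factor is linked
   to *any* coherent expression program.
3. **Factor up-regulation** (+15). Granted when the factor's own gene
   passes the up-direction 1.5-fold replicate-consistent rule. The
   large weight reflects that this is direct evidence about the factor
   itself rather than its motif.
4. **Within-family expression** (−10 to +5). Factors sharing a motif
   are distinguished only by expression: with family maximum $E$, a
   member scores +5 at $E$, +3 in $(E/2, E)$, +0 in $(E/4, E/2]$, −5
   in $(E/6, E/4]$, −10 at or below $E/6$. Boundary closure (upper
   edges inclusive) is a documented choice; ties at the maximum all
   take +5.

## The synthetic study

`simulationScenario()` encodes the study conditions used throughout
testing: 20,000 motifs (10,000 train + 10,000 held out), generative
parameters $\beta = (-2, 1, 2, 1)$, unbound NB$(K=1, r=0.5)$ (mean 1)
and bound NB$(K=5, r=0.8)$ (mean 20) — a ~20-fold separation in
flanking tag counts, chosen so synthetic benchmarks probe the same
regime as real DNase data where bound motifs sit in strong
hypersensitive sites. Features are sampled $f \sim U(0,1)$,
$c \sim \mathrm{Beta}(2,2)$, and $d \sim U(0.05, 1)$; the lower bound
on $d$ caps the implied TSS distance at ~19 kb so each simulated
motif's own TSS remains its nearest. The expression course covers
0, 1, 2, 4, 8, 12, 16, 24 h with two replicates, 2,000 genes by
default, 10% differentially expressed across four trajectory
archetypes (continuous up, early up saturating at 2 h, intermediate up
saturating at 12 h, continuous down) with true fold changes in
\[2, 4\] and replicate noise SD 0.1 on the log2 scale.

`simulateGenomeFixture()` realizes a scenario as files: motifs are laid
on a fixed-pitch grid of loci on one pseudo-chromosome, wide enough
that counting windows never overlap between motifs and each motif's
TSS (placed at its simulated distance) is its nearest. Each motif
receives its simulated tag count in *both* flanks, a constant
conservation score over its interval, and — if truly bound — a
ChIP-like peak, so evaluation labels equal true states and feature
extraction on the files reproduces the simulated table exactly.
Everything is a deterministic function of the scenario seed, down to
the emitted bytes.

What the generator does **not** emulate: overlapping motifs of
different PWMs, irregular gene density, fragment-length artefacts,
mappability gaps, chromosome-scale covariation of conservation and
accessibility, and array/sequencing normalization effects. Passing
tests therefore demonstrate correctness of the algorithms under the
model's own assumptions, not performance on real data.

## Numerical and design notes

* Coordinates are Bioconductor-convention GRanges (1-based, closed)
  internally; BED (0-based half-open) and FIMO (1-based inclusive) are
  converted at the I/O boundary. A tag's position is its 5' end (BED
  start for `+`/unstranded reads, end for `-`); tag strand is
  otherwise ignored, and flanking windows are defined on the reference
  strand regardless of motif strand.
* Conservation over uncovered bases defaults to 0 (conservative);
  overlapping bedGraph intervals are an error rather than averaged.
* Window counting truncates at the chromosome start; counts are
  integer by construction even though the abstract feature range is
  continuous.
* Region classification by histone marks uses a fixed precedence
  (K27ac∧K4me3 promoter → K27ac enhancer → K4me1 primed →
  K9me3/K27me3 repressed → other), making categories mutually
  exclusive and exhaustive.
* Problem sizes in the test-suite and pipeline defaults (thousands of
  motifs, hundreds of genes, hundreds of permutations) are chosen so a
  complete run takes minutes on one core while every statistical check
  retains comfortable Monte-Carlo margins; the model-scale defaults
  (20,000 motifs, 10,000/10,000 split, 100,000 permutations) remain
  the scenario and function defaults.

## Known limitations

* One motif set at a time: no joint occupancy model across PWMs, no
  footprint-shape information within the accessible region.
* The posterior threshold for "bound" calls is a convention (default
  0.99), not an error-rate guarantee.
* TFScore is a rubric: it rank-orders candidates for follow-up, and
  its bin edges — taken from the published scheme, including the
  corrected 24 h edges — are not fitted to data.
* The permutation FDR assumes genes are exchangeable under the null;
  gene-specific variance structure (common on arrays) would make it
  optimistic.
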