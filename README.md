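# AccessTF

Predicting in-vivo transcription-factor binding at genome-wide motif
matches from DNase-seq chromatin accessibility, and ranking
transcription factors by their predicted importance for a biological
transition.

Genome-wide PWM scans (FIMO) yield millions of motif matches, almost
all unbound in any given cell state. This package scores every match
with a posterior probability of being bound, then aggregates the bound
motifs — together with differential accessibility, differential
expression and factor expression — into a per-factor importance score.
It is aimed at regulatory-genomics analysts working with DNase-seq (or
similar accessibility) data plus expression time courses, and was
built around an inducible model of breast cellular transformation.

## The model

Each motif match *i* has features *f* (normalized PWM score,
`(FIMO score − 10)/10` clamped to [0, 1]), *d* (TSS proximity,
`1/(1 + dist/1000)`), *c* (mean PhastCons conservation) and *n* (the
smaller of the DNase tag counts in the 200 bp flanks — motifs at the
edges of accessible regions get tags on one side only and are rarely
bound). Binding *b<sub>i</sub>* is hidden:

- prior: logit *P*(*b<sub>i</sub>* = 1) = β₀ + β₁*f* + β₂*d* + β₃*c*
- emission: *n<sub>i</sub>* | *b<sub>i</sub>* = *k* ~
  NegBin(*K<sub>k</sub>*, *r<sub>k</sub>*), mean
  *K<sub>k</sub>r<sub>k</sub>*/(1 − *r<sub>k</sub>*)

Parameters are estimated by EM (initialized with the top-5% tag-count
motifs as bound), and the posterior *P*(*b* = 1 | *f*, *d*, *c*, *n*)
is the per-motif output. On top of this, **TFScore** ranks factors by
four criteria: accessibility gain at bound motifs (0–5 points at 6 h
and at 24 h), motif enrichment near differentially expressed gene
clusters (0–5, one-sided Fisher exact test binned on −log₁₀ *P*),
up-regulation of the factor itself (+15), and expression relative to
the factor's motif family (−10 to +5). The total is the plain sum.

A seeded synthetic-data module emulates every input (FIMO tables, tag
BEDs, conservation bedGraph, TSS tables, ChIP-like peaks, expression
matrices), so the full pipeline runs and is tested without any
external download.

## Worked example

Simulate the default synthetic study (20,000 motifs, bound motifs with
~20× the unbound flanking tag counts), fit on 10,000 motifs, and
evaluate the held-out 10,000:

```r
library(AccessTF)

scen   <- simulationScenario(seed = 1)
motifs <- simulateMotifDataset(scen)
split  <- splitTrainTest(nrow(motifs), seed = 1)
fit    <- fitAccessTF(motifs[split$train, ], seed = 1)
fit
#> AccessTFFit: 10000 motifs, 58 EM iterations (converged)
#>   final log-likelihood: -31164.8998
#> AccessTFParams
#>   logistic prior: beta0=-2.017, beta1=1.027, beta2=2.044, beta3=0.9068
#>   unbound NB: K0=0.948 r0=0.524 (mean 1.04)
#>   bound   NB: K1=5.289 r1=0.7899 (mean 19.9)

post  <- predictPosterior(fit, motifs[split$test, ])
truth <- motifs$b[split$test] == 1
rocAUC(post$gamma, truth)   # 0.997
prAUC(post$gamma, truth)    # 0.998
```

The generative parameters were β = (−2, 1, 2, 1), unbound mean 1,
bound mean 20 — the fit recovers them closely, and held-out
discrimination against the true binding states is near-perfect.

Scoring factors with the rubric (component scores as returned by the
`criterion*` functions):

```r
comp <- data.frame(pwm = c("STAT", "CTCF"), gene = c("STAT3", "CTCF"),
                   c1_6h = c(3, 0), c1_24h = c(4, 0), c2 = c(2, 1),
                   c3 = c(15, 0), c4 = c(5, 5))
totalTFScore(comp)
#>    pwm  gene c1_6h c1_24h c2 c3 c4 total rank
#> 1 STAT STAT3     3      4  2 15  5    29    1
#> 2 CTCF  CTCF     0      0  1  0  5     6    2
```

A factor that gains accessibility at its bound motifs, is enriched
near a DE cluster, and is itself up-regulated totals 29 and ranks
first.

`runPipeline(list(outdir = "run"))` executes the whole flow
(simulate → extract features → fit → predict → evaluate → DE/cluster →
TFScore) with plain-file handoff and an MD5 manifest;
`inst/scripts/accesstf.R` exposes the same steps from a shell.

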