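---
title: "Merging operon predictions with diel expression: model and methods"
author: "dieloperon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging operon predictions with diel expression: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dieloperon)
```

## The model

Prokaryotic operon predictors work from genome sequence alone and tend to
fragment long operons. When a whole-genome expression time series over the
24-h day is available, the fragments of a true operon should move together:
they share one transcript, so their log-expression curves should nearly
coincide after mean-centering. `dieloperon` turns that expectation into a
supervised decision rule for *pairs of adjacent predicted operons*
("priors"): merge the pair if a classifier, trained on operon-like versus
operon-impossible gene groups from the same data set, scores the pair's
expression coherence above 0.5.

### Curve distance

Two profiles sampled at shared hours $t_1 < \dots < t_n$ are compared by the
area between their piecewise-linear interpolants,

$$d(f,g) \;=\; \frac{1}{t_n - t_1}\int_{t_1}^{t_n} \lvert f(t) - g(t)\rvert\,dt .$$

Each segment is integrated exactly: with endpoint differences $d_i$,
$d_{i+1}$ and width $\Delta t$, a non-crossing segment contributes the
trapezoid $\Delta t\,(|d_i|+|d_{i+1}|)/2$ and a sign-crossing segment the two
triangles $\Delta t\,(d_i^2+d_{i+1}^2)/(2(|d_i|+|d_{i+1}|))$. The result is a
genuine metric on the interpolants (non-negativity, symmetry, triangle
inequality — property-tested), is invariant to adding a common constant to
both profiles, and scales linearly with the time axis unless normalized.
Correlation-based similarity is deliberately avoided: correlation is
insensitive to amplitude and ill-behaved for flat profiles, both common in
diel data.

Whether the "right" normalization is by span, by $n-1$, or by nothing is not
fixed by the method's description; we divide by span so distances are
comparable across studies with different sampling windows. Any fixed positive
rescaling of all distances rescales all four features together, which the
classifiers either absorb exactly (tree splits, standardized kNN) or absorb
through refitting, so the choice affects feature units, not decisions.

### Features, training sets, candidates

A gene group becomes the 4-vector (min, mean, sd, max) of its pairwise
distances (sample sd, $n-1$ denominator, 0 for a single pair). Positive
instances are priors with at least two usable profiles and at least one diel
gene, featurized over *all* within-group pairs. Negative instances are
windows of consecutive genes with at least one gene on each strand (such a
window cannot be one operon, since co-translation requires one strand) and at
least one diel gene. Merge candidates are adjacent prior pairs with no
intervening genes, one contig, one strand, and a diel gene in *each* prior;
they are featurized over cross-prior pairs only. The within-prior exclusion
is applied to candidates and not to training instances: only candidates
contain sub-groups whose internal distances were already judged coherent by
the original predictor, and mixing those in would let a candidate smuggle in
low distances that carry no information about the *junction* being tested.
This reading of an ambiguous rule is a design choice of this package.

"Diel" is a pure range threshold: a gene is diel when its log2 range reaches
$\log_2(\text{min\_fold})$, default 2× (1 log2 unit). The call is invariant
to centering; no harmonic regression or rhythmicity p-value is involved. A
warning (not an error) is raised when the sampling span is outside 20–28 h,
since the 2×-over-a-day definition presumes roughly one cycle.

### Classification

Five classifier specs ship in the registry: ridge-regularized logistic
regression, a logistic model tree (LMT), an information-gain decision tree,
Gaussian naive Bayes, and k-nearest-neighbors. They are evaluated by
stratified 5-fold cross-validation with one shared, seeded fold assignment;
the selection metric is plain accuracy, with balanced accuracy as the first
tie-break (honoring "best on both classes") and registry order as the final,
deterministic one. The winner is refitted on all instances and applied to the
candidates; a candidate is merged when its score is strictly greater than
0.5. Scores are monotone classifier outputs, not calibrated probabilities.

The LMT here grows a binary tree by information gain and fits a ridge
logistic model on all four features at each leaf; depth 0 therefore *is*
plain logistic regression (asserted to 1e-9). This is a simplification of
the original LogitBoost-based LMT induction; equivalence with that
implementation's scores is not claimed, and the harness — not any one
classifier — is the point: the best model is organism-dependent and should be
re-selected per data set.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_fold` | 2 | diel threshold, fold change over the day |
| `normalize_by_span` | TRUE | divide ABLIM by the sampling span (h) |
| `k_folds` | 5 | CV folds (stratified) |
| `threshold` | 0.5 | acceptance threshold on the score, strict `>` |
| `size_policy` | match_positive | negative window sizes: empirical positive-size distribution (seeded) or fixed `k` |
| `max_negatives` | n positives | cap on negative instances (balanced training) |
| LMT `max_depth`, `min_leaf`, `lambda` | 3, 15, 0.01 | tree depth, leaf support, ridge penalty |

Numerical choices worth knowing: the ridge penalty is applied to every
coefficient including the intercept, which keeps pure-leaf logistic fits
finite and deterministic (the base-rate property then holds to ~1e-3 rather
than exactly, which is irrelevant at these penalty sizes); IRLS uses
step-halving on the penalized deviance and a 1e-10 convergence tolerance;
tree split ties break to the lowest feature index then lowest threshold;
fold assignment, negative-window draws and all generator draws derive from
the run seed, and no output embeds a timestamp, so identical configurations
are byte-identical.

Degenerate inputs: profiles with any missing value are structurally retained
but unusable — they are never diel, never enter distances, and instances or
candidates touching them are skipped/dropped with a logged reason. A score of
exactly 0.5 is not merged. Single-gene priors may be candidate members but
cannot be positive instances.

## The synthetic world

The generator emulates the shape of the motivating study — a draft
cyanobacterial genome and an 8-timepoint diel log2-expression study — with
planted ground truth:

- transcription units laid out per contig; each is a multi-gene operon with
  probability `p_operon_gene` = 0.5 (sizes 2:0.5, 3:0.3, 4:0.2), else a
  singleton; consecutive units switch strand at rate 0.5;
- each unit is diel with probability 0.79 (the fraction reported for
  *Crocosphaera*); a diel unit gets a phase $\varphi \sim U[0,24)$ and gene
  $i$ the profile $A\sin(2\pi(t-\varphi-\varepsilon_i)/24) + N(0,\sigma^2)$,
  with amplitude $A = 1$ log2 unit (a 2× swing, so diel by definition),
  gene-level jitter $\varepsilon_i \sim N(0, 0.5^2)$ h and noise
  $\sigma = 0.1$; arrhythmic genes are pure noise;
- 8 timepoints every 3 h; default 4,407 genes (tests scale this down for
  runtime, stated per test);
- each true operon of size ≥2 is split once, at a uniform internal boundary,
  with probability `p_split_prior` (default 0.15) into two priors — the pairs
  that *should* merge; adjacent same-strand priors from different units are
  the pairs that should not.

What the generator does **not** emulate: read-count noise and library-size
effects (values are idealized log2 abundances), asymmetric or damped
waveforms, operon-internal promoters, and annotation errors. A green
recovery test therefore establishes that the pipeline's logic and wiring are
correct under the stated statistical model — not that real genomes will
yield the same accuracy.

Two deliberate choices in the recovery tests: `diel_fraction = 1`, because
the recovery criteria presuppose that every planted split pair reaches the
classifier, and a split pair in an arrhythmic operon is excluded upstream by
the method's own "≥1 diel gene per prior" rule; and a 6-h minimum phase
separation between consecutive diel units in the *noiseless* test (via
`min_phase_sep_h`, a rejection re-draw), because with zero noise the only
way two distinct adjacent operons can be indistinguishable is exact phase
coincidence, and the criterion is stated for separated phases.

## Known limitations

- Candidate pairs are classified independently; chains of 3+ fragments merge
  only through re-running the pipeline on merged output.
- The negative-set construction (window sizes, overlap, count) is
  configurable because the original construction is underdetermined;
  `match_positive` with non-overlapping windows avoids a size-confounded
  classifier but is one choice among several defensible ones.
- The two prior-operon file dialects are pragmatic stand-ins; no attempt is
  made to parse any particular database's export format.
- Organisms with weak or uniform diel variation will yield nearly identical
  4-vectors for positives and negatives, and the cross-validation accuracy —
  reported before any merge decision is made — is the intended warning sign.
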