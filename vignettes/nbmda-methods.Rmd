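---
title: "Methods: neighborhood-based scoring of miRNA-disease associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neighborhood-based scoring of miRNA-disease associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbmda)
```

## The problem and the model

Curated miRNA-disease catalogues are extremely sparse bipartite networks:
most diseases have a handful of confirmed miRNA partners, and the
overwhelming majority of pairs are simply unobserved rather than known
negatives. `nbmda` treats candidate prioritisation as bipartite link
prediction under the *local community paradigm*: a pair is plausible when
it closes many quadrangles (length-3 paths `d_i - m_k - d_l - m_j`) and
when the interior nodes of those quadrangles - the pair's common
neighbours (CN) - are themselves densely interlinked (local community
links, LCL). Per network the index is

$$\mathrm{CJC}(i,j) = \frac{\mathrm{CN}\cdot\mathrm{LCL}}
{|N(d_i)\cup N(m_j)|},$$

and the final score geometric-averages the index over three networks: the
observed one (MDA) and two KNN-densified variants (SDA, from disease
neighbours; SMA, from miRNA neighbours). The densification is what makes
a quadrangle-based index workable at catalogue sparsity - without it many
true pairs have no quadrangle at all and every such score collapses to 0.

The modelling assumptions, in order of importance:

* *guilt by association*: similar diseases share miRNAs and functionally
  similar miRNAs share diseases; both the KNN voting and the Gaussian
  kernels encode this.
* the unobserved pairs used as the negative pool during evaluation are
  mostly true negatives (realistic at ~3% positive density, but it means
  reported AUCs slightly understate performance).
* side-information matrices (ontology-derived disease similarity, miRNA
  functional similarity) are informative where present; where an entry is
  zero the model falls back to the interaction-profile kernel rather than
  trusting the zero.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `k` | neighbours consulted per entity | 3 | small k keeps votes local; accepted range is any `k` below the axis size |
| `vote_threshold` | agreeing neighbours needed to add an edge | `floor(k/2)+1` = 2 | a *strict majority*; the augmentation is deliberately conservative |
| `delta` | semantic decay per ontology level | 0.5 | halves an ancestor's contribution per step; in (0, 1] |
| `gamma_prime_m`, `gamma_prime_d` | kernel bandwidth bases | 1 | realised bandwidth divides by the mean squared profile norm, so the kernel is invariant to overall catalogue density |
| `folds`, `repeats` | cross-validation design | 5, 100 | repeats cut fold-assignment noise; the spread is retained in `per_repeat_aucs` |
| `similarity_mode` | `dynamic` / `static` | `dynamic` | see below |

All parameters live in one validated object (`nbmda_config()`), can be
read from flat YAML (`load_config()`), and are snapshotted into every
evaluation result so a report can be reproduced from its own settings.

## Numerical and procedural choices

Several choices are genuinely open in this model family; the package
fixes them as follows.

**Seed-edge removal and degrees.** When scoring a pair whose edge is
already known, that edge is removed *in each network independently*
before anything is counted, and the degrees in the CJC denominator are
taken after removal. Post-removal degrees keep the index identical for
known and unknown pairs embedded in the same surrounding topology, which
is what lets cross-validation rank held-out edges fairly. The
denominator is implemented as `deg(d_i) + deg(m_j)`; in a bipartite graph
the two neighbour sets are disjoint so this equals the union size (the
test suite asserts this against a genuine set union).

**Union augmentation.** Recommended edges are unioned with the original
ones rather than replacing them: the construction exists to densify a
sparse network, and discarding known evidence would be perverse. "Most
of the K neighbours" is read as a strict majority (2 of 3 at the
default); the threshold is exposed because other readings are defensible.

**LCL counting.** Every network edge whose two endpoints are both common
neighbours counts, whether or not that edge lies on a quadrangle through
the seed pair - the literal "links that exist between CNs".

**Ties.** KNN neighbour selection breaks similarity ties by ascending
index, so runs are deterministic; ranked prediction lists break score
ties the same way. AUCs use mid-ranks throughout.

**Zero guards.** CJC is defined as 0 when the seed pair is isolated
(0/0); a kernel over an all-zero association matrix errors as degenerate,
while individual all-zero profiles are fine (their kernel rows are still
well-defined). The zero test in similarity integration uses
`|x| <= 1e-12` since primary similarities arrive from files as floats.
Similarity files may be asymmetric or out of [0, 1] by up to 1e-8
(repaired by averaging/clipping); anything worse is treated as data
corruption and errors.

**Dynamic versus static evaluation.** In `dynamic` mode (default) the
kernels, integrated similarities and KNN augmentation are recomputed from
each training matrix, so no information about a held-out edge can reach
the training side; the acceptance tests verify bit-identical training
artefacts when the full matrix is distorted at the held-out entry.
`static` mode computes everything once from the full matrix - cheaper,
and what several published models in this family appear to have done, but
mildly leaky; the mode is recorded in each result's settings.

**LOOCV negative pool and ROC construction.** Each held-out positive is
ranked against every pair unknown in the *full* matrix, rescored in that
iteration. Because the negative pool is recomputed per iteration, the
ROC is built from per-positive hit rates (the fraction of that
iteration's negatives the positive outscores, ties at half): the curve is
the empirical CDF of the complementary hit rate, traced with its step
corners, and its trapezoidal area equals the mean hit rate exactly - the
AUC invariant holds to 1e-9 by construction, not by approximation. The
k-fold AUC is the mean of per-repeat AUCs; since every positive is scored
exactly once per repeat this equals the pooled value.

**Random streams.** Every stochastic operation takes an explicit seed
and restores the caller's RNG state; k-fold repeat `r` draws from
`seed + r`, so any repeat can be reproduced in isolation.

## The synthetic generator

`make_bipartite()` plants an aligned block structure: diseases and
miRNAs fall into `n_blocks` contiguous groups, within-block pairs get
edges with probability `p_in` = 0.5 and cross-block pairs with
`p_out` = 0.02. At the default 30 x 30 with 3 blocks this yields ~150
positives at ~17% density - denser than real catalogues, chosen so toy
networks still contain quadrangles - with a strong planted contrast.
`make_fs()` emulates a functional-similarity resource consistent with
those blocks (0.8 within, 0.1 across, truncated Gaussian noise);
`make_dag()` grows a random rooted tree plus extra forward edges, giving
realistic multi-parent ontology shapes whose semantic similarity is
*uninformative about the blocks* - deliberately, so signal recovery does
not depend on an oracle-quality ontology.

What the fixtures do **not** emulate: the heavy-tailed degree
distribution of real catalogues, curation biases (well-studied diseases
accumulate edges), correlated noise between the similarity resources and
the network, and literature-validation ground truth. Passing the planted
-signal tests therefore shows the pipeline recovers a block signal its
similarity inputs partially encode; it does not certify the headline
AUCs achievable on curated catalogues, which require the external
resources themselves.

## Problem sizes used by the test and acceptance suites

Oracle-equivalence suites run on graphs up to 10 x 10 so the brute-force
quadruple enumerator stays exact and fast; pipeline suites use 30 x 30.
The acceptance script runs LOOCV (~150 iterations with full dynamic
refitting) and 5-fold CV x 5 repeats, plus a permuted-matrix null, in
well under a minute; the per-pair index is computed in compiled code
(`src/cjc.cpp`) with co-degree matrices precomputed once per network,
which is what makes dynamic-mode refitting per held-out edge affordable.

## Known limitations

* Quadrangle counting is O(pairs x network size) even with
  precomputation; scoring a full catalogue-sized matrix (hundreds by
  hundreds) is fine, but dynamic-mode LOOCV over thousands of positives
  at that scale is hours, not minutes.
* Diseases absent from the ontology get zero semantic rows (with a
  warning) and fall back to kernel similarity; no fuzzy name matching is
  attempted - term mapping is the user's responsibility.
* The score is unnormalised (CN x LCL / degrees, then a geometric mean);
  scores are comparable within a run, not across datasets.
* New entities without any known association receive score 0 against
  every partner in MDA (no quadrangle can exist), so the model cannot
  rank them - the KNN augmentation mitigates this only for entities with
  similar, annotated neighbours.
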