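---
title: "Models and methods in phenorank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in phenorank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenorank)
```

This vignette is the package's own account of the science it implements: the
models and their assumptions, the parameters that matter, what the synthetic
generator does and does not emulate, and the numerical and design choices
made where the design was genuinely open.

## Setting

A patient presents with a set of phenotype terms $Q$ drawn from a
single-rooted DAG ontology (is-a edges only). A knowledge base associates
each disease $d_k$ with an annotation set $H_k$ of terms, some carrying a
frequency $p_{tk}$ — the probability that a patient with $d_k$ shows $t$.
Writing $A(S)$ for the ancestor closure of a term set, annotations propagate:
a disease annotated with a specific term implicitly carries every more
general form. All diagnostic methods produce a total ranking of the
knowledge base for a given $Q$, with minimum-rank (competition) ties broken
for display by disease code, so outputs are deterministic.

## Information content and its two conventions

$IC(t) = -\log P(t)$, with $P(t)$ the fraction of diseases annotated with
$t$. The package counts annotations through ancestor closures by default
(`compute_ic(..., closure = TRUE)`): the overlap statistics that consume
$IC$ intersect queries with closures, which presupposes propagated
annotation semantics. Raw (direct-only) counting is available behind the
flag since the convention is not forced by the definitions. Logs are natural
throughout; the base rescales every score monotonically and cannot change a
ranking. Terms annotating no disease get the smallest observed nonzero
probability instead of zero, keeping $IC$ finite for query terms the
knowledge base never uses.

## ICTO

$\mathrm{Sim}(Q \to H_k) = \sum_{t \in Q \cap A(H_k)} IC(t)$, symmetrized by
averaging both directions. Query terms outside $A(H_k)$ contribute exactly
nothing, so the one-sided score is invariant to unrelated ("noise")
phenotypes — a property the test suite asserts over a thousand randomized
trials. Pairwise best-match measures lack this invariance: every extra query
term drags the best-match average.

## PPO

A naive Bayes model over the ontology:
$\log P(d_k \mid Q) \propto \sum_{t \in Q} \log P(t \mid d_k)$, assuming a
flat disease prior and conditional independence of the query phenotypes
given the disease. The conditional takes three forms: the recorded frequency
$p_{tk}$ (or a default $dp$ when unknown) on directly annotated terms; a
propagated value on terms of $A(H_k) \setminus H_k$, computed bottom-up over
$C_k = \mathrm{children}(t) \cap A(H_k)$; and the background $P(t)$
elsewhere. A term that is both directly annotated and an ancestor of other
annotations keeps its direct frequency — the recorded value is evidence, the
propagated one an imputation.

Three propagation rules are provided: `max` (most informative child),
`ind` ($1-\prod(1-p)$, children as independent evidence) and `sum`
(truncated sum). They are ordered $f_{max} \le f_{ind} \le f_{sum}$ at every
ancestor, which the suite verifies on random fixtures. **Defaults:**
`rule = "ind"` — the only rule bounded by the other two that matches the
model's own independence assumption — and `dp = 0.5`, an uninformative
midpoint; the deployed values in the system this package re-implements were
tuned on clinical cases and never published, so both are configuration.
Implementation: one reverse-topological sweep of $A(H_k)$ per disease,
memoized across cases.

**A limitation worth knowing.** Rank-1 self-retrieval (querying a disease's
own annotation set) is *not* guaranteed by PPO. If another disease's closure
contains the entire query with high propagated probabilities while the true
disease records low frequencies (an "occasional" phenotype at 0.17, say),
the likelihood genuinely prefers the covering disease: knowing your
phenotype is rare under your own disease is evidence against you that a
vaguer competitor never supplies. ICTO's reverse direction penalizes the
competitor's unmatched annotation mass, which is why it keeps perfect
self-retrieval where PPO can drop to ~80% top-1 in frequency-rich synthetic
worlds. This is a property of the model, not of the implementation — the
propagation itself is checked exactly against an independent recursive
oracle on dozens of random DAGs.

The gene extension multiplies $\prod_{g \in G} P(g \mid d_k)$ into the
likelihood, with a configurable background ($10^{-3}$) for unlisted
gene–disease pairs; with $G = \emptyset$ it reduces to the phenotype model.

## Few-shot classifiers

Each disease contributes one **standard case**: the multi-hot indicator of
$A(H_k)$ over the column index (union of all closures), labeled with the
disease. Augmentation expands this one-shot training set:

- **Mixup** draws $\lambda \sim \mathrm{Beta}(\alpha, \alpha)$ and forms
  convex combinations of two cases' features and one-hot labels.
- **Random perturbation** applies $K$ operations per sample — remove (never
  the last active term), generalize (replace with a proper ancestor),
  specialize (proper descendant), or add-noise (a term unrelated to every
  active term); operations without an eligible target are skipped with a
  warning.

Defaults (`aug_config()`): 4 Mixup + 4 perturbation samples per disease,
$\alpha = 0.4$, $K = 2$, equal operation mix. None of these counts are
published; they are modest values that exercise every operation while
keeping the training set small.

**CNB** estimates
$\theta_{kj} = (\alpha_j + \sum_{y_i \ne k} x_{ij}) / (\alpha + \sum_{y_i \ne k} \sum_{j'} x_{ij'})$
— the smoothed fraction of phenotype mass in the *complement* of class $k$,
robust when each class has a single genuine example — and ranks by ascending
$\sum_j q_j \log \theta_{kj}$. Laplace smoothing ($\alpha_j = 1$) is the
default. Soft labels are accommodated by weighting row $i$ with
$(1 - y_{ik})$, which reduces to the indicator sum for one-hot labels; the
packaged pipeline nevertheless trains CNB on hard-label data (standards +
perturbation) and reserves Mixup's soft labels for the MLP, where
cross-entropy against soft targets is standard. Queries are ancestor-closed
before encoding, matching the standard-case construction.

**MLP**: one hidden layer (ReLU), softmax output, cross-entropy with soft
targets, L2 penalty, full-batch gradient descent, all seeded — implemented
in the package because no suitable soft-target implementation ships with
this environment, and determinism of the whole pipeline was a requirement.
Defaults: 64 hidden units, learning rate 0.5, 200 epochs, L2 $10^{-4}$.
The best-loss epoch's weights are returned, with a warning when the final
half of training never improved.

## Order-statistics ensemble

Each member ranking contributes a rank ratio $r_i = \mathrm{rank}_i / D$ for
a disease; the sorted vector $r_1 \le \dots \le r_N$ is scored by the joint
CDF of $N$ uniform order statistics,
$Z = N! \int_0^{r_1}\!\!\int_{s_1}^{r_2}\!\!\cdots\int_{s_{N-1}}^{r_N}
ds_N \cdots ds_1$, evaluated by the recursion
$V_k = \sum_{i=1}^k (-1)^{i-1} (V_{k-i}/i!)\, r_{N-k+1}^i$, $Z = N! V_N$.
The ratios must be sorted: the integral is only a CDF over the ordered
region (unsorted input is a contract error, not silently fixed). $Z$ lies in
$[0,1]$, is non-decreasing in every coordinate, and is symmetric in the
members once sorted — permuting the input rankings cannot change the output.

$Z$ is turned into a P-value with a simulated null (sorted iid uniforms),
fitted by moment matching: Beta for $N \le 5$, Gamma for $N > 5$. Moment
matching was chosen over maximum likelihood because it is closed-form,
cheap, and reproducible; the stored simulation also provides an
empirical-CDF fallback (`null_cdf(..., empirical = TRUE)`). Default
$10^5$ samples, seed `20240101`. For $N = 1$ the null is uniform and the
fit recovers Beta(1,1) to within sampling error — a calibration check the
suite runs; for $N = 3$ the fitted CDF stays within Kolmogorov distance
0.02 of its own simulation.

Physician merging converts a short ordered candidate list into a full
ranking — listed diseases get ratios $1/D, \dots, m/D$, all unlisted
diseases the maximally uninformative ratio 1 — and combines it with the
model ranking at $N = 2$. The convention is ours; how the original system
encoded short human lists is not published. An empty list contributes a
constant coordinate and provably preserves the model's order.

## Synthetic worlds

The generator states one world and sticks to it (`sim_config()`):

- ontology: 60 terms, single root, one uniform parent per new node plus a
  20% chance of a second parent (diamond paths); acyclic by construction;
- knowledge base: 20 diseases, 4–8 annotations each, sampled with weight
  $1 + \mathrm{depth}$ (annotation corpora skew specific), pairwise-distinct
  sets unless duplicates are requested;
- frequencies on 50% of annotations, drawn 20% obligate (1.0), 40% very
  frequent (0.895), 30% frequent (0.545), 10% occasional (0.17) — class
  midpoints of the standard frequency subontology, fixture knobs rather
  than claims about real annotation densities;
- cases: a disease's annotation terms (frequency-weighted when sampling a
  subset), with an `imprecision_rate` fraction replaced by proper ancestors
  and a `noise_rate` fraction by terms outside the disease's
  ancestor/descendant cones; cases with fewer than three distinct terms are
  discarded, mirroring the standard evaluation filter. Four presets
  (`noise-low/high`, `imprecise-low/high` at 20%/50%) echo the usual
  corrupted-case regimes.

What this emulates: the combinatorial structure of ontology-annotated
diagnosis — closure overlap, frequency heterogeneity, imprecise and noisy
reporting. What it does not: the scale of a real ontology (13k+ terms), the
long-tailed co-annotation structure of real disease families, correlated
phenotypes, or EHR extraction artifacts. A green test here establishes
correctness of the machinery and qualitative behavior (degradation under
corruption, ensemble robustness), not clinical performance figures.

## Evaluation choices

First-hit rank takes the best rank among multiple true codes; a true disease
absent from the prediction gets sentinel rank $D + 1$, keeping medians
finite while penalizing the miss. Top-k recall is the fraction of cases at
rank $\le k$; medians use the even-length mean convention. Bootstrap
intervals are percentile 2.5/97.5 at 10,000 repetitions — "nonparametric
bootstrap" with no further qualifier means the percentile flavor; BCa was
deliberately not implemented. Method comparisons use the two-sided Wilcoxon
signed-rank with the Pratt treatment of zero differences (zeros ranked, then
removed from the statistic) and a tie/zero-corrected normal approximation;
`stats::wilcox.test` drops zeros instead, so the statistic is computed in
the package and cross-checked against the stats version on zero-free data.

## Numerical and naming decisions

- **MinIC**: the literature definition behind this baseline was not
  recoverable offline; the implemented pair score is the min-normalized
  Resnik ratio $IC(\mathrm{MICA}) / \min(IC(a), IC(b))$ (defined as 1 when
  both ICs vanish), best-match averaged like the other pairwise measures. A
  literal "minimum IC over common ancestors" is degenerate — the root is
  always a common ancestor with IC 0.
- MICA search includes the terms themselves; Lin at two zero-IC terms is 1.
- Propagated probabilities are clamped to $(0,1]$ only by construction —
  the rules cannot leave the interval when inputs are in it.
- CNB scores may reach $-\infty$ when an unsmoothed $\theta$ is zero on an
  active column; ascending ranking treats that as best-possible evidence.
- Every stochastic component (simulation, augmentation, MLP init, null fit,
  bootstrap) takes an explicit seed; the pipeline derives per-component
  seeds from one global seed by a stable hash, so adding a method never
  perturbs another's stream.

## Known limitations

Only is-a edges are honored (no part-of); a single ontology root is
required; equivalence classes for cross-source disease codes must be
supplied, never inferred; the MLP is a deliberately small fully-deterministic
network, not a tuned deep model; and PPO's self-retrieval caveat above
applies whenever recorded frequencies are informative.
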