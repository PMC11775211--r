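# phenorank

Differential diagnosis of rare diseases from phenotype profiles.

Rare-disease patients typically accumulate a set of phenotypic abnormalities —
recorded as terms of a phenotype ontology such as the HPO — long before they
receive a diagnosis. `phenorank` takes such a term set *Q* and a knowledge base
of disease–phenotype annotations (each disease *d* with annotation set *H* and
optional per-phenotype frequencies) and returns a full ranking of candidate
diseases, for clinicians or pipelines doing phenotype-driven diagnosis. It is
aimed at method developers and evaluators: everything, including the data, can
be generated and scored inside the package.

## Models

With A(·) the ancestor closure in the ontology DAG and IC(t) = −log P(t) the
information content of a term (P(t) = fraction of diseases annotated with t
under closure):

- **ICTO** — information-content term overlap:
  Sim(Q→H) = Σ_{t ∈ Q ∩ A(H)} IC(t), symmetrized as
  Sim(Q,H) = ½[Sim(Q→H) + Sim(H→Q)]. The one-sided form is provably
  insensitive to query terms unrelated to the disease.
- **PPO** — probability propagation in the ontology: a naive Bayes model
  log P(d|Q) ∝ Σ_{t∈Q} log P(t|d), where P(t|d) is the recorded frequency
  (or a default *dp*) on annotated terms, a value propagated bottom-up over
  C = children(t) ∩ A(H) on ancestor terms (rules: max, independent-union
  1−Π(1−p), or truncated sum), and the background P(t) elsewhere. A gene
  extension multiplies in P(g|d) over a candidate gene set.
- **CNB / MLP** — few-shot classifiers trained on one "standard case" per
  disease (the multi-hot closure indicator), expanded by Mixup interpolation
  and random perturbation (remove / generalize / specialize / add-noise).
  CNB scores by complement statistics θ_kj; the MLP is a single-hidden-layer
  softmax network.
- **Ensemble** — order statistics over member rankings: each disease's sorted
  rank ratios r₁ ≤ … ≤ r_N give Z = N!·V_N via the recursion
  V_k = Σᵢ (−1)^{i−1} (V_{k−i}/i!) r_{N−k+1}^i; Z is converted to a P-value
  under a simulated null (Beta fit for N ≤ 5, Gamma above) and diseases are
  ranked by ascending P-value.
- **Baselines** — SimGIC, SimUI, term overlap, cosine, and best-match-average
  Resnik / Lin / Jiang–Conrath / MinIC.

An evaluation harness provides first-hit ranks, top-k recall, median rank,
10,000-rep percentile bootstrap intervals, and paired Wilcoxon signed-rank
comparisons (Pratt zero handling).

## Worked example

```r
library(phenorank)

cfg   <- sim_preset("noise-low", seed = 42)       # 20% unrelated query terms
onto  <- sim_ontology(cfg)                        # 60-term single-rooted DAG
kb    <- sim_kb(onto, cfg)                        # 20 annotated diseases
cases <- filter_cases(sim_cases(kb, cfg, n_cases = 50))

diag <- diagnose(cases, kb, methods = c("icto", "ppo", "cnb", "mlp"), seed = 1)
print(diag$predictions$ensemble[[cases[[1]]$case_id]], n = 3)
#> <phb_ranking> method=ensemble, 20 diseases (showing 3)
#>    disease    codes      score rank
#> 1 SIM:0005 SIM:0005 0.01562044    1
#> 2 SIM:0017 SIM:0017 0.01907675    2
#> 3 SIM:0019 SIM:0019 0.11787033    3
cases[[1]]$true_codes
#> [1] "SIM:0005"
```

The consensus puts the generating disease first: its score 0.016 is the
probability, under the null of random rankings, of rank ratios jointly at
least this good across the four members — the smaller, the stronger the
consensus. Evaluating all methods:

```r
ev <- evaluate_diagnosis(diag, cases, n_boot = 1000, seed = 1)
ev$ensemble
#> <phb_eval> n = 50 | median rank 1 | top1 0.860, top3 0.980, top10 1.000
round(ev$ensemble$ci$top3, 3)
#> [1] 0.94 1.00
compare_methods(ev$ppo$per_case_rank, ev$ensemble$per_case_rank)$p_value
#> [1] 0.000935
```

So on this corrupted synthetic set the ensemble diagnoses 98% of cases within
its top 3 (95% CI 0.94–1.00) and outperforms PPO alone significantly.

Ontologies, annotation tables and cases round-trip through OBO / HPOA-style
TSV / JSON-lines readers and writers (`load_obo`, `load_hpoa`,
`merge_sources`, `read_cases_jsonl`, ...), so the same machinery runs on real
HPO releases and annotation downloads. A thin command-line wrapper over these
functions ships in `inst/cli/phenorank.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the full pipeline — synthetic ontology, knowledge base, and the four
corruption scenario presets; all thirteen methods plus the ensemble; top-k
recall and median-rank summaries printed per scenario — and writes the
machine-readable report to `--out`.

## Vignette

`vignettes/methods.Rmd` documents the models, their assumptions, every
tunable parameter with its default and rationale, what the synthetic
generator does and does not emulate, and known limitations.
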