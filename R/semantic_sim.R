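#' Information-content term-overlap similarity (one-sided)
#'
#' Sums the information content of the query terms that fall inside the
#' ancestor closure of the disease annotation set:
#' \deqn{Sim(Q \to H) = \sum_{t \in Q \cap A(H)} IC(t).}
#' Query terms outside A(H) contribute nothing, which makes the one-sided
#' score insensitive to patient phenotypes unrelated to the disease — the
#' property that distinguishes this measure from pairwise best-match scores.
#'
#' @param q character vector of query term CURIEs.
#' @param h character vector of disease annotation term CURIEs.
#' @param ic a `phb_ictable` from [compute_ic()].
#' @param o a `phb_ontology`.
#' @return Non-negative numeric score (nats).
#' @export
icto_one_sided <- function(q, h, ic, o) {
  stopifnot(inherits(ic, "phb_ictable"), inherits(o, "phb_ontology"))
  overlap <- intersect(unique(q), annotation_closure(o, h))
  if (length(overlap) == 0L) return(0)
  sum(ic_of(ic, overlap))
}

#' Symmetric information-content term-overlap similarity
#'
#' Averages the two one-sided scores:
#' \deqn{Sim(Q, H) = \frac{1}{2}[Sim(Q \to H) + Sim(H \to Q)].}
#'
#' @inheritParams icto_one_sided
#' @return Non-negative numeric score.
#' @export
icto_symmetric <- function(q, h, ic, o) {
  (icto_one_sided(q, h, ic, o) + icto_one_sided(h, q, ic, o)) / 2
}

mica_ic <- function(a, b, ic, o) {
  # most informative common ancestor, terms themselves included
  ca <- intersect(c(a, o$anc[[a]]), c(b, o$anc[[b]]))
  if (length(ca) == 0L) return(0)
  max(ic_of(ic, ca))
}

bma <- function(q, h, pair_fun) {
  # symmetric best-match average over a pairwise term score
  s <- outer(seq_along(q), seq_along(h),
             Vectorize(function(i, j) pair_fun(q[[i]], h[[j]])))
  (mean(apply(s, 1L, max)) + mean(apply(s, 2L, max))) / 2
}

#' Baseline semantic-similarity measures
#'
#' The classical ontology-similarity baselines, in two families. Set-based
#' measures compare ancestor closures A(Q) and A(H):
#' `simgic` (IC-weighted Jaccard), `simui` (Jaccard), `term_overlap`
#' (overlap coefficient), `cosine` (Otsuka-Ochiai). Pairwise measures score
#' term pairs through their most informative common ancestor (MICA, the term
#' pair itself included) and aggregate by symmetric best-match average:
#' `resnik` IC(MICA); `lin` 2 IC(MICA)/(IC(a)+IC(b)); `jc` the
#' Jiang-Conrath similarity 1/(1 + IC(a) + IC(b) - 2 IC(MICA)); `min_ic`
#' the min-normalized Resnik score IC(MICA)/min(IC(a), IC(b)) (defined as 1
#' when both terms have zero IC).
#'
#' @param measure one of `"simgic"`, `"simui"`, `"term_overlap"`,
#'   `"cosine"`, `"resnik"`, `"lin"`, `"jc"`, `"min_ic"`.
#' @inheritParams icto_one_sided
#' @return Numeric score; set-based measures and `lin`/`jc`/`min_ic` lie in
#'   \[0, 1\], `resnik` in IC units.
#' @export
baseline_similarity <- function(measure, q, h, ic, o) {
  measure <- match.arg(measure, c("simgic", "simui", "term_overlap",
                                  "cosine", "resnik", "lin", "jc", "min_ic"))
  q <- unique(q); h <- unique(h)
  if (measure %in% c("simgic", "simui", "term_overlap", "cosine")) {
    aq <- annotation_closure(o, q)
    ah <- annotation_closure(o, h)
    inter <- intersect(aq, ah)
    uni <- union(aq, ah)
    return(switch(measure,
      simgic = {
        den <- sum(ic_of(ic, uni))
        if (den == 0) 0 else sum(ic_of(ic, inter)) / den
      },
      simui = length(inter) / length(uni),
      term_overlap = length(inter) / min(length(aq), length(ah)),
      cosine = length(inter) / sqrt(length(aq) * length(ah))))
  }
  check_terms(o, q); check_terms(o, h)
  pair_fun <- switch(measure,
    resnik = function(a, b) mica_ic(a, b, ic, o),
    lin = function(a, b) {
      den <- ic_of(ic, a) + ic_of(ic, b)
      if (den == 0) 1 else 2 * mica_ic(a, b, ic, o) / den
    },
    jc = function(a, b) {
      1 / (1 + ic_of(ic, a) + ic_of(ic, b) - 2 * mica_ic(a, b, ic, o))
    },
    min_ic = function(a, b) {
      m <- min(ic_of(ic, a), ic_of(ic, b))
      if (m == 0) 1 else mica_ic(a, b, ic, o) / m
    })
  bma(q, h, pair_fun)
}

#' Rank knowledge-base diseases by a similarity measure
#'
#' Scores every disease entry against the case's query terms and returns a
#' full ranking (descending score, minimum-rank ties).
#'
#' @param case a `phb_case`.
#' @param kb a `phb_kb`.
#' @param ic a `phb_ictable`.
#' @param method `"icto"` (symmetric), `"icto_one_sided"`, or any measure
#'   accepted by [baseline_similarity()].
#' @return A `phb_ranking`.
#' @export
rank_diseases_by_similarity <- function(case, kb, ic,
                                        method = c("icto", "icto_one_sided",
                                                   "simgic", "simui",
                                                   "term_overlap", "cosine",
                                                   "resnik", "lin", "jc",
                                                   "min_ic")) {
  method <- match.arg(method)
  stopifnot(inherits(case, "phb_case"), inherits(kb, "phb_kb"))
  o <- kb$ontology
  q <- case$query
  score_one <- function(d) {
    h <- names(d$annotations)
    if (length(h) == 0L) return(0)
    switch(method,
      icto = icto_symmetric(q, h, ic, o),
      icto_one_sided = icto_one_sided(q, h, ic, o),
      baseline_similarity(method, q, h, ic, o))
  }
  scores <- vapply(kb$diseases, score_one, 0)
  ranked_prediction(kb, scores, method = method, decreasing = TRUE)
}
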