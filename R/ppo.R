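#' Parameters for probability propagation in the ontology
#'
#' @param dp default conditional probability used for annotations without a
#'   frequency record, in (0, 1).
#' @param rule propagation rule for ancestor terms: `"ind"` treats the
#'   children present in the closure as independent evidence
#'   (1 - prod(1 - p)), `"max"` takes the maximum child probability, and
#'   `"sum"` the sum truncated at 1.
#' @param gene_background fallback P(gene | disease) for gene-disease pairs
#'   absent from the gene evidence table.
#' @return A list of class `phb_ppo_params`.
#' @export
ppo_params <- function(dp = 0.5, rule = c("ind", "max", "sum"),
                       gene_background = 1e-3) {
  stopifnot(is.numeric(dp), dp > 0, dp < 1,
            is.numeric(gene_background), gene_background > 0)
  structure(list(dp = dp, rule = match.arg(rule),
                 gene_background = gene_background),
            class = "phb_ppo_params")
}

#' Propagate annotation frequencies up the ontology for one disease
#'
#' Computes the conditional probability P(t | d) for every term t in the
#' ancestor closure A(H) of the disease's annotation set H. Directly
#' annotated terms take their recorded frequency (or `dp` when the frequency
#' is unknown) — a direct frequency wins even when the term is also an
#' ancestor of other annotations. Each remaining ancestor term receives the
#' propagation rule applied over C = children(t) intersected with A(H),
#' computed bottom-up in reverse topological order.
#'
#' @param disease one disease entry from a `phb_kb` (list with
#'   `annotations`).
#' @param o a `phb_ontology`.
#' @param params a `phb_ppo_params`.
#' @return Named numeric vector over A(H): P(t | d) in (0, 1].
#' @export
ppo_propagate <- function(disease, o, params = ppo_params()) {
  stopifnot(inherits(o, "phb_ontology"), inherits(params, "phb_ppo_params"))
  h <- names(disease$annotations)
  if (length(h) == 0L) stop("cannot propagate a disease with no annotations")
  a <- annotation_closure(o, h)
  prob <- stats::setNames(numeric(length(a)), a)
  direct <- stats::setNames(rep(params$dp, length(h)), h)
  for (t in h) {
    r <- disease$annotations[[t]]
    if (!is.null(r) && !is.na(r$value) && r$value > 0) direct[[t]] <- r$value
  }
  in_a <- stats::setNames(rep(TRUE, length(a)), a)
  # reverse topological order: children before parents
  for (t in rev(o$topo)) {
    if (!isTRUE(in_a[t])) next
    if (t %in% h) {
      prob[[t]] <- direct[[t]]
    } else {
      ck <- o$children[[t]]
      ck <- ck[!is.na(in_a[ck]) & in_a[ck]]
      pc <- prob[ck]
      prob[[t]] <- switch(params$rule,
        max = max(pc),
        ind = 1 - prod(1 - pc),
        sum = min(1, sum(pc)))
    }
  }
  prob
}

#' Rank diseases with the propagation-based naive Bayes model
#'
#' Assuming a flat disease prior and conditional independence of query
#' phenotypes given the disease, each disease is scored by
#' \deqn{\log P(d \mid Q) \propto \sum_{t \in Q} \log P(t \mid d),}
#' where P(t | d) is the propagated profile value when t lies in the
#' disease's annotation closure and the background probability P(t)
#' otherwise.
#'
#' @param case a `phb_case`.
#' @param kb a `phb_kb`.
#' @param ic a `phb_ictable` supplying background probabilities.
#' @param params a `phb_ppo_params`.
#' @param profiles optional precomputed list of propagated profiles (one per
#'   KB disease, in KB order) to amortize across cases.
#' @return A `phb_ranking` (descending log-probability).
#' @export
ppo_rank <- function(case, kb, ic, params = ppo_params(), profiles = NULL) {
  stopifnot(inherits(case, "phb_case"), inherits(kb, "phb_kb"),
            inherits(ic, "phb_ictable"))
  if (is.null(profiles)) profiles <- ppo_profiles(kb, params)
  q <- case$query
  bg <- log(pmax(bgprob_of(ic, q), ic$floor))
  scores <- vapply(seq_along(kb$diseases), function(k) {
    prof <- profiles[[k]]
    v <- prof[q]
    out <- ifelse(is.na(v), bg, log(v))
    sum(out)
  }, 0)
  ranked_prediction(kb, scores, method = "ppo", decreasing = TRUE)
}

#' Precompute propagated profiles for every disease in a knowledge base
#'
#' @inheritParams ppo_rank
#' @return List of named numeric vectors (one per disease, KB order);
#'   diseases without annotations yield an empty profile.
#' @export
ppo_profiles <- function(kb, params = ppo_params()) {
  lapply(kb$diseases, function(d) {
    if (length(d$annotations) == 0L) return(stats::setNames(numeric(0), character(0)))
    ppo_propagate(d, kb$ontology, params)
  })
}

#' Rank diseases from phenotypes plus gene evidence
#'
#' Extends the propagation model with a set of candidate disease genes G,
#' assuming conditional independence between phenotypes and genes given the
#' disease: the score adds `sum(log P(g | d))` over G, with P(g | d) looked
#' up in `gene_prob` and falling back to `params$gene_background` for
#' unlisted pairs. With an empty gene set the ranking equals [ppo_rank()].
#'
#' @inheritParams ppo_rank
#' @param genes character vector of gene symbols (may be empty).
#' @param gene_prob data.frame with columns `gene`, `code`, `prob` mapping
#'   (gene, disease code) pairs to P(g | d); codes must be KB codes.
#' @return A `phb_ranking`.
#' @export
ppo_rank_with_genes <- function(case, genes, gene_prob, kb, ic,
                                params = ppo_params(), profiles = NULL) {
  base <- ppo_rank(case, kb, ic, params, profiles)
  if (length(genes) == 0L) {
    attr(base, "method") <- "ppo_genes"
    return(base)
  }
  idx <- kb_code_index(kb)
  gp <- matrix(params$gene_background, nrow = length(kb$diseases),
               ncol = length(genes),
               dimnames = list(NULL, genes))
  if (!is.null(gene_prob) && nrow(gene_prob) > 0L) {
    for (i in seq_len(nrow(gene_prob))) {
      g <- gene_prob$gene[[i]]
      k <- idx[gene_prob$code[[i]]]
      if (!is.na(k) && g %in% genes) gp[k, g] <- gene_prob$prob[[i]]
    }
  }
  add <- rowSums(log(gp))
  # base is sorted; recompute from per-disease scores in KB order
  primary <- kb_codes(kb)
  base_scores <- base$score[match(primary, base$disease)]
  ranked_prediction(kb, base_scores + add, method = "ppo_genes",
                    decreasing = TRUE)
}

#' Read a gene-evidence TSV
#'
#' Three columns: gene symbol, disease code, probability.
#'
#' @param path TSV path.
#' @return data.frame with columns `gene`, `code`, `prob`.
#' @export
read_gene_evidence <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("expected three tab-separated columns in ", path)
  data.frame(gene = df[[1L]], code = df[[2L]], prob = as.numeric(df[[3L]]),
             stringsAsFactors = FALSE)
}
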