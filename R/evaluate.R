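#' First-hit rank of the true diagnosis
#'
#' When a case carries several true diagnosis codes, its rank is the best
#' (minimum) rank among the prediction entries sharing any of those codes.
#' If no true code appears in the prediction the sentinel `D + 1` is
#' returned with a warning (D = list length), which keeps medians finite
#' while penalizing the miss.
#'
#' @param pred a `phb_ranking`.
#' @param true_codes non-empty character vector of diagnosis codes.
#' @return Positive integer rank.
#' @export
first_hit_rank <- function(pred, true_codes) {
  stopifnot(inherits(pred, "phb_ranking"), length(true_codes) >= 1L)
  r <- rank_of(pred, true_codes)
  if (is.na(r)) {
    warning("no true code present in prediction; sentinel rank D + 1")
    return(nrow(pred) + 1L)
  }
  r
}

#' Point metrics over per-case first-hit ranks
#'
#' Top-k recall is the fraction of cases ranked at or above k; the median
#' rank uses the usual even-length convention (mean of the central pair).
#'
#' @param ranks positive integer vector of first-hit ranks, one per case.
#' @param ks k values for top-k recall.
#' @return List of class `phb_eval` with `top_k_recall` (named numeric),
#'   `median_rank`, `n_cases`.
#' @export
eval_metrics <- function(ranks, ks = c(1L, 3L, 10L)) {
  stopifnot(length(ranks) >= 1L, all(ranks >= 1))
  tk <- vapply(ks, function(k) mean(ranks <= k), 0)
  structure(list(top_k_recall = stats::setNames(tk, paste0("top", ks)),
                 median_rank = stats::median(ranks),
                 n_cases = length(ranks)),
            class = "phb_eval")
}

#' @export
print.phb_eval <- function(x, ...) {
  cat("<phb_eval> n =", x$n_cases, "| median rank", x$median_rank, "|",
      paste(names(x$top_k_recall),
            sprintf("%.3f", x$top_k_recall), collapse = ", "), "\n")
  invisible(x)
}

#' Percentile bootstrap confidence interval for a rank metric
#'
#' Resamples cases with replacement and takes the 2.5/97.5 percentiles of
#' the metric across replicates. Deterministic under the seed.
#'
#' @param ranks per-case first-hit ranks.
#' @param metric `"recall"` (with `k`) or `"median"`.
#' @param k recall cutoff when `metric = "recall"`.
#' @param n_boot bootstrap repetitions (>= 100).
#' @param seed integer seed.
#' @param conf confidence level.
#' @return Numeric `c(lower, upper)`.
#' @export
bootstrap_ci <- function(ranks, metric = c("recall", "median"), k = 10L,
                         n_boot = 10000L, seed = 1L, conf = 0.95) {
  metric <- match.arg(metric)
  stopifnot(n_boot >= 100L, length(ranks) >= 1L)
  if (length(ranks) < 5L) warning("fewer than 5 cases; interval will be wide")
  stat <- if (metric == "recall") function(r) mean(r <= k) else stats::median
  n <- length(ranks)
  withr_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(b) {
      stat(ranks[sample.int(n, n, replace = TRUE)])
    }, 0)
    a <- (1 - conf) / 2
    unname(stats::quantile(reps, c(a, 1 - a), type = 7))
  })
}

#' Compare two methods by the Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test on per-case first-hit ranks, using the
#' Pratt treatment of zero differences (zeros are ranked with the rest,
#' then removed from the statistic) and a normal approximation with tie and
#' zero corrections. With every difference zero the result is
#' `p = 1, statistic = 0`.
#'
#' @param ranks_a,ranks_b paired rank vectors of equal length (>= 6 pairs).
#' @param alpha significance threshold recorded on the result.
#' @return List of class `phb_comparison`: `statistic` (standardized),
#'   `p_value`, `significant`, `direction` (sign of median difference
#'   a - b; negative means method A ranks better).
#' @export
compare_methods <- function(ranks_a, ranks_b, alpha = 0.05) {
  stopifnot(length(ranks_a) == length(ranks_b), length(ranks_a) >= 6L)
  d <- ranks_a - ranks_b
  out <- pratt_signed_rank(d)
  structure(list(statistic = out$z, p_value = out$p,
                 significant = out$p < alpha,
                 direction = sign(stats::median(d)),
                 alpha = alpha),
            class = "phb_comparison")
}

# Pratt (1959) zero-inclusive signed-rank with normal approximation.
pratt_signed_rank <- function(d) {
  n <- length(d)
  n0 <- sum(d == 0)
  if (n0 == n) return(list(z = 0, p = 1))
  r <- rank(abs(d))            # zeros get the smallest ranks (ties averaged)
  wpos <- sum(r[d > 0])
  mu <- (n * (n + 1) / 2 - n0 * (n0 + 1) / 2) / 2
  ties <- table(r[d != 0])
  v <- n * (n + 1) * (2 * n + 1) / 24 -
    n0 * (n0 + 1) * (2 * n0 + 1) / 24 -
    sum(ties^3 - ties) / 48
  if (v <= 0) return(list(z = 0, p = 1))
  z <- (wpos - mu) / sqrt(v)
  list(z = z, p = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Evaluate a set of per-case rankings
#'
#' Convenience wrapper: computes first-hit ranks against each case's true
#' codes, then point metrics and (optionally) bootstrap intervals.
#'
#' @param predictions named list case_id -> `phb_ranking`.
#' @param cases list of `phb_case` (matched by `case_id`).
#' @param ks top-k cutoffs.
#' @param n_boot bootstrap repetitions; 0 disables intervals.
#' @param seed integer seed for the bootstrap.
#' @return A `phb_eval` with an extra `ci` element (named list metric ->
#'   c(lower, upper)) and `per_case_rank`.
#' @export
evaluate_predictions <- function(predictions, cases, ks = c(1L, 3L, 10L),
                                 n_boot = 0L, seed = 1L) {
  ids <- vapply(cases, `[[`, "", "case_id")
  ranks <- vapply(cases, function(cs) {
    pred <- predictions[[cs$case_id]]
    if (is.null(pred)) stop("no prediction for case ", cs$case_id)
    first_hit_rank(pred, cs$true_codes)
  }, 0)
  out <- eval_metrics(ranks, ks)
  out$per_case_rank <- stats::setNames(ranks, ids)
  if (n_boot > 0L) {
    ci <- lapply(ks, function(k) bootstrap_ci(ranks, "recall", k = k,
                                              n_boot = n_boot, seed = seed))
    names(ci) <- paste0("top", ks)
    ci$median <- bootstrap_ci(ranks, "median", n_boot = n_boot, seed = seed)
    out$ci <- ci
    out$n_boot <- n_boot
    out$seed <- seed
  }
  out
}
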