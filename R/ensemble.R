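#' Rank ratios of a disease across method rankings
#'
#' Divides the disease's rank under each method by the knowledge-base size
#' and sorts the ratios ascending — the form the order-statistics Z
#' statistic consumes.
#'
#' @param rankings list of `phb_ranking` over the same disease universe.
#' @param disease a disease code resolvable in every ranking.
#' @return Sorted numeric vector of length `length(rankings)` in (0, 1\].
#' @export
rank_ratios <- function(rankings, disease) {
  stopifnot(length(rankings) >= 1L)
  D <- nrow(rankings[[1L]])
  r <- vapply(rankings, function(rk) {
    if (nrow(rk) != D) stop("rankings cover different disease universes")
    rr <- rank_of(rk, disease)
    if (is.na(rr)) stop("disease ", disease, " absent from a ranking")
    rr / D
  }, 0)
  sort(r)
}

#' Order-statistics Z statistic
#'
#' Given the sorted rank ratios r_1 <= ... <= r_N of one disease across N
#' methods, Z is the probability that N sorted iid uniforms fall jointly
#' below them coordinate-wise — the joint CDF of the N-dimensional uniform
#' order statistic. Small Z means the ratios are jointly nearer the top of
#' the lists than chance produces. Computed by the recursion
#' \deqn{V_k = \sum_{i=1}^{k} (-1)^{i-1} \frac{V_{k-i}}{i!} r_{N-k+1}^i,
#'       \quad V_0 = 1, \quad Z = N! \, V_N.}
#'
#' @param r sorted non-decreasing numeric vector with values in \[0, 1\].
#' @return Z in \[0, 1\].
#' @export
z_statistic <- function(r) {
  n <- length(r)
  stopifnot(n >= 1L)
  if (is.unsorted(r)) stop("rank ratios must be sorted ascending")
  if (any(r < 0 | r > 1)) stop("rank ratios must lie in [0, 1]")
  v <- numeric(n + 1L)
  v[[1L]] <- 1
  for (k in seq_len(n)) {
    i <- seq_len(k)
    v[[k + 1L]] <- sum((-1)^(i - 1) * v[k - i + 1L] / factorial(i) *
                         r[[n - k + 1L]]^i)
  }
  min(max(factorial(n) * v[[n + 1L]], 0), 1)
}

# vectorized over rows of a matrix of sorted ratios (one disease per row)
z_statistic_rows <- function(R) {
  n <- ncol(R)
  V <- vector("list", n + 1L)
  V[[1L]] <- rep(1, nrow(R))
  for (k in seq_len(n)) {
    acc <- 0
    rk <- R[, n - k + 1L]
    for (i in seq_len(k)) {
      acc <- acc + (-1)^(i - 1) * V[[k - i + 1L]] / factorial(i) * rk^i
    }
    V[[k + 1L]] <- acc
  }
  pmin(pmax(factorial(n) * V[[n + 1L]], 0), 1)
}

# n draws of the sorted order statistic of N iid uniforms, via normalized
# cumulative sums of exponential spacings (column-wise, no row apply)
sorted_uniform_rows <- function(n, N) {
  E <- matrix(stats::rexp(n * (N + 1L)), nrow = n)
  CS <- E
  for (j in seq_len(N)[-1L]) CS[, j] <- CS[, j - 1L] + E[, j]
  CS[, N + 1L] <- if (N >= 1L) CS[, N] + E[, N + 1L] else E[, N + 1L]
  CS[, seq_len(N), drop = FALSE] / CS[, N + 1L]
}

#' Fit the null distribution of the Z statistic
#'
#' Simulates Z under the null (ranks uniform and independent across
#' methods: ratio vectors are sorted iid uniforms) and fits a parametric
#' approximation by moment matching — a Beta distribution when `N <= 5`, a
#' Gamma distribution when `N > 5`. The fitted CDF turns a Z value into an
#' approximate P-value for consensus ranking.
#'
#' @param N number of member methods.
#' @param mc_samples Monte-Carlo sample count (a warning below 1000).
#' @param seed integer seed; the fit is deterministic given it.
#' @return A list of class `phb_null`: `family` (`"beta"` or `"gamma"`),
#'   `par1`/`par2` (shape1/shape2 or shape/rate), `N`, `mc_samples`,
#'   `seed`, and the simulated `z` sample (for empirical-CDF fallback).
#' @export
fit_null <- function(N, mc_samples = 1e5, seed = 20240101L) {
  stopifnot(N >= 1L)
  if (mc_samples < 1000) warning("fewer than 1000 null samples; fit will be noisy")
  withr_seed(seed, {
    R <- sorted_uniform_rows(mc_samples, N)
    z <- z_statistic_rows(R)
    m <- mean(z); v <- stats::var(z)
    if (N <= 5L) {
      common <- m * (1 - m) / v - 1
      par1 <- m * common
      par2 <- (1 - m) * common
      family <- "beta"
    } else {
      par1 <- m^2 / v   # shape
      par2 <- m / v     # rate
      family <- "gamma"
    }
    structure(list(family = family, par1 = par1, par2 = par2, N = as.integer(N),
                   mc_samples = mc_samples, seed = seed, z = z),
              class = "phb_null")
  })
}

#' CDF of a fitted Z null
#'
#' @param null a `phb_null`.
#' @param z numeric vector of Z values.
#' @param empirical use the stored simulation's empirical CDF instead of the
#'   parametric fit.
#' @return Approximate P-values in \[0, 1\].
#' @export
null_cdf <- function(null, z, empirical = FALSE) {
  stopifnot(inherits(null, "phb_null"))
  if (empirical) {
    return(stats::ecdf(null$z)(z))
  }
  if (null$family == "beta") stats::pbeta(z, null$par1, null$par2)
  else stats::pgamma(z, shape = null$par1, rate = null$par2)
}

#' Combine method rankings by order statistics
#'
#' For each disease, the sorted rank ratios across the member rankings give
#' a Z statistic; its P-value under the fitted null orders the consensus
#' list (ascending — stronger joint top-ranking first).
#'
#' @param rankings list of at least two `phb_ranking` over the same
#'   knowledge base.
#' @param kb the `phb_kb` the rankings cover.
#' @param null a `phb_null` fitted with `N = length(rankings)`; fitted on
#'   the fly when `NULL`.
#' @return A `phb_ranking` with P-value scores (ascending).
#' @export
ensemble_rank <- function(rankings, kb, null = NULL) {
  stopifnot(length(rankings) >= 2L, inherits(kb, "phb_kb"))
  N <- length(rankings)
  D <- length(kb$diseases)
  primary <- kb_codes(kb)
  ratio_mat <- vapply(rankings, function(rk) {
    if (nrow(rk) != D) stop("ranking does not cover the knowledge base")
    rr <- rk$rank[match(primary, rk$disease)]
    if (anyNA(rr)) stop("disease universe mismatch between rankings and KB")
    rr / D
  }, numeric(D))
  if (D == 1L) ratio_mat <- matrix(ratio_mat, nrow = 1L)
  R <- t(apply(ratio_mat, 1L, sort))
  if (is.null(null)) null <- fit_null(N)
  if (null$N != N) stop("null was fitted for N = ", null$N, ", not ", N)
  z <- z_statistic_rows(R)
  p <- null_cdf(null, z)
  ranked_prediction(kb, p, method = "ensemble", decreasing = FALSE)
}

#' Merge a model ranking with a physician's candidate list
#'
#' Physicians emit short ordered candidate lists, not total orders. The list
#' is expanded to a full ranking by giving the m listed diseases the rank
#' ratios 1/D ... m/D in order and every unlisted disease the maximally
#' uninformative ratio 1. The expanded human ranking is then combined with
#' the model ranking by the order-statistics rule (N = 2).
#'
#' @param model a `phb_ranking` over `kb`.
#' @param human character vector of disease codes in the physician's
#'   preference order (may be short or empty; unknown codes are dropped
#'   with a message).
#' @param kb the `phb_kb`.
#' @param null optional `phb_null` with `N = 2`.
#' @return A `phb_ranking` (method `"human+model"`).
#' @export
merge_with_physician <- function(model, human, kb, null = NULL) {
  stopifnot(inherits(model, "phb_ranking"), inherits(kb, "phb_kb"))
  D <- length(kb$diseases)
  primary <- kb_codes(kb)
  idx <- kb_code_index(kb)
  human <- as.character(human)
  known <- human[human %in% names(idx)]
  if (length(known) < length(human)) {
    message(length(human) - length(known), " unknown physician code(s) dropped")
  }
  hratio <- rep(1, D)
  if (length(known) > 0L) {
    ki <- idx[known]
    hratio[ki] <- seq_along(known) / D
  }
  mratio <- model$rank[match(primary, model$disease)] / D
  if (anyNA(mratio)) stop("model ranking does not cover the knowledge base")
  R <- t(apply(cbind(mratio, hratio), 1L, sort))
  if (is.null(null)) null <- fit_null(2L)
  if (null$N != 2L) stop("physician merging needs a null fitted for N = 2")
  p <- null_cdf(null, z_statistic_rows(R))
  out <- ranked_prediction(kb, p, method = "human+model", decreasing = FALSE)
  out
}
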