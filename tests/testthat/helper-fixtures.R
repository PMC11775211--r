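# Shared fixtures and independent oracles. Oracles deliberately use the
# rawest possible machinery (edge-following loops, double loops, explicit
# recursion) so they share no code path with the implementation.

chain_ontology <- function() {
  # R <- A <- B
  ontology(c("T:1", "T:2", "T:3"),
           list("T:2" = "T:1", "T:3" = "T:2"))
}

diamond_ontology <- function() {
  # R <- A, R <- B, A <- C, B <- C
  ontology(c("T:1", "T:2", "T:3", "T:4"),
           list("T:2" = "T:1", "T:3" = "T:1", "T:4" = c("T:2", "T:3")))
}

six_node_ontology <- function() {
  # root T:1; T:2,T:3 below root; T:4 under T:2; T:5 under T:2 and T:3; T:6 under T:5
  ontology(paste0("T:", 1:6),
           list("T:2" = "T:1", "T:3" = "T:1", "T:4" = "T:2",
                "T:5" = c("T:2", "T:3"), "T:6" = "T:5"))
}

# Ancestor closure by plain breadth-first search over the parent map only.
bfs_ancestors <- function(o, t, include_self = FALSE) {
  acc <- character(0)
  front <- o$parents[[t]]
  while (length(front) > 0L) {
    acc <- union(acc, front)
    front <- setdiff(unique(unlist(o$parents[front], use.names = FALSE)), acc)
  }
  if (include_self) union(t, acc) else acc
}

bfs_closure <- function(o, terms) {
  out <- character(0)
  for (t in terms) out <- union(out, bfs_ancestors(o, t, include_self = TRUE))
  out
}

# IC table by explicit (term, disease) double loop.
oracle_ic <- function(o, kb, closure = TRUE) {
  n <- length(kb$diseases)
  p <- numeric(length(o$terms))
  names(p) <- o$terms
  for (t in o$terms) {
    cnt <- 0
    for (d in kb$diseases) {
      ts <- names(d$annotations)
      if (closure) ts <- bfs_closure(o, ts)
      if (t %in% ts) cnt <- cnt + 1
    }
    p[[t]] <- cnt / n
  }
  floor_p <- min(p[p > 0])
  p[p == 0] <- floor_p
  list(background_prob = p, ic = -log(p))
}

# PPO conditional probabilities by top-down recursion with memoisation,
# following the three propagation rules directly.
oracle_ppo <- function(disease, o, dp = 0.5, rule = "ind") {
  h <- names(disease$annotations)
  a <- bfs_closure(o, h)
  memo <- new.env(parent = emptyenv())
  val <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    if (t %in% h) {
      r <- disease$annotations[[t]]
      out <- if (is.null(r) || is.na(r$value) || r$value <= 0) dp else r$value
    } else {
      ck <- intersect(o$children[[t]], a)
      pc <- vapply(ck, val, 0)
      out <- if (rule == "max") max(pc)
      else if (rule == "ind") 1 - prod(1 - pc)
      else min(1, sum(pc))
    }
    memo[[t]] <- out
    out
  }
  vapply(a, val, 0)
}

# Complement naive Bayes theta by explicit double loop (hard labels).
oracle_cnb_theta <- function(X, y, alpha_j = 1) {
  K <- length(unique(y))
  M <- ncol(X)
  alpha <- alpha_j * M
  theta <- matrix(0, K, M)
  for (k in seq_len(K)) {
    for (j in seq_len(M)) {
      num <- alpha_j
      for (i in seq_len(nrow(X))) if (y[[i]] != k) num <- num + X[i, j]
      den <- alpha
      for (i in seq_len(nrow(X))) {
        if (y[[i]] != k) den <- den + sum(X[i, ])
      }
      theta[k, j] <- num / den
    }
  }
  theta
}

# Monte-Carlo estimate of the joint order-statistic CDF: draw iid uniforms,
# sort each draw, count coordinate-wise dominations.
mc_z_matrix <- function(n, N) {
  U <- matrix(stats::runif(n * N), nrow = n)
  ord <- order(rep(seq_len(n), times = N), c(U))
  matrix(U[ord], nrow = n, byrow = TRUE)
}

mc_z_estimate <- function(S, r) {
  cond <- S[, 1L] <= r[[1L]]
  for (j in seq_len(ncol(S))[-1L]) cond <- cond & (S[, j] <= r[[j]])
  mean(cond)
}

# tiny knowledge base over an arbitrary ontology
toy_kb <- function(o, sets, freqs = NULL) {
  entries <- lapply(seq_along(sets), function(k) {
    ann <- stats::setNames(vector("list", length(sets[[k]])), sets[[k]])
    if (!is.null(freqs) && !is.null(freqs[[k]])) {
      for (t in names(freqs[[k]])) {
        ann[[t]] <- list(value = freqs[[k]][[t]], provenance = "fraction")
      }
    }
    list(codes = sprintf("D:%04d", k), name = paste("disease", k),
         annotations = ann)
  })
  knowledge_base(entries, o)
}

random_world <- function(seed, n_terms = 30L, n_diseases = 8L,
                         ann_range = c(2L, 5L)) {
  cfg <- sim_config(n_terms = n_terms, n_diseases = n_diseases,
                    annotations_per_disease = ann_range, seed = seed)
  o <- sim_ontology(cfg)
  list(cfg = cfg, o = o, kb = sim_kb(o, cfg))
}

quiet_augment <- function(...) suppressWarnings(augment_training(...))
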