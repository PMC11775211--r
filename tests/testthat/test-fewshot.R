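test_that("standard cases are closure indicator rows", {
  o <- six_node_ontology()
  kb <- toy_kb(o, list(c("T:4"), c("T:6")))
  tr <- build_standard_cases(kb)
  expect_equal(dim(tr$X), c(2L, length(tr$term_index)))
  expect_equal(names(which(tr$X[1L, ] == 1)),
               sort(annotation_closure(o, "T:4")))
  expect_equal(names(which(tr$X[2L, ] == 1)),
               sort(annotation_closure(o, "T:6")))
  expect_equal(tr$Y, diag(1, 2))
  # root-only disease is a one-hot at the root column
  kb2 <- toy_kb(o, list("T:1", "T:4"))
  tr2 <- build_standard_cases(kb2)
  expect_equal(sum(tr2$X[1L, ]), 1)
  expect_equal(unname(tr2$X[1L, "T:1"]), 1)
})

test_that("standard-case matrices match the brute-force closure construction", {
  w <- random_world(4)
  tr <- build_standard_cases(w$kb)
  for (i in seq_along(w$kb$diseases)) {
    cl <- bfs_closure(w$o, names(w$kb$diseases[[i]]$annotations))
    expect_setequal(names(which(tr$X[i, ] == 1)), cl)
  }
})

test_that("mixup interpolates features and labels", {
  m <- mixup(c(1, 0), c(1, 0), c(0, 1), c(0, 1), lambda = 0.5)
  expect_equal(m$x, c(0.5, 0.5))
  expect_equal(m$y, c(0.5, 0.5))
  m1 <- mixup(c(1, 0), c(1, 0), c(0, 1), c(0, 1), lambda = 1)
  expect_equal(m1$x, c(1, 0))
  expect_error(mixup(c(1, 0), c(1, 0), c(0, 1, 1), c(0, 1)), "dimension")
  # Beta(alpha, alpha) is symmetric: empirical mean of lambda near 1/2
  set.seed(99)
  lam <- replicate(100, mixup(c(1, 0), c(1, 0), c(0, 1), c(0, 1),
                              alpha = 0.4)$lambda)
  se <- sqrt(stats::var(lam) / length(lam))
  expect_lt(abs(mean(lam) - 0.5), 3 * se + 1e-3)
  expect_true(all(lam >= 0 & lam <= 1))
})

test_that("random perturbation applies the configured operations", {
  ch <- chain_ontology()
  x <- c("T:1" = 1, "T:2" = 0, "T:3" = 1)
  set.seed(1)
  # pure removal drops exactly one active term (never the last)
  cfg <- aug_config(perturb_K = 1L, perturb_mix = c(1, 0, 0, 0))
  out <- random_perturb(x, ch, cfg)
  expect_equal(sum(out), 1)   # one of the two active terms removed
  # generalize on active leaf T:3 moves it to T:2 (T:1 already active)
  x2 <- c("T:1" = 0, "T:2" = 0, "T:3" = 1)
  cfg2 <- aug_config(perturb_K = 1L, perturb_mix = c(0, 1, 0, 0))
  out2 <- random_perturb(x2, ch, cfg2)
  expect_equal(sum(out2), 1)
  expect_equal(unname(out2[["T:3"]]), 0)
  expect_true(out2[["T:2"]] == 1 || out2[["T:1"]] == 1)
  # specialize moves an ancestor downward
  x3 <- c("T:1" = 1, "T:2" = 0, "T:3" = 0)
  cfg3 <- aug_config(perturb_K = 1L, perturb_mix = c(0, 0, 1, 0))
  out3 <- random_perturb(x3, ch, cfg3)
  expect_equal(sum(out3), 1)
  expect_equal(unname(out3[["T:1"]]), 0)
  # chain has no unrelated term: noise op warns and skips
  cfg4 <- aug_config(perturb_K = 1L, perturb_mix = c(0, 0, 0, 1))
  expect_warning(out4 <- random_perturb(x, ch, cfg4), "noise")
  expect_equal(out4, x)
})

test_that("perturbation is reproducible under a fixed seed and removal counts are exact", {
  w <- random_world(2)
  tr <- build_standard_cases(w$kb)
  x <- tr$X[1L, ]
  cfg <- aug_config(perturb_K = 3L)
  set.seed(11)
  a <- suppressWarnings(random_perturb(x, w$o, cfg, term_index = tr$term_index))
  set.seed(11)
  b <- suppressWarnings(random_perturb(x, w$o, cfg, term_index = tr$term_index))
  expect_identical(a, b)
  cfgR <- aug_config(perturb_K = 5L, perturb_mix = c(1, 0, 0, 0))
  for (i in seq_len(nrow(tr$X))) {
    xi <- tr$X[i, ]
    out <- suppressWarnings(random_perturb(xi, w$o, cfgR, term_index = tr$term_index))
    expect_equal(sum(xi) - sum(out), min(5L, sum(xi) - 1L))
  }
})

test_that("augmentation appends rows without touching the standards", {
  w <- random_world(3, n_diseases = 5L)
  tr <- build_standard_cases(w$kb)
  aug <- quiet_augment(tr, aug_config(n_mixup = 2L, n_perturb = 2L), seed = 5)
  D <- nrow(tr$X)
  expect_equal(nrow(aug$X), D + 4L * D)
  expect_equal(aug$X[seq_len(D), ], tr$X)
  expect_equal(aug$Y[seq_len(D), ], tr$Y)
  # soft labels sum to one; mixup rows are convex combinations
  expect_equal(rowSums(aug$Y), rep(1, nrow(aug$Y)))
  expect_true(all(aug$X >= 0 & aug$X <= 1))
  # deterministic under seed
  aug2 <- quiet_augment(tr, aug_config(n_mixup = 2L, n_perturb = 2L), seed = 5)
  expect_identical(aug, aug2)
})

test_that("complement naive Bayes reproduces the hand-computed example", {
  # two diseases, three columns, rows (1,1,0) and (0,1,1), Laplace smoothing
  tr <- structure(list(X = rbind(c(1, 1, 0), c(0, 1, 1)),
                       Y = diag(1, 2), term_index = c("a", "b", "c"),
                       diseases = c("D:1", "D:2")),
                  class = "phb_train")
  fit <- cnb_fit(tr, alpha_j = 1)
  expect_equal(unname(fit$theta[1L, ]), c(1 / 5, 2 / 5, 2 / 5))
  expect_equal(unname(fit$theta[2L, ]), c(2 / 5, 2 / 5, 1 / 5))
  # scoring q = (1,0,0): disease 1 has the smaller (more negative) score
  s1 <- log(0.2); s2 <- log(0.4)
  expect_lt(s1, s2)
  expect_error(cnb_fit(structure(list(X = matrix(1, 1, 2), Y = matrix(1, 1, 1),
                                      term_index = c("a", "b"),
                                      diseases = "D:1"),
                                 class = "phb_train")),
               "two classes")
})

test_that("CNB theta and scores match the double-loop oracle on augmented fixtures", {
  for (seed in 1:3) {
    w <- random_world(seed, n_diseases = 5L)
    tr <- build_standard_cases(w$kb)
    aug <- quiet_augment(tr, aug_config(n_mixup = 0L, n_perturb = 2L),
                         seed = seed, include = "perturb")
    fit <- cnb_fit(aug, alpha_j = 1)
    y <- apply(aug$Y, 1L, which.max)
    want <- oracle_cnb_theta(aug$X, y, alpha_j = 1)
    expect_equal(unname(fit$theta), want, tolerance = 1e-12)
    # ranking scores equal the oracle inner product
    q <- as.numeric(aug$X[1L, ])
    r <- cnb_rank(q, fit, w$kb)
    for (k in seq_len(nrow(want))) {
      expect_equal(r$score[r$disease == fit$diseases[[k]]],
                   sum(q * log(want[k, ])), tolerance = 1e-12)
    }
  }
})

test_that("CNB ranking handles the zero-query tie and ranks ascending", {
  w <- random_world(5, n_diseases = 4L)
  tr <- build_standard_cases(w$kb)
  fit <- cnb_fit(tr)
  r0 <- cnb_rank(rep(0, length(tr$term_index)), fit, w$kb)
  expect_equal(r0$rank, rep(1L, 4L))
  expect_equal(r0$score, rep(0, 4L))
  # scores are non-decreasing down an ascending ranking
  r <- cnb_rank(as.numeric(tr$X[2L, ]), fit, w$kb)
  expect_true(all(diff(r$score) >= 0))
  expect_equal(r$disease[[1L]], fit$diseases[[2L]])
})

test_that("the perceptron separates disjoint-closure diseases and is deterministic", {
  # three diseases in distinct branches of a wide shallow ontology
  o <- ontology(paste0("T:", 1:10),
                list("T:2" = "T:1", "T:3" = "T:1", "T:4" = "T:1",
                     "T:5" = "T:2", "T:6" = "T:2", "T:7" = "T:3",
                     "T:8" = "T:3", "T:9" = "T:4", "T:10" = "T:4"))
  kb <- toy_kb(o, list(c("T:5", "T:6"), c("T:7", "T:8"), c("T:9", "T:10")))
  tr <- build_standard_cases(kb)
  aug <- quiet_augment(tr, aug_config(), seed = 1)
  fit <- mlp_fit(aug, mlp_params(hidden_size = 16L, epochs = 150L, seed = 2))
  for (i in 1:3) {
    r <- mlp_rank(as.numeric(tr$X[i, ]), fit, kb)
    expect_equal(r$disease[[1L]], tr$diseases[[i]])
  }
  fit2 <- mlp_fit(aug, mlp_params(hidden_size = 16L, epochs = 150L, seed = 2))
  expect_identical(fit$W1, fit2$W1)
  r1 <- mlp_rank(as.numeric(tr$X[1L, ]), fit, kb)
  r2 <- mlp_rank(as.numeric(tr$X[1L, ]), fit2, kb)
  expect_identical(r1$disease, r2$disease)
  # zero-epoch model is deterministic given its seed
  f0a <- mlp_fit(tr, mlp_params(hidden_size = 8L, epochs = 0L, seed = 3))
  f0b <- mlp_fit(tr, mlp_params(hidden_size = 8L, epochs = 0L, seed = 3))
  expect_identical(mlp_rank(as.numeric(tr$X[1L, ]), f0a, kb)$disease,
                   mlp_rank(as.numeric(tr$X[1L, ]), f0b, kb)$disease)
})
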