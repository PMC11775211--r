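test_that("the Z recursion reproduces closed forms", {
  expect_equal(z_statistic(0.3), 0.3)                      # N = 1: CDF of one uniform
  r <- c(0.2, 0.5)
  expect_equal(z_statistic(r), 2 * r[1] * r[2] - r[1]^2)   # N = 2 closed form
  expect_equal(z_statistic(c(1, 1, 1, 1)), 1)
  expect_equal(z_statistic(c(0, 0.4, 0.9)), 0)             # empty first region
  expect_error(z_statistic(c(0.5, 0.2)), "sorted")
  expect_error(z_statistic(c(0.2, 1.3)), "\\[0, 1\\]")
  # closed form at N = 2 on random vectors to machine precision
  set.seed(1)
  for (rep in 1:100) {
    r2 <- sort(stats::runif(2))
    expect_equal(z_statistic(r2), 2 * r2[1] * r2[2] - r2[1]^2,
                 tolerance = 1e-12)
  }
})

test_that("Z agrees with Monte-Carlo estimates of the order-statistic CDF", {
  set.seed(20)
  n <- 20000L
  for (N in 2:5) {
    S <- mc_z_matrix(n, N)
    for (rep in 1:20) {
      r <- sort(stats::runif(N))
      est <- mc_z_estimate(S, r)
      se <- sqrt(est * (1 - est) / n)
      expect_lt(abs(z_statistic(r) - est), 3 * se + 3 / n)
    }
  }
})

test_that("Z is monotone in every coordinate and symmetric-safe", {
  set.seed(3)
  for (rep in 1:50) {
    N <- sample(2:5, 1L)
    r <- sort(stats::runif(N))
    z0 <- z_statistic(r)
    expect_gte(z0, 0); expect_lte(z0, 1)
    i <- sample(N, 1L)
    up <- r
    up[i] <- min(1, up[i] + stats::runif(1, 0, 1 - up[i]))
    up <- sort(up)
    expect_gte(z_statistic(up), z0 - 1e-12)
  }
})

test_that("the vectorized Z matches the scalar recursion", {
  set.seed(4)
  R <- t(apply(matrix(stats::runif(300), ncol = 3L), 1L, sort))
  expect_equal(phenorank:::z_statistic_rows(R),
               apply(R, 1L, z_statistic), tolerance = 1e-12)
})

test_that("the fitted null is Beta(~1,~1) for one method and deterministic", {
  n1 <- fit_null(1L, mc_samples = 5e4, seed = 123)
  expect_equal(n1$family, "beta")
  expect_lt(abs(n1$par1 - 1), 0.1)
  expect_lt(abs(n1$par2 - 1), 0.1)
  n1b <- fit_null(1L, mc_samples = 5e4, seed = 123)
  expect_identical(n1$par1, n1b$par1)
  expect_warning(fit_null(2L, mc_samples = 500), "noisy")
  # gamma family above five methods
  n6 <- fit_null(6L, mc_samples = 2e4, seed = 5)
  expect_equal(n6$family, "gamma")
  expect_true(n6$par1 > 0 && n6$par2 > 0)
})

test_that("rank ratios divide by KB size and sort ascending", {
  w <- random_world(1, n_diseases = 10L)
  ic <- compute_ic(w$o, w$kb)
  codes <- vapply(w$kb$diseases, function(d) d$codes[[1L]], "")
  set.seed(5)
  case <- patient_case(sample(w$o$terms, 4), character(0), "c")
  r1 <- rank_diseases_by_similarity(case, w$kb, ic, "icto")
  r2 <- ppo_rank(case, w$kb, ic)
  rr <- rank_ratios(list(r1, r2), codes[[3L]])
  expect_length(rr, 2L)
  expect_true(!is.unsorted(rr))
  expect_equal(sort(c(rank_of(r1 <- r1, codes[[3L]]),
                      rank_of(r2, codes[[3L]])) / 10), rr)
})

test_that("ensemble ordering follows coordinate-wise dominance and identical inputs", {
  w <- random_world(2, n_diseases = 12L)
  ic <- compute_ic(w$o, w$kb)
  set.seed(6)
  case <- patient_case(sample(w$o$terms, 5), character(0), "c")
  r <- rank_diseases_by_similarity(case, w$kb, ic, "icto")
  null2 <- fit_null(2L, mc_samples = 2e4, seed = 7)
  ens <- ensemble_rank(list(r, r), w$kb, null2)
  # identical members: consensus order equals the member order
  expect_equal(rank_of(ens, r$disease[[1L]]), 1L)
  ord_member <- r$disease[order(r$rank)]
  ord_ens <- ens$disease[order(ens$rank)]
  expect_equal(ord_ens, ord_member)
  # a disease ranked first by all members beats one ranked last by all
  expect_lt(ens$rank[ens$disease == r$disease[[1L]]],
            ens$rank[ens$disease == r$disease[[nrow(r)]]])
})

test_that("ensemble order matches a Monte-Carlo oracle of the joint CDF", {
  w <- random_world(3, n_diseases = 20L)
  codes <- vapply(w$kb$diseases, function(d) d$codes[[1L]], "")
  D <- 20L
  set.seed(8)
  # four synthetic member rankings: random permutations
  members <- lapply(1:4, function(i) {
    ranked_prediction(w$kb, sample(D), method = paste0("m", i))
  })
  null4 <- fit_null(4L, mc_samples = 5e4, seed = 9)
  ens <- ensemble_rank(members, w$kb, null4)
  n <- 200000L
  S <- mc_z_matrix(n, 4L)
  zs <- vapply(codes, function(cd) {
    z_statistic(rank_ratios(members, cd))
  }, 0)
  est <- vapply(codes, function(cd) {
    mc_z_estimate(S, rank_ratios(members, cd))
  }, 0)
  # wherever MC separates two Z values clearly, the ensemble agrees
  for (a in seq_len(D - 1L)) {
    for (b in (a + 1L):D) {
      sea <- sqrt(est[a] * (1 - est[a]) / n)
      seb <- sqrt(est[b] * (1 - est[b]) / n)
      if (abs(est[a] - est[b]) > 3 * (sea + seb) + 1e-6) {
        better_mc <- if (est[a] < est[b]) codes[a] else codes[b]
        worse_mc <- if (est[a] < est[b]) codes[b] else codes[a]
        expect_lt(ens$rank[ens$disease == better_mc],
                  ens$rank[ens$disease == worse_mc])
      }
    }
  }
  # permuting member order leaves the consensus unchanged
  ens2 <- ensemble_rank(members[c(3, 1, 4, 2)], w$kb, null4)
  expect_equal(ens$disease, ens2$disease)
  expect_equal(ens$rank, ens2$rank)
})

test_that("the fitted null CDF tracks its own empirical simulation", {
  n3 <- fit_null(3L, mc_samples = 1e5, seed = 31)
  zs <- sort(n3$z)
  emp <- seq_along(zs) / length(zs)
  ks <- max(abs(null_cdf(n3, zs) - emp))
  expect_lt(ks, 0.02)
  expect_equal(null_cdf(n3, zs[1:5], empirical = TRUE),
               stats::ecdf(n3$z)(zs[1:5]))
})

test_that("physician merging respects dominance and degenerates gracefully", {
  w <- random_world(4, n_diseases = 20L)
  ic <- compute_ic(w$o, w$kb)
  set.seed(10)
  case <- patient_case(sample(w$o$terms, 5), character(0), "c")
  model <- rank_diseases_by_similarity(case, w$kb, ic, "icto")
  null2 <- fit_null(2L, mc_samples = 2e4, seed = 11)
  # empty human list: model order preserved (human side constant)
  m0 <- merge_with_physician(model, character(0), w$kb, null2)
  expect_equal(m0$disease[order(m0$rank, m0$disease)],
               model$disease[order(model$rank, model$disease)])
  # human confirming the model's top pick keeps it on top
  top <- model$disease[[1L]]
  m1 <- merge_with_physician(model, top, w$kb, null2)
  expect_equal(rank_of(m1, top), 1L)
  # human naming a mid-pack disease improves its merged rank
  mid <- model$disease[order(model$rank)][[8L]]
  r0 <- rank_of(model, mid)
  expect_gt(r0, 2L)
  m2 <- merge_with_physician(model, mid, w$kb, null2)
  expect_lt(rank_of(m2, mid), r0)
  expect_message(merge_with_physician(model, c(top, "NOPE:1"), w$kb, null2),
                 "unknown")
})
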