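#' Build the standard-case training matrix
#'
#' Each disease contributes exactly one "standard case": the multi-hot
#' indicator of its ancestor-closed annotation set over the column index
#' (the union of all closures). Labels are one-hot rows of the same length
#' as the disease list.
#'
#' @param kb a `phb_kb`.
#' @return A list of class `phb_train`: `X` (D x M multi-hot matrix), `Y`
#'   (D x D one-hot label matrix), `term_index` (column CURIEs),
#'   `diseases` (primary codes, KB order).
#' @export
build_standard_cases <- function(kb) {
  stopifnot(inherits(kb, "phb_kb"))
  if (length(kb$diseases) == 0L) stop("empty knowledge base")
  o <- kb$ontology
  closures <- lapply(kb$diseases, function(d)
    annotation_closure(o, names(d$annotations)))
  term_index <- sort(unique(unlist(closures, use.names = FALSE)))
  D <- length(kb$diseases)
  M <- length(term_index)
  X <- matrix(0, nrow = D, ncol = M, dimnames = list(NULL, term_index))
  for (i in seq_len(D)) X[i, closures[[i]]] <- 1
  Y <- diag(1, D)
  structure(list(X = X, Y = Y, term_index = term_index,
                 diseases = kb_codes(kb), ontology = o),
            class = "phb_train")
}

#' Augmentation configuration
#'
#' @param n_mixup Mixup samples generated per disease.
#' @param mixup_alpha shape of the symmetric Beta the mixing coefficient is
#'   drawn from.
#' @param n_perturb random-perturbation samples per disease.
#' @param perturb_K phenotypes altered per perturbed sample.
#' @param perturb_mix probabilities over the four operations
#'   (remove, generalize, specialize, add_noise); must sum to 1.
#' @return A list of class `phb_aug_config`.
#' @export
aug_config <- function(n_mixup = 4L, mixup_alpha = 0.4,
                       n_perturb = 4L, perturb_K = 2L,
                       perturb_mix = c(remove = 0.25, generalize = 0.25,
                                       specialize = 0.25, add_noise = 0.25)) {
  stopifnot(perturb_K >= 1L, abs(sum(perturb_mix) - 1) < 1e-8,
            length(perturb_mix) == 4L)
  names(perturb_mix) <- c("remove", "generalize", "specialize", "add_noise")
  structure(list(n_mixup = n_mixup, mixup_alpha = mixup_alpha,
                 n_perturb = n_perturb, perturb_K = perturb_K,
                 perturb_mix = perturb_mix),
            class = "phb_aug_config")
}

#' Mixup interpolation of two training samples
#'
#' Draws lambda from Beta(alpha, alpha) (or uses `lambda` when supplied) and
#' returns the convex combinations `lambda * a + (1 - lambda) * b` of both
#' feature vectors and label vectors.
#'
#' @param xa,xb feature vectors (equal length).
#' @param ya,yb label vectors (equal length; typically one-hot).
#' @param alpha Beta shape.
#' @param lambda optional fixed mixing coefficient in \[0, 1\].
#' @return list with `x`, `y` and the `lambda` used.
#' @export
mixup <- function(xa, ya, xb, yb, alpha = 0.4, lambda = NULL) {
  if (length(xa) != length(xb)) stop("feature dimension mismatch in mixup")
  if (length(ya) != length(yb)) stop("label dimension mismatch in mixup")
  if (is.null(lambda)) lambda <- stats::rbeta(1L, alpha, alpha)
  list(x = lambda * xa + (1 - lambda) * xb,
       y = lambda * ya + (1 - lambda) * yb,
       lambda = lambda)
}

#' Randomly perturb a multi-hot phenotype vector
#'
#' Applies exactly K operations sampled from the configured mix. `remove`
#' deactivates an active term (never the last one); `generalize` replaces an
#' active term by one of its proper ancestors; `specialize` by one of its
#' proper descendants; `add_noise` activates a term that is neither an
#' ancestor nor a descendant of any active term. Operations without an
#' eligible target are skipped with a warning. The label is unchanged by
#' construction (the caller keeps it).
#'
#' @param x multi-hot numeric vector named by term CURIE, or unnamed with
#'   `term_index` supplied.
#' @param o a `phb_ontology`.
#' @param cfg a `phb_aug_config`.
#' @param term_index column CURIEs when `x` is unnamed.
#' @return Perturbed multi-hot vector (same length and names).
#' @export
random_perturb <- function(x, o, cfg = aug_config(), term_index = names(x)) {
  stopifnot(inherits(o, "phb_ontology"), length(term_index) == length(x))
  v <- stats::setNames(as.numeric(x), term_index)
  ops <- sample(names(cfg$perturb_mix), cfg$perturb_K, replace = TRUE,
                prob = cfg$perturb_mix)
  for (op in ops) {
    active <- names(v)[v > 0]
    if (op == "remove") {
      if (length(active) <= 1L) next  # never emit an empty case
      v[[sample(active, 1L)]] <- 0
    } else if (op %in% c("generalize", "specialize")) {
      # pick an active term that has an eligible in-index replacement
      cand <- sample(active)
      done <- FALSE
      for (t in cand) {
        pool <- if (op == "generalize") o$anc[[t]] else o$desc[[t]]
        pool <- intersect(pool, term_index)
        pool <- setdiff(pool, active)
        if (length(pool) > 0L) {
          v[[t]] <- 0
          v[[sample(pool, 1L)]] <- 1
          done <- TRUE
          break
        }
      }
      if (!done) warning("no eligible replacement for ", op, "; operation skipped")
    } else {  # add_noise
      related <- unique(c(active,
                          unlist(o$anc[active], use.names = FALSE),
                          unlist(o$desc[active], use.names = FALSE)))
      pool <- setdiff(term_index, related)
      if (length(pool) == 0L) {
        warning("no eligible noise term; operation skipped")
        next
      }
      v[[sample(pool, 1L)]] <- 1
    }
  }
  v
}

#' Augment a standard-case training set
#'
#' Appends `n_mixup` Mixup samples (soft labels) and `n_perturb`
#' random-perturbation samples (hard labels) per disease to the standard
#' cases, which are never altered themselves.
#'
#' @param train a `phb_train` from [build_standard_cases()].
#' @param cfg a `phb_aug_config`.
#' @param seed integer seed; all augmentation randomness derives from it.
#' @param include character subset of `c("mixup", "perturb")`.
#' @return A `phb_train` with the additional rows appended.
#' @export
augment_training <- function(train, cfg = aug_config(), seed = 1L,
                             include = c("mixup", "perturb")) {
  stopifnot(inherits(train, "phb_train"))
  D <- nrow(train$X)
  withr_seed(seed, {
    Xs <- list(train$X)
    Ys <- list(train$Y)
    if ("mixup" %in% include && cfg$n_mixup > 0L && D >= 2L) {
      for (i in seq_len(D)) {
        for (r in seq_len(cfg$n_mixup)) {
          j <- sample(setdiff(seq_len(D), i), 1L)
          m <- mixup(train$X[i, ], train$Y[i, ], train$X[j, ], train$Y[j, ],
                     alpha = cfg$mixup_alpha)
          Xs <- c(Xs, list(matrix(m$x, 1L)))
          Ys <- c(Ys, list(matrix(m$y, 1L)))
        }
      }
    }
    if ("perturb" %in% include && cfg$n_perturb > 0L) {
      for (i in seq_len(D)) {
        for (r in seq_len(cfg$n_perturb)) {
          px <- random_perturb(train$X[i, ], train$ontology, cfg,
                               term_index = train$term_index)
          Xs <- c(Xs, list(matrix(px, 1L)))
          Ys <- c(Ys, list(matrix(train$Y[i, ], 1L)))
        }
      }
    }
    X <- do.call(rbind, Xs)
    colnames(X) <- train$term_index
    structure(list(X = X, Y = do.call(rbind, Ys),
                   term_index = train$term_index,
                   diseases = train$diseases, ontology = train$ontology),
              class = "phb_train")
  })
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Fit a complement naive Bayes model
#'
#' Estimates, for every disease k and term column j, the smoothed fraction
#' \deqn{\theta_{kj} = \frac{\alpha_j + \sum_{y_i \ne k} x_{ij}}
#'                          {\alpha + \sum_{y_i \ne k} \sum_{j'} x_{ij'}}}
#' of phenotype mass occurring in the complement of class k. With soft
#' labels, row i contributes weight (1 - y_ik) to class k's complement;
#' with one-hot labels this is exactly the indicator sum above.
#'
#' @param train a `phb_train` (at least two diseases).
#' @param alpha_j per-column smoothing; scalar recycled over columns.
#' @return A list of class `phb_cnb`: `theta` (D x M), `term_index`,
#'   `diseases`, `log_theta`.
#' @export
cnb_fit <- function(train, alpha_j = 1) {
  stopifnot(inherits(train, "phb_train"))
  D <- length(train$diseases)
  if (D < 2L) stop("complement statistics need at least two classes")
  M <- ncol(train$X)
  alpha_vec <- rep(alpha_j, length.out = M)
  alpha <- sum(alpha_vec)
  W <- 1 - train$Y                       # complement weight of row i for class k
  num <- t(W) %*% train$X                # D x M: sum over complement rows
  num <- sweep(num, 2L, alpha_vec, `+`)
  den <- alpha + as.numeric(t(W) %*% rowSums(train$X))
  theta <- num / den
  structure(list(theta = theta, log_theta = log(theta),
                 term_index = train$term_index, diseases = train$diseases),
            class = "phb_cnb")
}

#' Rank diseases with a fitted complement naive Bayes model
#'
#' Scores each disease by `sum_j q_j log(theta_kj)` and ranks in ascending
#' order: less query mass in a class's complement means the class itself is
#' more likely. Queries are ancestor-closed before encoding so that they
#' match the standard-case construction. A zero theta met by an active query
#' column drives the score to -Inf, i.e. best-possible evidence for that
#' disease.
#'
#' @param case a `phb_case` (or a numeric multi-hot vector over
#'   `model$term_index`).
#' @param model a `phb_cnb`.
#' @param kb the `phb_kb` the model was fitted on.
#' @param close_query ancestor-close the query before encoding?
#' @return A `phb_ranking` (ascending complement score).
#' @export
cnb_rank <- function(case, model, kb, close_query = TRUE) {
  stopifnot(inherits(model, "phb_cnb"), inherits(kb, "phb_kb"))
  q <- encode_query(case, model$term_index, kb$ontology, close_query)
  s <- as.numeric(model$log_theta %*% q)   # -Inf allowed
  ranked_prediction(kb, s, method = "cnb", decreasing = FALSE)
}

encode_query <- function(case, term_index, o, close_query = TRUE) {
  if (inherits(case, "phb_case")) {
    ts <- case$query
    ts <- ts[ts %in% o$terms]
    if (close_query) ts <- annotation_closure(o, ts)
    as.numeric(term_index %in% ts)
  } else {
    stopifnot(length(case) == length(term_index))
    as.numeric(case)
  }
}

#' Parameters of the single-hidden-layer perceptron
#'
#' @param hidden_size hidden units.
#' @param l2_lambda L2 penalty on the weights.
#' @param learning_rate full-batch gradient-descent step size.
#' @param epochs training epochs.
#' @param seed integer seed for weight initialization.
#' @return A list of class `phb_mlp_params`.
#' @export
mlp_params <- function(hidden_size = 64L, l2_lambda = 1e-4,
                       learning_rate = 0.5, epochs = 200L, seed = 1L) {
  stopifnot(hidden_size >= 1L, l2_lambda >= 0, learning_rate > 0, epochs >= 0L)
  structure(list(hidden_size = hidden_size, l2_lambda = l2_lambda,
                 learning_rate = learning_rate, epochs = epochs, seed = seed),
            class = "phb_mlp_params")
}

#' Fit the few-shot multilayer perceptron
#'
#' One hidden layer (ReLU), softmax output, trained by full-batch gradient
#' descent on the cross-entropy against (possibly soft) label rows, with L2
#' regularization. Training is deterministic given the seed. The weights
#' from the best-loss epoch are returned; if the final epoch is not the
#' best, a warning notes the non-monotone convergence.
#'
#' @param train a `phb_train` (typically augmented, see
#'   [augment_training()]).
#' @param params a `phb_mlp_params`.
#' @return A list of class `phb_mlp` with weight matrices `W1`, `b1`, `W2`,
#'   `b2`, plus `term_index` and `diseases`.
#' @export
mlp_fit <- function(train, params = mlp_params()) {
  stopifnot(inherits(train, "phb_train"), inherits(params, "phb_mlp_params"))
  X <- train$X
  Y <- train$Y
  M <- ncol(X); D <- ncol(Y); H <- params$hidden_size
  withr_seed(params$seed, {
    W1 <- matrix(stats::rnorm(M * H, sd = sqrt(2 / M)), M, H)
    b1 <- numeric(H)
    W2 <- matrix(stats::rnorm(H * D, sd = sqrt(2 / H)), H, D)
    b2 <- numeric(D)
    n <- nrow(X)
    best <- list(loss = Inf)
    lr <- params$learning_rate
    for (e in seq_len(params$epochs)) {
      Z1 <- sweep(X %*% W1, 2L, b1, `+`)
      A1 <- pmax(Z1, 0)
      Z2 <- sweep(A1 %*% W2, 2L, b2, `+`)
      P <- softmax_rows(Z2)
      loss <- -sum(Y * log(pmax(P, 1e-12))) / n +
        params$l2_lambda * (sum(W1^2) + sum(W2^2)) / 2
      if (loss < best$loss) best <- list(loss = loss, W1 = W1, b1 = b1,
                                         W2 = W2, b2 = b2, epoch = e)
      dZ2 <- (P - Y) / n
      dW2 <- t(A1) %*% dZ2 + params$l2_lambda * W2
      db2 <- colSums(dZ2)
      dA1 <- dZ2 %*% t(W2)
      dZ1 <- dA1 * (Z1 > 0)
      dW1 <- t(X) %*% dZ1 + params$l2_lambda * W1
      db1 <- colSums(dZ1)
      W2 <- W2 - lr * dW2; b2 <- b2 - lr * db2
      W1 <- W1 - lr * dW1; b1 <- b1 - lr * db1
    }
    if (params$epochs == 0L) {
      best <- list(loss = NA_real_, W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                   epoch = 0L)
    } else if (best$epoch < params$epochs * 0.5) {
      warning("MLP training not converged; returning best epoch ", best$epoch)
    }
    structure(list(W1 = best$W1, b1 = best$b1, W2 = best$W2, b2 = best$b2,
                   loss = best$loss, epoch = best$epoch,
                   term_index = train$term_index, diseases = train$diseases),
              class = "phb_mlp")
  })
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Rank diseases with a fitted perceptron
#'
#' Forward pass on the (ancestor-closed) query encoding; diseases ranked by
#' descending predicted class probability. An untrained model (zero epochs)
#' yields whatever deterministic scores its random initialization produces.
#'
#' @inheritParams cnb_rank
#' @param model a `phb_mlp`.
#' @return A `phb_ranking`.
#' @export
mlp_rank <- function(case, model, kb, close_query = TRUE) {
  stopifnot(inherits(model, "phb_mlp"), inherits(kb, "phb_kb"))
  q <- encode_query(case, model$term_index, kb$ontology, close_query)
  a1 <- pmax(as.numeric(q %*% model$W1) + model$b1, 0)
  z2 <- as.numeric(a1 %*% model$W2) + model$b2
  p <- exp(z2 - max(z2)); p <- p / sum(p)
  ranked_prediction(kb, p, method = "mlp", decreasing = TRUE)
}
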