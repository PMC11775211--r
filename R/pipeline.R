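#' Filter cases by minimum query size
#'
#' Evaluation datasets exclude cases with fewer than three phenotype terms;
#' this applies the same inclusion rule at a configurable threshold.
#'
#' @param cases list of `phb_case`.
#' @param min_terms minimum query size (>= 1).
#' @return Filtered list; a message reports the exclusion count; an error
#'   if nothing survives.
#' @export
filter_cases <- function(cases, min_terms = 3L) {
  stopifnot(min_terms >= 1L)
  keep <- vapply(cases, function(cs) length(cs$query) >= min_terms, TRUE)
  if (!any(keep)) stop("all cases dropped by the minimum-term filter")
  if (any(!keep)) message(sum(!keep), " case(s) excluded (< ", min_terms, " terms)")
  cases[keep]
}

# stable per-module seed derived from one global seed; stays < 2^31
derive_seed <- function(seed, module) {
  h <- sum(utf8ToInt(module) * seq_along(utf8ToInt(module)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Run the diagnostic methods over a set of cases
#'
#' End-to-end orchestration: prepares whatever each requested method needs
#' (IC table, propagated profiles, fitted classifiers), ranks every case
#' under every method, and optionally adds the order-statistics ensemble
#' over the configured member methods.
#'
#' @param cases list of `phb_case`.
#' @param kb a `phb_kb`.
#' @param methods character vector from `c("icto", "icto_one_sided",
#'   "simgic", "simui", "term_overlap", "cosine", "resnik", "lin", "jc",
#'   "min_ic", "ppo", "cnb", "mlp")`.
#' @param ensemble add an `"ensemble"` entry aggregating
#'   `ensemble_members`?
#' @param ensemble_members members of the ensemble (default the four novel
#'   methods; must be a subset of `methods`).
#' @param seed global seed; per-component seeds are derived from it
#'   stably so adding a method never perturbs another's stream.
#' @param ppo a `phb_ppo_params`.
#' @param aug a `phb_aug_config` for classifier augmentation.
#' @param mlp a `phb_mlp_params` (its seed is overridden by the derived
#'   stream).
#' @param cnb_alpha complement naive Bayes smoothing.
#' @param null_samples Monte-Carlo sample count for the ensemble null.
#' @param ic optional precomputed `phb_ictable`.
#' @return List of class `phb_diagnosis`: `predictions` (method -> named
#'   list case_id -> `phb_ranking`), `methods`, `seed`, `null` (when the
#'   ensemble ran).
#' @export
diagnose <- function(cases, kb,
                     methods = c("icto", "ppo", "cnb", "mlp"),
                     ensemble = length(methods) >= 2L,
                     ensemble_members = intersect(methods,
                                                  c("icto", "ppo", "cnb", "mlp")),
                     seed = 1L,
                     ppo = ppo_params(),
                     aug = aug_config(),
                     mlp = mlp_params(),
                     cnb_alpha = 1,
                     null_samples = 1e5,
                     ic = NULL) {
  stopifnot(inherits(kb, "phb_kb"), length(cases) >= 1L)
  sim_methods <- c("icto", "icto_one_sided", "simgic", "simui",
                   "term_overlap", "cosine", "resnik", "lin", "jc", "min_ic")
  unknown <- setdiff(methods, c(sim_methods, "ppo", "cnb", "mlp"))
  if (length(unknown) > 0L) stop("unknown method(s): ",
                                 paste(unknown, collapse = ", "))
  if (is.null(ic)) ic <- compute_ic(kb$ontology, kb)
  ids <- vapply(cases, `[[`, "", "case_id")
  if (anyDuplicated(ids)) stop("duplicate case_id among cases")

  profiles <- if ("ppo" %in% methods) ppo_profiles(kb, ppo) else NULL
  cnb_model <- mlp_model <- NULL
  if (any(c("cnb", "mlp") %in% methods)) {
    std <- build_standard_cases(kb)
    if ("cnb" %in% methods) {
      tr <- augment_training(std, aug, seed = derive_seed(seed, "cnb"),
                             include = "perturb")
      cnb_model <- cnb_fit(tr, alpha_j = cnb_alpha)
    }
    if ("mlp" %in% methods) {
      tr <- augment_training(std, aug, seed = derive_seed(seed, "mlp-aug"))
      mp <- mlp
      mp$seed <- derive_seed(seed, "mlp-init")
      mlp_model <- mlp_fit(tr, mp)
    }
  }

  run_method <- function(m) {
    preds <- lapply(cases, function(cs) {
      if (m %in% sim_methods) rank_diseases_by_similarity(cs, kb, ic, m)
      else if (m == "ppo") ppo_rank(cs, kb, ic, ppo, profiles = profiles)
      else if (m == "cnb") cnb_rank(cs, cnb_model, kb)
      else mlp_rank(cs, mlp_model, kb)
    })
    stats::setNames(preds, ids)
  }
  predictions <- stats::setNames(lapply(methods, run_method), methods)

  null <- NULL
  if (ensemble) {
    members <- intersect(ensemble_members, methods)
    if (length(members) < 2L) stop("ensemble needs at least two member methods")
    null <- fit_null(length(members), mc_samples = null_samples,
                     seed = derive_seed(seed, "ensemble-null"))
    predictions$ensemble <- stats::setNames(lapply(ids, function(cid) {
      ensemble_rank(lapply(members, function(m) predictions[[m]][[cid]]),
                    kb, null)
    }), ids)
  }
  structure(list(predictions = predictions,
                 methods = names(predictions),
                 seed = seed, null = null),
            class = "phb_diagnosis")
}

#' Evaluate a diagnosis run per method
#'
#' @param diag a `phb_diagnosis` from [diagnose()].
#' @param cases the cases it was run on.
#' @param ks top-k cutoffs.
#' @param n_boot bootstrap repetitions per method (0 = none).
#' @param seed bootstrap seed.
#' @return Named list method -> `phb_eval`.
#' @export
evaluate_diagnosis <- function(diag, cases, ks = c(1L, 3L, 10L),
                               n_boot = 0L, seed = 1L) {
  stopifnot(inherits(diag, "phb_diagnosis"))
  lapply(stats::setNames(nm = diag$methods), function(m) {
    evaluate_predictions(diag$predictions[[m]], cases, ks = ks,
                         n_boot = n_boot, seed = seed)
  })
}

#' Run a full simulated scenario
#'
#' Generates a synthetic world from `cfg`, diagnoses the cases with the
#' requested methods, and evaluates every method. Deterministic given
#' `cfg$seed` and `seed`.
#'
#' @param cfg a `phb_sim_config`.
#' @param n_cases cases to simulate.
#' @param methods,seed,... forwarded to [diagnose()].
#' @param ks top-k cutoffs for evaluation.
#' @return List with `ontology`, `kb`, `cases`, `diagnosis`, `evaluation`.
#' @export
run_scenario <- function(cfg, n_cases = 100L,
                         methods = c("icto", "ppo", "cnb", "mlp"),
                         seed = 1L, ks = c(1L, 3L, 10L), ...) {
  o <- sim_ontology(cfg)
  kb <- sim_kb(o, cfg)
  cases <- sim_cases(kb, cfg, n_cases = n_cases)
  if (length(cases) == 0L) stop("simulation produced no usable cases")
  diag <- diagnose(cases, kb, methods = methods, seed = seed, ...)
  ev <- evaluate_diagnosis(diag, cases, ks = ks)
  list(ontology = o, kb = kb, cases = cases, diagnosis = diag,
       evaluation = ev)
}
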