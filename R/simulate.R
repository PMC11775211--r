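#' Configuration for the synthetic world generator
#'
#' The generator emulates the structures real diagnostic data take: a
#' single-rooted is-a DAG of phenotype terms, per-disease annotation sets
#' biased toward specific (deep) terms with partial frequency information,
#' and patient cases derived from a disease's annotations and corrupted by
#' "imprecise" phenotypes (replaced by proper ancestors) and "noise"
#' phenotypes (unrelated to the disease).
#'
#' @param n_terms terms in the ontology (>= 2).
#' @param n_diseases diseases in the knowledge base.
#' @param dag_branching mean parents-per-node control; values above 1 add
#'   second parents creating diamond paths (1.2 gives about 20% of nodes a
#'   second parent).
#' @param annotations_per_disease integer range `c(lo, hi)`.
#' @param frequency_coverage fraction of annotations receiving a frequency.
#' @param duplicate_fraction fraction of diseases arranged in pairs sharing
#'   identical annotation sets (emulating non-specific annotation sets);
#'   `round(duplicate_fraction * n_diseases)` pairs are created.
#' @param noise_rate fraction of each case's terms replaced by unrelated
#'   terms.
#' @param imprecision_rate fraction replaced by proper ancestors.
#' @param terms_per_case integer range for case sizes, or `NULL` to use the
#'   disease's full annotation set.
#' @param seed mandatory integer seed.
#' @return A list of class `phb_sim_config`.
#' @export
sim_config <- function(n_terms = 60L, n_diseases = 20L, dag_branching = 1.2,
                       annotations_per_disease = c(4L, 8L),
                       frequency_coverage = 0.5, duplicate_fraction = 0,
                       noise_rate = 0, imprecision_rate = 0,
                       terms_per_case = NULL, seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  stopifnot(n_terms >= 2L, n_diseases >= 1L,
            noise_rate >= 0, noise_rate <= 1,
            imprecision_rate >= 0, imprecision_rate <= 1,
            frequency_coverage >= 0, frequency_coverage <= 1,
            length(annotations_per_disease) == 2L,
            all(annotations_per_disease >= 1L))
  structure(list(n_terms = as.integer(n_terms),
                 n_diseases = as.integer(n_diseases),
                 dag_branching = dag_branching,
                 annotations_per_disease = as.integer(annotations_per_disease),
                 frequency_coverage = frequency_coverage,
                 duplicate_fraction = duplicate_fraction,
                 noise_rate = noise_rate,
                 imprecision_rate = imprecision_rate,
                 terms_per_case = terms_per_case,
                 seed = as.integer(seed)),
            class = "phb_sim_config")
}

sim_term_id <- function(i) sprintf("SP:%07d", i)

#' Generate a synthetic single-rooted DAG ontology
#'
#' Term i (i > 1) attaches to one uniformly chosen earlier term; with
#' probability `dag_branching - 1` it also gains a second, distinct earlier
#' parent, which creates diamond paths. Because edges always point from
#' earlier to later terms the construction is acyclic, and term 1 is the
#' unique root.
#'
#' @param cfg a `phb_sim_config`.
#' @return A validated `phb_ontology`.
#' @export
sim_ontology <- function(cfg) {
  stopifnot(inherits(cfg, "phb_sim_config"))
  withr_seed(cfg$seed + 1L, {
    n <- cfg$n_terms
    p2 <- min(max(cfg$dag_branching - 1, 0), 0.9)
    ids <- sim_term_id(seq_len(n))
    parents <- stats::setNames(vector("list", n), ids)
    parents[[ids[[1L]]]] <- character(0)
    for (i in 2:n) {
      pool <- seq_len(i - 1L)
      p <- if (length(pool) == 1L) pool else sample(pool, 1L)
      ps <- p
      if (length(pool) > 1L && stats::runif(1L) < p2) {
        q <- sample(setdiff(pool, p), 1L)
        ps <- c(ps, q)
      }
      parents[[ids[[i]]]] <- ids[ps]
    }
    ontology(ids, parents,
             names = stats::setNames(paste("synthetic term", seq_len(n)), ids))
  })
}

sim_freq_mixture <- c(1.0, 0.895, 0.545, 0.17)      # class midpoints
sim_freq_weights <- c(0.2, 0.4, 0.3, 0.1)           # obligate .. occasional

#' Generate a synthetic disease-phenotype knowledge base
#'
#' Each disease draws an annotation-set size from the configured range and
#' samples non-root terms with probability proportional to 1 + depth (real
#' annotation corpora skew toward specific terms). A configured fraction of
#' annotations receives frequency records drawn from the class-midpoint
#' mixture (20% obligate, 40% very frequent, 30% frequent, 10% occasional).
#' With `duplicate_fraction` 0, annotation sets are guaranteed pairwise
#' distinct; otherwise the first `round(duplicate_fraction * n_diseases)`
#' pairs of diseases share identical term sets.
#'
#' @param o a `phb_ontology` from [sim_ontology()].
#' @param cfg a `phb_sim_config`.
#' @return A `phb_kb` with codes `SIM:0001`, `SIM:0002`, ...
#' @export
sim_kb <- function(o, cfg) {
  stopifnot(inherits(o, "phb_ontology"), inherits(cfg, "phb_sim_config"))
  withr_seed(cfg$seed + 2L, {
    pool <- setdiff(o$terms, o$root)
    w <- 1 + o$depth[pool]
    n <- cfg$n_diseases
    lo <- cfg$annotations_per_disease[[1L]]
    hi <- cfg$annotations_per_disease[[2L]]
    n_pairs <- round(cfg$duplicate_fraction * n)
    seen <- character(0)
    sets <- vector("list", n)
    for (k in seq_len(n)) {
      if (n_pairs > 0 && k <= 2L * n_pairs && k %% 2L == 0L) {
        sets[[k]] <- sets[[k - 1L]]   # duplicate pair partner
        next
      }
      for (try in 1:100) {
        sz <- if (lo == hi) lo else sample(lo:hi, 1L)
        sz <- min(sz, length(pool))
        s <- sort(sample(pool, sz, prob = w))
        key <- paste(s, collapse = ",")
        if (!key %in% seen) break
      }
      seen <- c(seen, key)
      sets[[k]] <- s
    }
    entries <- vector("list", n)
    for (k in seq_len(n)) {
      s <- sets[[k]]
      nf <- round(cfg$frequency_coverage * length(s))
      withf <- if (nf > 0) sample(seq_along(s), nf) else integer(0)
      ann <- stats::setNames(vector("list", length(s)), s)
      for (i in withf) {
        v <- sample(sim_freq_mixture, 1L, prob = sim_freq_weights)
        ann[[i]] <- list(value = v, provenance = "frequency-class")
      }
      entries[[k]] <- list(codes = sprintf("SIM:%04d", k),
                           name = paste("synthetic disease", k),
                           annotations = ann)
    }
    knowledge_base(entries, o,
                   source_manifest = data.frame(source = "simulate",
                                                n_records = sum(lengths(sets))))
  })
}

#' Generate synthetic patient cases from a knowledge base
#'
#' Each case picks a disease uniformly, samples its query from the disease's
#' annotation terms (weighted by recorded frequency where available,
#' `0.5` for frequency-unknown terms), then corrupts it: an
#' `imprecision_rate` fraction of terms is replaced by random proper
#' ancestors, and a `noise_rate` fraction by terms lying outside the
#' ancestor/descendant cones of all the disease's annotation terms. Cases
#' ending with fewer than `min_terms` distinct terms are discarded, matching
#' the evaluation filter.
#'
#' @param kb a `phb_kb`.
#' @param cfg a `phb_sim_config`.
#' @param n_cases number of cases to attempt.
#' @param min_terms inclusion filter (default 3).
#' @return List of `phb_case` (possibly shorter than `n_cases`).
#' @export
sim_cases <- function(kb, cfg, n_cases = 100L, min_terms = 3L) {
  stopifnot(inherits(kb, "phb_kb"), inherits(cfg, "phb_sim_config"))
  o <- kb$ontology
  withr_seed(cfg$seed + 3L, {
    out <- list()
    for (i in seq_len(n_cases)) {
      k <- sample(length(kb$diseases), 1L)
      d <- kb$diseases[[k]]
      h <- names(d$annotations)
      if (length(h) < 1L) {
        warning("disease without annotations skipped in case simulation")
        next
      }
      if (is.null(cfg$terms_per_case)) {
        q <- h
      } else {
        lo <- cfg$terms_per_case[[1L]]; hi <- cfg$terms_per_case[[2L]]
        sz <- min(if (lo == hi) lo else sample(lo:hi, 1L), length(h))
        wts <- vapply(h, function(t) {
          r <- d$annotations[[t]]
          if (is.null(r) || is.na(r$value)) 0.5 else r$value
        }, 0)
        q <- sample(h, sz, prob = wts)
      }
      n_imp <- round(cfg$imprecision_rate * length(q))
      if (n_imp > 0) {
        repl <- sample(seq_along(q), n_imp)
        for (j in repl) {
          anc <- setdiff(o$anc[[q[[j]]]], o$root)
          if (length(anc) == 0L) anc <- o$anc[[q[[j]]]]
          if (length(anc) > 0L) q[[j]] <- sample(anc, 1L)
        }
      }
      n_noise <- round(cfg$noise_rate * length(q))
      if (n_noise > 0) {
        related <- unique(c(h, unlist(o$anc[h], use.names = FALSE),
                            unlist(o$desc[h], use.names = FALSE)))
        pool <- setdiff(o$terms, related)
        if (length(pool) > 0L) {
          repl <- sample(seq_along(q), min(n_noise, length(q)))
          noise <- sample(pool, length(repl), replace = length(pool) < length(repl))
          q[repl] <- noise
        }
      }
      q <- unique(q)
      if (length(q) < min_terms) next
      out[[length(out) + 1L]] <- patient_case(
        q, true_codes = d$codes,
        case_id = sprintf("sim-case-%04d", i))
    }
    out
  })
}

#' Packaged simulation scenario presets
#'
#' Four presets echoing corrupted-case regimes: `noise-low`/`noise-high`
#' replace 20%/50% of case terms with unrelated ones, and
#' `imprecise-low`/`imprecise-high` replace 20%/50% with proper ancestors.
#'
#' @param name preset name.
#' @param seed integer seed.
#' @return A `phb_sim_config`.
#' @export
sim_preset <- function(name = c("noise-low", "noise-high",
                                "imprecise-low", "imprecise-high"),
                       seed = 1L) {
  name <- match.arg(name)
  rates <- switch(name,
    "noise-low" = c(noise = 0.2, imprec = 0),
    "noise-high" = c(noise = 0.5, imprec = 0),
    "imprecise-low" = c(noise = 0, imprec = 0.2),
    "imprecise-high" = c(noise = 0, imprec = 0.5))
  sim_config(noise_rate = rates[["noise"]],
             imprecision_rate = rates[["imprec"]],
             terms_per_case = c(4L, 8L), seed = seed)
}

#' Write a knowledge base as an HPOA-style TSV
#'
#' Columns: database_id, disease_name, qualifier, hpo_id, frequency.
#' Only the primary code is written per disease; [load_hpoa()] reads the
#' file back.
#'
#' @param kb a `phb_kb`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hpoa <- function(kb, path) {
  stopifnot(inherits(kb, "phb_kb"))
  rows <- list()
  for (d in kb$diseases) {
    for (t in names(d$annotations)) {
      r <- d$annotations[[t]]
      rows[[length(rows) + 1L]] <- data.frame(
        database_id = d$codes[[1L]], disease_name = d$name, qualifier = "",
        hpo_id = t,
        frequency = if (is.null(r) || is.na(r$value)) "" else
          format(r$value, digits = 10),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#database_id\tdisease_name\tqualifier\thpo_id\tfrequency", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
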