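#' Construct a phenotype ontology from parent links
#'
#' Builds and validates the directed acyclic graph (DAG) of phenotype terms
#' that every diagnostic method in this package operates on. Terms are
#' identified by CURIEs (`"HP:0000118"`-style strings); edges are is-a links
#' from a child term to each of its parents. The graph must be acyclic and
#' single-rooted: exactly one term may have no parents, and every other term
#' must reach it by following parent links.
#'
#' @param terms character vector of term CURIEs (`"PREFIX:digits"`).
#' @param parents named list mapping each term to the character vector of its
#'   parent CURIEs (the root maps to `character(0)` or may be omitted).
#' @param names optional named character vector of human-readable labels.
#' @return An object of class `phb_ontology` with components `terms`,
#'   `parents`, `children`, `root`, `depth` (shortest distance from the
#'   root), `topo` (a topological order, parents before children), and
#'   precomputed `anc`/`desc` closures (proper ancestors / descendants,
#'   excluding the term itself).
#' @seealso [load_obo()], [ancestors()], [annotation_closure()]
#' @export
ontology <- function(terms, parents, names = NULL) {
  terms <- unique(as.character(terms))
  if (length(terms) < 1L) stop("ontology needs at least one term")
  bad <- terms[!is_term_id(terms)]
  if (length(bad) > 0L) {
    stop("malformed term IDs (expected PREFIX:digits): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  par <- stats::setNames(vector("list", length(terms)), terms)
  for (t in names(parents)) {
    if (!t %in% terms) stop("parent map references unknown term: ", t)
    p <- unique(as.character(parents[[t]]))
    unknown <- setdiff(p, terms)
    if (length(unknown) > 0L) {
      stop("term ", t, " has unknown parent(s): ",
           paste(unknown, collapse = ", "))
    }
    if (t %in% p) stop("self-loop at term ", t)
    par[[t]] <- p
  }
  for (t in terms) if (is.null(par[[t]])) par[[t]] <- character(0)

  roots <- terms[vapply(par, length, 1L) == 0L]
  if (length(roots) != 1L) {
    stop("ontology must have exactly one root; found ",
         length(roots), ": ", paste(utils::head(roots, 5L), collapse = ", "))
  }
  root <- roots[[1L]]

  chl <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) chl[[t]] <- character(0)
  for (t in terms) for (p in par[[t]]) chl[[p]] <- c(chl[[p]], t)

  # Kahn's algorithm: topological order + cycle detection.
  indeg <- vapply(par, length, 1L)
  queue <- root
  topo <- character(0)
  while (length(queue) > 0L) {
    t <- queue[[1L]]; queue <- queue[-1L]
    topo <- c(topo, t)
    for (ch in chl[[t]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(topo) < length(terms)) {
    cyc <- terms[indeg > 0L]
    stop("cycle detected involving term(s): ",
         paste(utils::head(find_one_cycle(par, cyc), 10L), collapse = " -> "))
  }

  anc <- stats::setNames(vector("list", length(terms)), terms)
  depth <- stats::setNames(integer(length(terms)), terms)
  for (t in topo) {
    ps <- par[[t]]
    if (length(ps) == 0L) {
      anc[[t]] <- character(0); depth[[t]] <- 0L
    } else {
      anc[[t]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
      depth[[t]] <- min(depth[ps]) + 1L
    }
  }
  desc <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) desc[[t]] <- character(0)
  for (t in rev(topo)) {
    for (p in par[[t]]) desc[[p]] <- unique(c(desc[[p]], t, desc[[t]]))
  }

  lab <- stats::setNames(rep(NA_character_, length(terms)), terms)
  if (!is.null(names)) lab[base::names(names)] <- unname(names)

  structure(
    list(terms = terms, parents = par, children = chl, root = root,
         depth = depth, topo = topo, anc = anc, desc = desc, name = lab),
    class = "phb_ontology"
  )
}

is_term_id <- function(x) grepl("^[A-Za-z][A-Za-z0-9_]*:[0-9]+$", x)

# Walk parent links from a node known to be on a cycle until a repeat is seen.
find_one_cycle <- function(par, candidates) {
  start <- candidates[[1L]]
  path <- start
  cur <- start
  repeat {
    nxt <- intersect(par[[cur]], candidates)
    if (length(nxt) == 0L) return(path)
    cur <- nxt[[1L]]
    if (cur %in% path) return(c(path[which(path == cur):length(path)], cur))
    path <- c(path, cur)
  }
}

#' @export
print.phb_ontology <- function(x, ...) {
  cat("<phb_ontology> ", length(x$terms), " terms, ",
      sum(vapply(x$parents, length, 1L)), " is-a edges, root ", x$root,
      ", max depth ", max(x$depth), "\n", sep = "")
  invisible(x)
}

#' Load an ontology from an OBO flat file
#'
#' Reads the stanza-based OBO 1.2/1.4 format: `[Term]` stanzas with `id`,
#' `name`, `is_a`, `is_obsolete` and `synonym` tags. Only `is_a` edges define
#' the DAG; obsolete stanzas are dropped (together with edges pointing at
#' them); other relationship types are ignored. The result is validated by
#' [ontology()] (acyclic, single root).
#'
#' @param path path to an OBO file.
#' @return A `phb_ontology`.
#' @export
load_obo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  in_term <- FALSE
  cur <- NULL
  stanzas <- list()
  flush <- function(cur) if (!is.null(cur) && !is.null(cur$id)) c(stanzas, list(cur)) else stanzas
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "!")) next
    if (grepl("^\\[.*\\]$", ln)) {
      stanzas <- flush(cur)
      in_term <- identical(ln, "[Term]")
      cur <- if (in_term) list(is_a = character(0), obsolete = FALSE,
                               synonyms = character(0)) else NULL
      next
    }
    if (!in_term) next
    m <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L) {
      stop("OBO parse failure at line ", i, ": ", lines[[i]])
    }
    tag <- m[[2L]]; val <- m[[3L]]
    val <- sub("\\s*!.*$", "", val)   # trailing comments
    if (tag == "id") {
      if (!is_term_id(val)) stop("OBO parse failure at line ", i,
                                 ": malformed id '", val, "'")
      cur$id <- canonical_curie(val)
    } else if (tag == "is_a") {
      cur$is_a <- c(cur$is_a, canonical_curie(trimws(val)))
    } else if (tag == "is_obsolete") {
      cur$obsolete <- identical(tolower(trimws(val)), "true")
    } else if (tag == "name") {
      cur$name <- val
    } else if (tag == "synonym") {
      cur$synonyms <- c(cur$synonyms, val)
    }
  }
  stanzas <- flush(cur)
  if (length(stanzas) == 0L) stop("no [Term] stanzas found in ", path)
  keep <- !vapply(stanzas, `[[`, FALSE, "obsolete")
  stanzas <- stanzas[keep]
  ids <- vapply(stanzas, `[[`, "", "id")
  parents <- stats::setNames(
    lapply(stanzas, function(s) intersect(s$is_a, ids)), ids)
  labels <- stats::setNames(
    vapply(stanzas, function(s) s$name %||% NA_character_, ""), ids)
  ontology(ids, parents, names = labels)
}

canonical_curie <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1L]]
  paste0(toupper(parts[[1L]]), ":", paste(parts[-1L], collapse = ":"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an ontology as an OBO flat file
#'
#' Emits a minimal OBO 1.2 document ([load_obo()] round-trips it).
#'
#' @param o a `phb_ontology`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(o, path) {
  stopifnot(inherits(o, "phb_ontology"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in o$topo) {
    writeLines("", con)
    writeLines("[Term]", con)
    writeLines(paste0("id: ", t), con)
    if (!is.na(o$name[[t]])) writeLines(paste0("name: ", o$name[[t]]), con)
    for (p in o$parents[[t]]) writeLines(paste0("is_a: ", p), con)
  }
  invisible(path)
}

check_terms <- function(o, t) {
  unknown <- setdiff(t, o$terms)
  if (length(unknown) > 0L) {
    stop("unknown term(s): ", paste(utils::head(unknown, 5L), collapse = ", "))
  }
  invisible(TRUE)
}

#' Ancestors of a term
#'
#' Transitive closure over is-a parent links.
#'
#' @param o a `phb_ontology`.
#' @param t a single term CURIE present in `o`.
#' @param include_self include `t` itself in the result?
#' @return Character vector of term CURIEs.
#' @export
ancestors <- function(o, t, include_self = FALSE) {
  stopifnot(inherits(o, "phb_ontology"), length(t) == 1L)
  check_terms(o, t)
  if (include_self) c(t, o$anc[[t]]) else o$anc[[t]]
}

#' Descendants of a term
#'
#' @inheritParams ancestors
#' @return Character vector of term CURIEs.
#' @export
descendants <- function(o, t, include_self = FALSE) {
  stopifnot(inherits(o, "phb_ontology"), length(t) == 1L)
  check_terms(o, t)
  if (include_self) c(t, o$desc[[t]]) else o$desc[[t]]
}

#' Ancestor closure of a term set
#'
#' The annotation closure A(H): all terms of `terms` together with every
#' ancestor of each. This is the propagated-annotation semantics under which
#' a disease annotated with a specific phenotype implicitly carries all of
#' its more general forms.
#'
#' @param o a `phb_ontology`.
#' @param terms character vector of term CURIEs (may be empty).
#' @return Character vector (no duplicates); empty input gives empty output.
#' @export
annotation_closure <- function(o, terms) {
  stopifnot(inherits(o, "phb_ontology"))
  if (length(terms) == 0L) return(character(0))
  terms <- unique(as.character(terms))
  check_terms(o, terms)
  unique(c(terms, unlist(o$anc[terms], use.names = FALSE)))
}

#' Term background probabilities and information content
#'
#' For each ontology term t, the background probability P(t) is the fraction
#' of knowledge-base diseases annotated with t — by default counting a
#' disease as annotated with t whenever t lies in the ancestor closure of its
#' annotation set (`closure = TRUE`); with `closure = FALSE` only direct
#' annotations count. Information content is IC(t) = -log P(t) in nats.
#' Terms annotating no disease are floored at the smallest observed nonzero
#' probability so that their IC stays finite (queries may mention terms the
#' knowledge base never uses).
#'
#' @param o a `phb_ontology`.
#' @param kb a `phb_kb` (see [knowledge_base()]).
#' @param closure count diseases through ancestor-closed annotation sets?
#' @return An object of class `phb_ictable`: list with named numeric vectors
#'   `background_prob` and `ic` over all ontology terms, the `floor`
#'   probability used for zero-count terms, and the `closure` flag.
#' @export
compute_ic <- function(o, kb, closure = TRUE) {
  stopifnot(inherits(o, "phb_ontology"), inherits(kb, "phb_kb"))
  n <- length(kb$diseases)
  if (n == 0L) stop("cannot compute information content from an empty knowledge base")
  counts <- stats::setNames(numeric(length(o$terms)), o$terms)
  for (d in kb$diseases) {
    ts <- names(d$annotations)
    if (closure) ts <- annotation_closure(o, ts)
    counts[ts] <- counts[ts] + 1
  }
  p <- counts / n
  nz <- p[p > 0]
  if (length(nz) == 0L) stop("knowledge base has no annotations")
  floor_p <- min(nz)
  p[p == 0] <- floor_p
  structure(list(background_prob = p, ic = -log(p),
                 floor = floor_p, closure = closure),
            class = "phb_ictable")
}

# IC lookup tolerant of terms missing from the table (floored, with warning).
ic_of <- function(ic, terms) {
  out <- ic$ic[terms]
  miss <- is.na(out)
  if (any(miss)) {
    warning("term(s) missing from IC table, floored: ",
            paste(utils::head(terms[miss], 5L), collapse = ", "))
    out[miss] <- -log(ic$floor)
  }
  unname(out)
}

bgprob_of <- function(ic, terms) {
  out <- ic$background_prob[terms]
  miss <- is.na(out)
  if (any(miss)) out[miss] <- ic$floor
  unname(out)
}

#' Summarize an ontology as JSON
#'
#' Writes term/edge counts and a depth histogram.
#'
#' @param o a `phb_ontology`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ontology_summary <- function(o, path) {
  stopifnot(inherits(o, "phb_ontology"))
  dh <- table(o$depth)
  jsonlite::write_json(
    list(n_terms = length(o$terms),
         n_edges = sum(vapply(o$parents, length, 1L)),
         root = o$root,
         depth_histogram = stats::setNames(as.integer(dh), names(dh))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
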