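#' Build a disease-phenotype knowledge base
#'
#' A knowledge base is an ordered list of disease entries, each carrying one
#' or more source-qualified codes (e.g. `OMIM:261600`), a name, and a set of
#' phenotype annotations with optional frequency records. Entries are sorted
#' by primary code so that builds are deterministic.
#'
#' @param diseases list of entries; each a list with `codes` (character,
#'   non-empty), `name` (string) and `annotations` (named list mapping term
#'   CURIE to a frequency record from [parse_frequency()] or `NULL` for
#'   frequency-unknown).
#' @param ontology a `phb_ontology` all annotation terms must belong to.
#' @param source_manifest optional data.frame (source, n_records) for audit.
#' @return An object of class `phb_kb`.
#' @export
knowledge_base <- function(diseases, ontology, source_manifest = NULL) {
  stopifnot(inherits(ontology, "phb_ontology"))
  seen <- character(0)
  for (d in diseases) {
    if (length(d$codes) < 1L) stop("disease entry without codes")
    dup <- intersect(d$codes, seen)
    if (length(dup) > 0L) {
      stop("code appears in two entries after merging: ", dup[[1L]])
    }
    seen <- c(seen, d$codes)
    ts <- names(d$annotations)
    if (anyDuplicated(ts)) stop("duplicate annotation terms for ", d$codes[[1L]])
    check_terms(ontology, ts)
    if (length(ts) < 1L) d$flag_sparse <- TRUE
  }
  diseases <- lapply(diseases, function(d) {
    d$codes <- sort(unique(d$codes))
    d$flag_sparse <- length(d$annotations) < 1L
    d
  })
  ord <- order(vapply(diseases, function(d) d$codes[[1L]], ""))
  structure(list(diseases = diseases[ord], ontology = ontology,
                 source_manifest = source_manifest),
            class = "phb_kb")
}

#' @export
print.phb_kb <- function(x, ...) {
  na <- sum(vapply(x$diseases, function(d) length(d$annotations), 1L))
  cat("<phb_kb> ", length(x$diseases), " diseases, ", na, " annotations\n",
      sep = "")
  invisible(x)
}

kb_codes <- function(kb) {
  vapply(kb$diseases, function(d) d$codes[[1L]], "")
}

kb_code_index <- function(kb) {
  # map every code (not only primary) to its entry index
  idx <- integer(0)
  for (i in seq_along(kb$diseases)) {
    cs <- kb$diseases[[i]]$codes
    idx[cs] <- i
  }
  idx
}

#' Read HPOA-style disease-phenotype annotations
#'
#' Tab-separated with columns `database_id`, `disease_name`, `qualifier`,
#' `hpo_id`, `frequency` (header optional, comment lines start with `#`).
#' Files with only two columns are read as (database_id, hpo_id). Rows whose
#' term ID is malformed are dropped, with the rejection count reported as a
#' message.
#'
#' @param path TSV file path.
#' @param source label recorded on every returned row.
#' @return data.frame with columns `code`, `name`, `term`, `frequency`
#'   (`NA` when absent), `source`.
#' @export
load_hpoa <- function(path, source = "unknown") {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no data rows in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- vapply(fields, length, 1L)
  if (any(ncol < 2L)) stop("format error: rows with fewer than 2 tab-separated columns in ", path)
  # drop a header row if present
  if (grepl("database_id|disease[_ ]?id", fields[[1L]][[1L]], ignore.case = TRUE)) {
    fields <- fields[-1L]
  }
  if (length(fields) == 0L) stop("no data rows in ", path)
  get <- function(f, i) if (length(f) >= i) f[[i]] else NA_character_
  two_col <- all(vapply(fields, length, 1L) == 2L)
  rows <- lapply(fields, function(f) {
    if (two_col) {
      data.frame(code = f[[1L]], name = NA_character_, term = f[[2L]],
                 frequency = NA_character_, stringsAsFactors = FALSE)
    } else {
      data.frame(code = f[[1L]], name = get(f, 2L), term = get(f, 4L),
                 frequency = get(f, 5L), stringsAsFactors = FALSE)
    }
  })
  df <- do.call(rbind, rows)
  df$frequency[!is.na(df$frequency) & !nzchar(trimws(df$frequency))] <- NA_character_
  ok <- !is.na(df$term) & is_term_id(df$term)
  if (sum(!ok) > 0L) {
    message(sum(!ok), " row(s) with malformed term IDs rejected from ", path)
  }
  df <- df[ok, , drop = FALSE]
  df$code <- vapply(df$code, canonical_curie, "")
  df$term <- vapply(df$term, canonical_curie, "")
  df$source <- source
  rownames(df) <- NULL
  df
}

# HPO frequency-class subontology: class -> interval midpoint.
# Excluded (0%) annotations are dropped at merge time.
freq_class_midpoints <- c(
  "HP:0040280" = 1.0,    # obligate, 100%
  "HP:0040281" = 0.895,  # very frequent, 80-99%
  "HP:0040282" = 0.545,  # frequent, 30-79%
  "HP:0040283" = 0.17,   # occasional, 5-29%
  "HP:0040284" = 0.025,  # very rare, 1-4%
  "HP:0040285" = 0.0     # excluded, 0%
)
freq_class_labels <- c(
  "obligate" = 1.0, "very frequent" = 0.895, "frequent" = 0.545,
  "occasional" = 0.17, "very rare" = 0.025, "excluded" = 0.0
)

#' Parse a raw annotation frequency
#'
#' Accepts fractions (`"12/45"`), percentages (`"30%"`), bare probabilities
#' (`"0.3"`), and HPO frequency-class CURIEs or labels, which map to the
#' midpoints of their class intervals (obligate 1.0, very frequent 0.895,
#' frequent 0.545, occasional 0.17, very rare 0.025, excluded 0.0).
#' Unparseable strings yield `provenance = "default"` with `value = NA`; the
#' Bayesian model substitutes its default probability `dp` for those.
#'
#' @param raw a single non-empty string.
#' @param midpoints named numeric overriding the class-midpoint table.
#' @return list with `value` (numeric in \[0,1\] or `NA`) and `provenance`
#'   (one of `"fraction"`, `"percentage"`, `"frequency-class"`, `"default"`).
#' @export
parse_frequency <- function(raw, midpoints = freq_class_midpoints) {
  stopifnot(is.character(raw), length(raw) == 1L, nzchar(raw))
  raw <- trimws(raw)
  if (grepl("^[0-9]+\\s*/\\s*[0-9]+$", raw)) {
    ab <- as.numeric(strsplit(raw, "/", fixed = TRUE)[[1L]])
    if (ab[[2L]] == 0) stop("zero denominator in frequency '", raw, "'")
    return(list(value = min(1, ab[[1L]] / ab[[2L]]), provenance = "fraction"))
  }
  if (grepl("^[0-9.]+\\s*%$", raw)) {
    return(list(value = min(1, as.numeric(sub("%.*$", "", raw)) / 100),
                provenance = "percentage"))
  }
  if (raw %in% names(midpoints)) {
    return(list(value = unname(midpoints[[raw]]), provenance = "frequency-class"))
  }
  lab <- tolower(raw)
  if (lab %in% names(freq_class_labels)) {
    return(list(value = unname(freq_class_labels[[lab]]),
                provenance = "frequency-class"))
  }
  if (grepl("^[0-9]*\\.?[0-9]+$", raw)) {
    v <- as.numeric(raw)
    if (v >= 0 && v <= 1) return(list(value = v, provenance = "fraction"))
  }
  list(value = NA_real_, provenance = "default")
}

#' Merge annotation sources into a knowledge base
#'
#' Rows from different sources describing the same disease (per the
#' equivalence table) are consolidated into one entry whose codes are the
#' union of the class and whose annotation set is the union across sources.
#' When two sources give a frequency for the same term, the record from the
#' higher-priority source wins (`source_priority`, first = highest). Codes
#' in no equivalence class remain singleton entries. Annotations with an
#' "excluded" (zero) frequency are dropped.
#'
#' @param sources list of data.frames as returned by [load_hpoa()].
#' @param ontology a `phb_ontology`; rows whose term is absent are dropped
#'   with a message.
#' @param equivalence list of character vectors, each one class of codes
#'   naming the same disease; classes must be disjoint.
#' @param source_priority character vector of source labels, first = highest.
#' @return A `phb_kb`.
#' @export
merge_sources <- function(sources, ontology,
                          equivalence = list(),
                          source_priority = c("CCRD", "OMIM", "Orphanet")) {
  stopifnot(inherits(ontology, "phb_ontology"))
  all_codes <- unlist(equivalence, use.names = FALSE)
  if (anyDuplicated(all_codes)) {
    stop("overlapping equivalence classes: code ",
         all_codes[duplicated(all_codes)][[1L]], " appears twice")
  }
  rows <- do.call(rbind, sources)
  if (is.null(rows) || nrow(rows) == 0L) stop("no annotation rows to merge")
  drop <- !rows$term %in% ontology$terms
  if (any(drop)) {
    message(sum(drop), " annotation row(s) with terms absent from the ontology dropped")
    rows <- rows[!drop, , drop = FALSE]
  }

  class_of <- character(0)
  for (i in seq_along(equivalence)) {
    class_of[equivalence[[i]]] <- paste0("class", i)
  }
  key <- ifelse(rows$code %in% names(class_of), class_of[rows$code], rows$code)

  prio <- function(src) {
    p <- match(src, source_priority)
    ifelse(is.na(p), length(source_priority) + 1L, p)
  }

  entries <- list()
  for (k in unique(key)) {
    sub <- rows[key == k, , drop = FALSE]
    codes <- sort(unique(sub$code))
    nm <- sub$name[!is.na(sub$name)]
    ann <- list()
    # stable order: by term, then by source priority; first freq-bearing wins
    sub <- sub[order(sub$term, prio(sub$source)), , drop = FALSE]
    excluded <- character(0)
    for (i in seq_len(nrow(sub))) {
      t <- sub$term[[i]]
      fr <- sub$frequency[[i]]
      rec <- if (is.na(fr)) NULL else parse_frequency(fr)
      if (!is.null(rec) && !is.na(rec$value) && rec$value == 0) {
        excluded <- c(excluded, t)  # "excluded" class: drop annotation
        next
      }
      if (!t %in% names(ann)) {
        ann[t] <- list(rec)   # [[<- would drop the element when rec is NULL
      } else if (is.null(ann[[t]]) && !is.null(rec)) {
        ann[[t]] <- rec
      }
    }
    ann <- ann[setdiff(names(ann), excluded)]
    entries[[k]] <- list(codes = codes,
                         name = if (length(nm) > 0L) nm[[1L]] else k,
                         annotations = ann)
  }
  manifest <- data.frame(
    source = vapply(sources, function(s) s$source[[1L]], ""),
    n_records = vapply(sources, nrow, 1L))
  knowledge_base(unname(entries), ontology, source_manifest = manifest)
}

#' Restrict a knowledge base to a set of disease codes
#'
#' Keeps entries having at least one code in `codes` (order preserved).
#' Unknown codes are reported; an empty result is allowed with a warning.
#'
#' @param kb a `phb_kb`.
#' @param codes non-empty character vector of disease codes.
#' @return A `phb_kb` over the same ontology.
#' @export
restrict_kb <- function(kb, codes) {
  stopifnot(inherits(kb, "phb_kb"), length(codes) >= 1L)
  idx <- kb_code_index(kb)
  unknown <- setdiff(codes, names(idx))
  if (length(unknown) > 0L) {
    message(length(unknown), " unknown code(s) ignored: ",
            paste(utils::head(unknown, 5L), collapse = ", "))
  }
  keep <- sort(unique(idx[intersect(codes, names(idx))]))
  if (length(keep) == 0L) warning("restriction produced an empty knowledge base")
  structure(list(diseases = kb$diseases[keep], ontology = kb$ontology,
                 source_manifest = kb$source_manifest),
            class = "phb_kb")
}

#' Write / read a knowledge base as canonical JSON
#'
#' Entries are serialized with sorted keys so that identical knowledge bases
#' produce byte-identical files; [read_kb()] restores an identical object
#' (bound to the ontology supplied by the caller).
#'
#' @param kb a `phb_kb`.
#' @param path JSON file path.
#' @return `path` invisibly (writer); a `phb_kb` (reader).
#' @export
write_kb <- function(kb, path) {
  stopifnot(inherits(kb, "phb_kb"))
  ser <- lapply(kb$diseases, function(d) {
    ts <- sort(names(d$annotations))
    list(codes = as.list(d$codes), name = d$name,
         annotations = lapply(stats::setNames(ts, ts), function(t) {
           r <- d$annotations[[t]]
           if (is.null(r)) NULL
           else list(value = r$value, provenance = r$provenance)
         }))
  })
  jsonlite::write_json(list(schema = "phb_kb/1", diseases = ser), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_kb
#' @param ontology the `phb_ontology` to bind annotations against.
#' @export
read_kb <- function(path, ontology) {
  raw <- jsonlite::read_json(path)
  if (!identical(raw$schema, "phb_kb/1")) stop("unrecognized KB schema in ", path)
  entries <- lapply(raw$diseases, function(d) {
    ann <- lapply(d$annotations, function(r) {
      if (is.null(r)) NULL else list(value = r$value, provenance = r$provenance)
    })
    list(codes = unlist(d$codes), name = d$name, annotations = ann)
  })
  knowledge_base(entries, ontology)
}
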