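#' Build a ranked prediction from per-disease scores
#'
#' Shared by every diagnostic method. Diseases are sorted by score
#' (descending when larger is better, ascending otherwise), ties share the
#' minimum rank (competition ranking), and the display order within a tie is
#' by primary disease code so output is deterministic.
#'
#' @param kb a `phb_kb`.
#' @param scores numeric vector, one score per KB disease (KB order).
#' @param method label stored on the result.
#' @param decreasing `TRUE` when a larger score means a better (earlier) rank.
#' @return An object of class `phb_ranking`: a data.frame with columns
#'   `disease` (primary code), `codes` (all codes, `|`-separated), `score`,
#'   `rank`; attributes `method` and `tie_policy = "min"`.
#' @export
ranked_prediction <- function(kb, scores, method = "unknown", decreasing = TRUE) {
  stopifnot(inherits(kb, "phb_kb"), length(scores) == length(kb$diseases))
  if (length(scores) == 0L) stop("cannot rank an empty knowledge base")
  primary <- kb_codes(kb)
  key <- if (decreasing) -scores else scores
  ord <- order(key, primary)
  sorted_key <- key[ord]
  # competition (min) ranks: position of the first equal score
  rk <- match(sorted_key, sorted_key)
  df <- data.frame(
    disease = primary[ord],
    codes = vapply(kb$diseases[ord], function(d) paste(d$codes, collapse = "|"), ""),
    score = scores[ord],
    rank = rk,
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, method = method, tie_policy = "min",
            class = c("phb_ranking", "data.frame"))
}

#' @export
print.phb_ranking <- function(x, n = 10L, ...) {
  cat("<phb_ranking> method=", attr(x, "method"), ", ",
      nrow(x), " diseases (showing ", min(n, nrow(x)), ")\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), n))
  invisible(x)
}

#' Rank of a disease within a ranked prediction
#'
#' Minimum rank over entries sharing any code with `codes`; `NA` when the
#' disease does not appear.
#'
#' @param ranking a `phb_ranking`.
#' @param codes character vector of disease codes.
#' @return Integer rank or `NA`.
#' @export
rank_of <- function(ranking, codes) {
  hit <- vapply(strsplit(ranking$codes, "|", fixed = TRUE),
                function(cs) any(cs %in% codes), TRUE)
  if (!any(hit)) return(NA_integer_)
  min(ranking$rank[hit])
}

#' Write ranked predictions as TSV
#'
#' Columns: case_id, rank, disease, codes, score, method.
#'
#' @param rankings named list (case_id -> `phb_ranking`) or one ranking.
#' @param path output TSV path.
#' @param case_id used when a single ranking is given.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(rankings, path, case_id = "case") {
  if (inherits(rankings, "phb_ranking")) {
    rankings <- stats::setNames(list(rankings), case_id)
  }
  rows <- lapply(names(rankings), function(cid) {
    r <- rankings[[cid]]
    data.frame(case_id = cid, rank = r$rank, disease = r$disease,
               codes = r$codes, score = r$score,
               method = attr(r, "method"), stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Patient case constructor
#'
#' @param query character vector of phenotype term CURIEs (non-empty).
#' @param true_codes character vector of true diagnosis codes (may be empty
#'   for inference-only use).
#' @param case_id identifier string.
#' @return A list of class `phb_case`.
#' @export
patient_case <- function(query, true_codes = character(0), case_id = "case") {
  query <- unique(as.character(query))
  if (length(query) < 1L) stop("a case needs at least one query term")
  structure(list(case_id = case_id, query = query,
                 true_codes = as.character(true_codes)),
            class = "phb_case")
}

#' Read / write cases as JSON lines
#'
#' One JSON object per line: `{"case_id": ..., "terms": [...],
#' "diagnosis": [...]}`.
#'
#' @param path file path.
#' @return list of `phb_case` (reader); `path` invisibly (writer).
#' @export
read_cases_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln)
    patient_case(obj$terms, obj$diagnosis %||% character(0), obj$case_id)
  })
}

#' @rdname read_cases_jsonl
#' @param cases list of `phb_case`.
#' @export
write_cases_jsonl <- function(cases, path) {
  lines <- vapply(cases, function(cs) {
    jsonlite::toJSON(list(case_id = cs$case_id, terms = cs$query,
                          diagnosis = cs$true_codes), auto_unbox = TRUE)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read cases from a two-column TSV
#'
#' Columns: case_id, term (one row per term); diagnoses unknown.
#'
#' @param path TSV path.
#' @return list of `phb_case`.
#' @export
read_cases_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected two tab-separated columns in ", path)
  ids <- unique(df[[1L]])
  lapply(ids, function(cid) {
    patient_case(df[[2L]][df[[1L]] == cid], character(0), case_id = cid)
  })
}
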