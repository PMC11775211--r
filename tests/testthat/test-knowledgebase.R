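hpoa_lines <- function(rows, path) {
  writeLines(c("#database_id\tdisease_name\tqualifier\thpo_id\tfrequency", rows),
             path)
  path
}

test_that("HPOA loader transcribes rows and rejects malformed term IDs", {
  f <- hpoa_lines(c(
    "OMIM:261600\tPhenylketonuria\t\tHP:0001250\t12/45",
    "OMIM:261600\tPhenylketonuria\t\tHP:0002960\t",
    "OMIM:300100\tOther\t\tHP:0000011\t30%",
    "OMIM:300100\tOther\t\tnot-a-term\t"
  ), tempfile())
  expect_message(df <- load_hpoa(f, source = "OMIM"), "1 row")
  expect_equal(nrow(df), 3L)
  expect_equal(df$term[[1L]], "HP:0001250")
  expect_equal(df$frequency[[1L]], "12/45")
  expect_true(is.na(df$frequency[[2L]]))
  expect_error(load_hpoa(tempfile()), "not found")
})

test_that("frequency parsing covers fractions, percentages and class midpoints", {
  expect_equal(parse_frequency("12/45")$value, 12 / 45)
  expect_equal(parse_frequency("12/45")$provenance, "fraction")
  expect_equal(parse_frequency("30%")$value, 0.30)
  expect_equal(parse_frequency("HP:0040281")$value, 0.895)  # very frequent 80-99%
  expect_equal(parse_frequency("obligate")$value, 1.0)
  expect_equal(parse_frequency("very rare")$value, 0.025)
  expect_equal(parse_frequency("0.4")$value, 0.4)
  expect_equal(parse_frequency("mystery")$provenance, "default")
  expect_true(is.na(parse_frequency("mystery")$value))
  expect_error(parse_frequency("3/0"), "denominator")
})

make_source <- function(code, terms, source, freqs = NULL, name = "dis") {
  data.frame(code = code, name = name, term = terms,
             frequency = if (is.null(freqs)) NA_character_ else freqs,
             source = source, stringsAsFactors = FALSE)
}

test_that("merging consolidates equivalence classes and unions annotations", {
  o <- sim_ontology(sim_config(n_terms = 40L, seed = 5))
  t_all <- setdiff(o$terms, o$root)
  ta <- t_all[1:24]
  tb <- c(t_all[1:5], t_all[25:39])   # 5 shared, 15 new -> union 39
  s1 <- make_source("OMIM:261600", ta, "OMIM")
  s2 <- make_source("ORPHA:716", tb, "Orphanet")
  kb <- merge_sources(list(s1, s2), o,
                      equivalence = list(c("OMIM:261600", "ORPHA:716")))
  expect_equal(length(kb$diseases), 1L)
  d <- kb$diseases[[1L]]
  expect_setequal(d$codes, c("OMIM:261600", "ORPHA:716"))
  expect_equal(length(d$annotations), 39L)
})

test_that("a three-source code class becomes one entry carrying all codes", {
  o <- sim_ontology(sim_config(n_terms = 20L, seed = 5))
  ts <- setdiff(o$terms, o$root)[1:4]
  srcs <- list(make_source("OMIM:261600", ts, "OMIM"),
               make_source("ORPHA:716", ts[1:3], "Orphanet"),
               make_source("CCRD:90", ts[2:4], "CCRD"))
  kb <- merge_sources(srcs, o,
                      equivalence = list(c("OMIM:261600", "ORPHA:716", "CCRD:90")))
  expect_equal(length(kb$diseases), 1L)
  expect_setequal(kb$diseases[[1L]]$codes, c("OMIM:261600", "ORPHA:716", "CCRD:90"))
})

test_that("identity merge, frequency priority, and excluded annotations", {
  o <- sim_ontology(sim_config(n_terms = 20L, seed = 5))
  ts <- setdiff(o$terms, o$root)[1:3]
  s1 <- make_source("OMIM:1", ts, "OMIM", freqs = c("30%", NA, "HP:0040285"))
  kb <- merge_sources(list(s1), o)
  expect_equal(length(kb$diseases), 1L)
  # excluded-class annotation dropped
  expect_equal(length(kb$diseases[[1L]]$annotations), 2L)
  expect_equal(kb$diseases[[1L]]$annotations[[ts[[1L]]]]$value, 0.30)

  # CCRD outranks OMIM on frequency conflicts
  s2 <- make_source("CCRD:7", ts[1L], "CCRD", freqs = "80%")
  s3 <- make_source("OMIM:1", ts[1L], "OMIM", freqs = "30%")
  kb2 <- merge_sources(list(s3, s2), o, equivalence = list(c("OMIM:1", "CCRD:7")))
  expect_equal(kb2$diseases[[1L]]$annotations[[ts[[1L]]]]$value, 0.80)
  expect_error(
    merge_sources(list(s1), o, equivalence = list(c("A:1", "B:2"), c("B:2"))),
    "overlapping")
})

test_that("merge annotation sets are insensitive to source order", {
  o <- sim_ontology(sim_config(n_terms = 30L, seed = 2))
  ts <- setdiff(o$terms, o$root)
  s1 <- make_source("OMIM:1", ts[1:6], "OMIM")
  s2 <- make_source("ORPHA:2", ts[4:9], "Orphanet")
  eq <- list(c("OMIM:1", "ORPHA:2"))
  k1 <- merge_sources(list(s1, s2), o, equivalence = eq)
  k2 <- merge_sources(list(s2, s1), o, equivalence = eq)
  expect_setequal(names(k1$diseases[[1L]]$annotations),
                  names(k2$diseases[[1L]]$annotations))
  n_ann <- length(k1$diseases[[1L]]$annotations)
  expect_gte(n_ann, 6L)           # >= max per-source
  expect_lte(n_ann, 12L)          # <= sum
})

test_that("restriction keeps matching entries and tolerates unknown codes", {
  w <- random_world(4, n_diseases = 10L)
  codes <- vapply(w$kb$diseases, function(d) d$codes[[1L]], "")
  r <- restrict_kb(w$kb, codes[1:3])
  expect_equal(length(r$diseases), 3L)
  expect_equal(length(restrict_kb(w$kb, codes)$diseases), 10L)
  expect_message(r2 <- restrict_kb(w$kb, c(codes[1:2], "NOPE:1")), "unknown")
  expect_equal(length(r2$diseases), 2L)
  expect_warning(restrict_kb(w$kb, "NOPE:1"), "empty")
})

test_that("knowledge base round-trips through canonical JSON", {
  w <- random_world(6)
  f <- tempfile(fileext = ".json")
  write_kb(w$kb, f)
  kb2 <- read_kb(f, w$o)
  expect_equal(length(kb2$diseases), length(w$kb$diseases))
  for (i in seq_along(w$kb$diseases)) {
    a <- w$kb$diseases[[i]]; b <- kb2$diseases[[i]]
    expect_equal(a$codes, b$codes)
    expect_setequal(names(a$annotations), names(b$annotations))
    for (t in names(a$annotations)) {
      va <- if (is.null(a$annotations[[t]])) NA_real_ else a$annotations[[t]]$value
      vb <- if (is.null(b$annotations[[t]])) NA_real_ else b$annotations[[t]]$value
      expect_equal(va, vb)
    }
  }
  # canonical serialization is byte-stable
  f2 <- tempfile(fileext = ".json")
  write_kb(kb2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("knowledge base round-trips through the HPOA writer", {
  w <- random_world(8)
  f <- tempfile(fileext = ".hpoa")
  write_hpoa(w$kb, f)
  kb2 <- merge_sources(list(load_hpoa(f, "sim")), w$o)
  expect_equal(length(kb2$diseases), length(w$kb$diseases))
  for (i in seq_along(w$kb$diseases)) {
    expect_setequal(names(kb2$diseases[[i]]$annotations),
                    names(w$kb$diseases[[i]]$annotations))
  }
})
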