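test_that("punctuation segmentation splits and round-trips", {
  expect_identical(segment_fields("a,b;c", c(",", ";")), c("a", "b", "c"))
  expect_identical(segment_fields("", c(",")), character(0))
  expect_identical(segment_fields(",,;", c(",", ";")), character(0))
  # property: concatenation of segments equals input stripped of delimiters
  set.seed(2)
  delims <- c(",", ";", ".")
  for (i in 1:50) {
    chars <- sample(c(letters[1:6], delims), 30, replace = TRUE)
    txt <- paste(chars, collapse = "")
    segs <- segment_fields(txt, delims)
    expect_identical(paste(segs, collapse = ""),
                     gsub("[,;.]", "", txt))
  }
})

test_that("field names follow the canonical examination order", {
  out <- assign_field_names(c("p", "t", "l", "i", "x"))
  expect_identical(names(out), c("pulse", "tongue", "listening_smelling",
                                 "inspection", "physical_exam"))
  expect_identical(out$pulse, "p")
  # extra segments fold into the final field
  out6 <- assign_field_names(c("p", "t", "l", "i", "x", "y"))
  expect_identical(out6$physical_exam, "x y")
})

test_that("chief-complaint extraction is longest-match with a threshold", {
  lex <- data.frame(surface = c("oral ulcer", "unfavorable urination",
                                "ulcer"),
                    entity_id = c("e_oral", "e_urine", "e_ulcer"),
                    stringsAsFactors = FALSE)
  res <- extract_chief_entities(
    "recurring oral ulcer and unfavorable urination for years", lex)
  expect_identical(res$entity_id, c("e_oral", "e_urine"))
  expect_true(all(res$confidence == 1))
  expect_true(all(diff(res$start) > 0))
  # a low-confidence scorer deletes every candidate at the 0.5 threshold
  res0 <- extract_chief_entities("oral ulcer", lex, threshold = 0.5,
                                 scorer = function(s, e) 0.4)
  expect_equal(nrow(res0), 0)
  # nested surfaces resolve to the longest match only
  lex2 <- data.frame(surface = c("A B", "A"), entity_id = c("ab", "a"),
                     stringsAsFactors = FALSE)
  res2 <- extract_chief_entities("A B", lex2)
  expect_identical(res2$entity_id, "ab")
  expect_error(extract_chief_entities("x", lex[0, ]), "non-empty")
})

test_that("extraction equals the exhaustive longest-match oracle", {
  set.seed(9)
  vocab <- c("t1", "t2", "t3", "t4", "t5")
  for (i in 1:40) {
    n_tok <- sample(5:30, 1)
    tokens <- sample(vocab, n_tok, replace = TRUE)
    surfaces <- unique(c(
      paste(sample(vocab, 2), collapse = " "),
      sample(vocab, 2),
      paste(sample(vocab, 3, replace = TRUE), collapse = " ")))
    lex <- data.frame(surface = surfaces,
                      entity_id = paste0("e", seq_along(surfaces)),
                      stringsAsFactors = FALSE)
    got <- extract_chief_entities(paste(tokens, collapse = " "), lex)
    want <- oracle_longest_match(tokens, surfaces)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_identical(got$surface, vapply(want, `[[`, character(1),
                                           "surface"))
      expect_identical(got$start, vapply(want, function(s)
        as.integer(s$start), integer(1)))
    }
  }
})

test_that("input sequences follow the CLS/UNK/SEP layout with linked spans", {
  w <- tiny_world(6)
  recs <- generate_records(w)
  kg <- build_kg(recs, world_lexicons(w))
  s <- build_input_sequence(recs[[1]], kg, max_length = 64)
  expect_identical(s$tokens[1], "[CLS]")
  expect_identical(s$tokens[length(s$tokens)], "[SEP]")
  # each content token run is followed by a [UNK] separator
  seps <- which(s$tokens == "[UNK]")
  expect_gt(length(seps), 0)
  # spans never cover CLS/UNK/SEP positions and never overlap
  special <- c(1L, seps, length(s$tokens))
  covered <- integer(0)
  for (k in seq_len(nrow(s$spans))) {
    rows <- s$spans$start[k]:(s$spans$start[k] + s$spans$length[k] - 1L)
    expect_length(intersect(rows, special), 0)
    expect_length(intersect(rows, covered), 0)
    covered <- c(covered, rows)
  }
  # chief spans are tagged as such
  expect_true(any(s$spans$segment == "chief"))
  expect_error(build_input_sequence(recs[[1]], kg, max_length = 3),
               "max_length")
})

test_that("unknown symptom surfaces carry the sentinel span id", {
  w <- tiny_world(7)
  recs <- generate_records(w)
  kg <- build_kg(recs, world_lexicons(w))
  rec <- recs[[1]]
  rec$symptom_fields$pulse <- paste(rec$symptom_fields$pulse, "mystery_tok")
  rec$entity_hints <- NULL
  s <- build_input_sequence(rec, kg, max_length = 64)
  sent <- s$spans[s$spans$entity_id == syndromeKG:::SENTINEL_ENTITY, ]
  expect_gte(nrow(sent), 1)
  expect_true("mystery_tok" %in% s$tokens[sent$start])
})

test_that("over-long sequences truncate to max_length with SEP last", {
  w <- tiny_world(2)
  recs <- generate_records(w)
  kg <- build_kg(recs, world_lexicons(w))
  rec <- recs[[1]]
  rec$symptom_fields$pulse <- paste(rep("filler_tok", 300), collapse = " ")
  s <- build_input_sequence(rec, kg, max_length = 256)
  expect_length(s$tokens, 256)
  expect_identical(s$tokens[256], "[SEP]")
  expect_true(all(s$spans$start + s$spans$length - 1 <= 255))
})

test_that("the per-field separator switch collapses symptom separators", {
  w <- tiny_world(2)
  recs <- generate_records(w)
  kg <- build_kg(recs, world_lexicons(w))
  s_per <- build_input_sequence(recs[[1]], kg, 64, per_field_sep = TRUE)
  s_block <- build_input_sequence(recs[[1]], kg, 64, per_field_sep = FALSE)
  expect_gt(sum(s_per$tokens == "[UNK]"), sum(s_block$tokens == "[UNK]"))
})

test_that("lexicon TSV files round-trip", {
  lex <- data.frame(surface = c("a b", "c"), entity_id = c("e1", "e2"),
                    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  write_lexicon(lex, f)
  expect_identical(read_lexicon(f), lex)
})
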