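# Parsing, segmentation, entity extraction and input-sequence assembly.
#
# Tokenization is character-level, matching the per-character treatment the
# text encoder expects. Synthetic records use space-separated symbolic tokens
# (one token = one "character"); contiguous text without spaces is split into
# individual characters.

CLS_TOKEN <- "[CLS]"
SEP_TOKEN <- "[SEP]"
UNK_TOKEN <- "[UNK]"
SENTINEL_ENTITY <- "<unlinked>"

#' Tokenize a text field
#'
#' Space-separated text is split on whitespace; unspaced text is split into
#' single characters. Both conventions yield the unit the encoder treats as a
#' "character".
#'
#' @param x A character scalar.
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize_text <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(trimws(x))) return(character(0))
  x <- trimws(x)
  if (grepl("[[:space:]]", x)) {
    unlist(lapply(strsplit(x, "[[:space:]]+")[[1]], tokenize_text),
           use.names = FALSE)
  } else if (grepl("^[A-Za-z0-9_<>@.-]+$", x)) {
    x  # symbolic/word token: one token = one "character"
  } else {
    strsplit(x, "")[[1]]
  }
}

#' Segment raw field text on punctuation delimiters
#'
#' Splits `raw_text` at any of the delimiter characters, drops empty
#' segments, and trims surrounding whitespace. The concatenation of the
#' returned segments equals the input with delimiters removed.
#'
#' @param raw_text Character scalar.
#' @param delimiters Character vector of single-character delimiters
#'   (default: the comma/semicolon/period family in ASCII and full-width
#'   form).
#' @return Character vector of non-empty segments.
#' @export
#' @examples
#' segment_fields("a,b;c", c(",", ";"))
segment_fields <- function(raw_text,
                           delimiters = c(",", ";", ".", "，", "；",
                                          "。")) {
  if (length(delimiters) == 0) stop("delimiter set must be non-empty")
  if (is.null(raw_text) || is.na(raw_text) || !nzchar(raw_text))
    return(character(0))
  pat <- paste0("[", paste(gsub("([][\\^-])", "\\\\\\1", delimiters),
                           collapse = ""), "]")
  parts <- strsplit(raw_text, pat)[[1]]
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

#' Assign canonical field names to segmented symptom text
#'
#' The symptom block of a record covers five examination modalities in a
#' fixed order: pulse, tongue, listening/smelling, inspection, physical
#' examination. Extra segments are appended to the last field.
#'
#' @param segments Character vector from [segment_fields()].
#' @return Named list of field texts in canonical order.
#' @export
assign_field_names <- function(segments) {
  out <- stats::setNames(as.list(rep("", length(SYMPTOM_FIELDS))),
                         SYMPTOM_FIELDS)
  for (i in seq_along(segments)) {
    f <- SYMPTOM_FIELDS[min(i, length(SYMPTOM_FIELDS))]
    out[[f]] <- trimws(paste(out[[f]], segments[i]))
  }
  out
}

as_lexicon <- function(lexicon) {
  if (is.data.frame(lexicon)) {
    stopifnot(all(c("surface", "entity_id") %in% names(lexicon)))
    return(lexicon[, c("surface", "entity_id")])
  }
  data.frame(surface = names(lexicon), entity_id = unname(unlist(lexicon)),
             stringsAsFactors = FALSE)
}

# Longest-match, left-to-right, non-overlapping matching of lexicon surfaces
# (token sequences) against a token vector. Returns start/length/surface.
match_surfaces <- function(tokens, surfaces) {
  if (length(tokens) == 0 || length(surfaces) == 0)
    return(data.frame(surface = character(0), start = integer(0),
                      length = integer(0), stringsAsFactors = FALSE))
  surf_tokens <- lapply(surfaces, tokenize_text)
  max_len <- max(lengths(surf_tokens))
  key <- vapply(surf_tokens, paste, character(1), collapse = "")
  out <- list()
  i <- 1L
  while (i <= length(tokens)) {
    hit_len <- 0L
    for (L in seq(min(max_len, length(tokens) - i + 1L), 1L)) {
      cand <- paste(tokens[i:(i + L - 1L)], collapse = "")
      if (cand %in% key) { hit_len <- L; break }
    }
    if (hit_len > 0L) {
      out[[length(out) + 1L]] <- data.frame(
        surface = surfaces[match(paste(tokens[i:(i + hit_len - 1L)],
                                       collapse = ""), key)],
        start = i, length = hit_len, stringsAsFactors = FALSE)
      i <- i + hit_len
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0)
    return(data.frame(surface = character(0), start = integer(0),
                      length = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Extract chief-complaint symptom entities by dictionary matching
#'
#' Longest-match, left-to-right, non-overlapping matching of lexicon surfaces
#' against the tokenized chief complaint. Each match receives a confidence
#' from `scorer` (1.0 for exact lexicon hits by default; a learned
#' extractor's probability can be plugged in), and matches below `threshold`
#' are deleted.
#'
#' @param chief Chief-complaint text.
#' @param lexicon Data frame (`surface`, `entity_id`) or named vector
#'   surface -> entity id.
#' @param threshold Minimum confidence to keep an entity (default 0.5).
#' @param scorer Function `(surface, entity_id) -> confidence in [0, 1]`.
#' @param hints Optional named list/vector surface -> entity id used to
#'   resolve ambiguous surfaces (several entities sharing one surface).
#'   Unhinted ambiguity resolves to the first lexicon entry.
#' @return Data frame of class `"extraction_result"` with columns `surface`,
#'   `entity_id`, `confidence`, `start`, `length`, in text order.
#' @export
extract_chief_entities <- function(chief, lexicon, threshold = 0.5,
                                   scorer = NULL, hints = NULL) {
  lex <- as_lexicon(lexicon)
  if (nrow(lex) == 0) stop("lexicon must be non-empty")
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  if (is.null(scorer)) scorer <- function(surface, entity_id) 1.0
  tokens <- tokenize_text(chief)
  m <- match_surfaces(tokens, unique(lex$surface))
  if (nrow(m)) {
    m$entity_id <- vapply(m$surface, function(s) {
      if (!is.null(hints) && s %in% names(hints))
        return(as.character(hints[[s]]))
      lex$entity_id[match(s, lex$surface)]
    }, character(1))
    m$confidence <- mapply(scorer, m$surface, m$entity_id)
    stopifnot(all(m$confidence >= 0 & m$confidence <= 1))
    m <- m[m$confidence >= threshold, , drop = FALSE]
  } else {
    m$entity_id <- character(0)
    m$confidence <- numeric(0)
  }
  m <- m[, c("surface", "entity_id", "confidence", "start", "length")]
  rownames(m) <- NULL
  class(m) <- c("extraction_result", class(m))
  m
}

#' Build the model input sequence for a record
#'
#' Assembles the character/token sequence the encoder consumes:
#' `[CLS] field1 [UNK] field2 [UNK] ... chief-entity [UNK] ... [SEP]`,
#' with each symptom field and each extracted chief-complaint entity followed
#' by a `[UNK]` separator (set `per_field_sep = FALSE` to separate only the
#' symptom block from the chief block). Maximal token runs matching a KG
#' entity surface are annotated as entity spans; unmatched content runs get
#' the sentinel id, which the fusion layer later fills with a seeded random
#' vector. Sequences longer than `max_length` are right-truncated before
#' `[SEP]`, dropping spans that no longer fit.
#'
#' @param record An `emr_record`.
#' @param kg A `kgraph` whose entity surfaces drive span linking (the
#'   `surface` attribute; defaults to entity ids).
#' @param max_length Maximum token count including `[CLS]`/`[SEP]`
#'   (default 256).
#' @param chief_lexicon Lexicon for chief-complaint extraction; defaults to
#'   the KG's chief-complaint entities.
#' @param threshold Confidence threshold passed to
#'   [extract_chief_entities()].
#' @param scorer Optional confidence scorer, as in
#'   [extract_chief_entities()].
#' @param per_field_sep Insert `[UNK]` after every symptom field (default)
#'   rather than once after the whole block.
#' @return A list of class `"input_sequence"`: `tokens`, `spans` (data frame
#'   `entity_id`, `start`, `length`), `max_length`.
#' @export
build_input_sequence <- function(record, kg, max_length = 256,
                                 chief_lexicon = NULL, threshold = 0.5,
                                 scorer = NULL, per_field_sep = TRUE) {
  if (max_length < 4)
    config_error(sprintf("max_length must be at least 4, got %d", max_length))
  surfaces <- kg_surfaces(kg)
  hints <- record$entity_hints
  if (is.null(chief_lexicon)) {
    chief_ids <- kg$entities$entity_id[kg$entities$category == "chief_complaint"]
    chief_lexicon <- data.frame(
      surface = unname(surfaces[chief_ids]) %||% chief_ids,
      entity_id = chief_ids, stringsAsFactors = FALSE)
  }

  tokens <- CLS_TOKEN
  content_runs <- list()  # list of (tokens, start)
  add_run <- function(tok_vec) {
    if (length(tok_vec) == 0) return()
    start <- length(tokens) + 1L
    tokens <<- c(tokens, tok_vec)
    content_runs[[length(content_runs) + 1L]] <<- list(tokens = tok_vec,
                                                       start = start)
  }
  fields <- record$symptom_fields
  fields <- fields[vapply(fields, function(f)
    !is.null(f) && nzchar(trimws(f)), logical(1))]
  for (i in seq_along(fields)) {
    add_run(tokenize_text(fields[[i]]))
    if (per_field_sep || i == length(fields)) tokens <- c(tokens, UNK_TOKEN)
  }
  if (length(fields) == 0) tokens <- c(tokens, UNK_TOKEN)
  chief <- extract_chief_entities(record$chief_complaint %||% "",
                                  chief_lexicon, threshold = threshold,
                                  scorer = scorer, hints = hints)
  chief_span_ids <- character(0)
  for (i in seq_len(nrow(chief))) {
    add_run(tokenize_text(chief$surface[i]))
    chief_span_ids <- c(chief_span_ids, chief$entity_id[i])
    tokens <- c(tokens, UNK_TOKEN)
  }
  tokens <- c(tokens, SEP_TOKEN)

  # span linking: within each content run, longest-match against KG surfaces;
  # unmatched maximal sub-runs carry the sentinel id
  surf_to_id <- stats::setNames(names(surfaces), unname(surfaces))
  spans <- list()
  n_sym_runs <- length(content_runs) - nrow(chief)
  for (ri in seq_along(content_runs)) {
    run <- content_runs[[ri]]
    if (ri > n_sym_runs) {
      # chief runs: entity identity already known from extraction
      spans[[length(spans) + 1L]] <- data.frame(
        entity_id = chief_span_ids[ri - n_sym_runs], start = run$start,
        length = length(run$tokens), segment = "chief",
        stringsAsFactors = FALSE)
      next
    }
    m <- match_surfaces(run$tokens, unname(surfaces))
    covered <- rep(FALSE, length(run$tokens))
    for (k in seq_len(nrow(m))) {
      sid <- m$surface[k]
      eid <- if (!is.null(hints) && sid %in% names(hints))
        as.character(hints[[sid]]) else unname(surf_to_id[sid])
      spans[[length(spans) + 1L]] <- data.frame(
        entity_id = eid, start = run$start + m$start[k] - 1L,
        length = m$length[k], segment = "symptom", stringsAsFactors = FALSE)
      covered[m$start[k]:(m$start[k] + m$length[k] - 1L)] <- TRUE
    }
    # maximal uncovered runs -> sentinel spans
    r <- rle(covered)
    pos <- cumsum(c(1L, r$lengths))
    for (k in seq_along(r$values)) {
      if (!r$values[k]) {
        spans[[length(spans) + 1L]] <- data.frame(
          entity_id = SENTINEL_ENTITY, start = run$start + pos[k] - 1L,
          length = r$lengths[k], segment = "symptom",
          stringsAsFactors = FALSE)
      }
    }
  }
  spans <- if (length(spans)) do.call(rbind, spans) else
    data.frame(entity_id = character(0), start = integer(0),
               length = integer(0), segment = character(0),
               stringsAsFactors = FALSE)
  spans <- spans[order(spans$start), , drop = FALSE]
  rownames(spans) <- NULL

  # truncation: keep [SEP] final, drop tokens from the right, drop spans that
  # no longer fit entirely
  if (length(tokens) > max_length) {
    keep <- max_length - 1L
    tokens <- c(tokens[seq_len(keep)], SEP_TOKEN)
    fits <- spans$start + spans$length - 1L <= keep
    spans <- spans[fits, , drop = FALSE]
  }
  seq <- list(tokens = tokens, spans = spans, max_length = max_length)
  class(seq) <- "input_sequence"
  seq
}

#' @export
print.input_sequence <- function(x, ...) {
  cat("Input sequence:", length(x$tokens), "tokens,", nrow(x$spans),
      "entity spans (max_length ", x$max_length, ")\n", sep = " ")
  invisible(x)
}

#' Read / write a surface-to-entity lexicon as two-column TSV
#' @param path TSV path (columns `surface`, `entity_id`, with header).
#' @return Data frame with columns `surface`, `entity_id`.
#' @export
read_lexicon <- function(path) {
  utils::read.delim(path, colClasses = "character")
}

#' @rdname read_lexicon
#' @param lexicon Data frame to write.
#' @export
write_lexicon <- function(lexicon, path) {
  utils::write.table(as_lexicon(lexicon), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
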