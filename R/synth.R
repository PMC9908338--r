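#' Configuration for the synthetic EMR world
#'
#' A synthetic "world" plants the latent structure the pipeline is supposed to
#' recover: a set of syndromes, each owning a fixed symptom set, a chief
#' complaint set, and nature/location label sets. Records are then sampled
#' from syndromes, so every downstream stage (graph construction, embedding,
#' classification) has a known ground truth.
#'
#' @param n_syndromes Number of latent syndromes.
#' @param n_symptom_vocab Size of the symptom entity vocabulary.
#' @param n_chief_vocab Size of the chief-complaint entity vocabulary.
#' @param n_nature_labels,n_location_labels Label-space sizes.
#' @param symptoms_per_syndrome Symptoms drawn (without replacement) per
#'   syndrome.
#' @param chiefs_per_syndrome Chief-complaint entities per syndrome.
#' @param natures_per_syndrome,locations_per_syndrome Labels per syndrome
#'   (each at least 1).
#' @param noise_rate Probability that a record swaps one symptom token for a
#'   uniformly random vocabulary symptom.
#' @param noise_chief If `TRUE`, noise may also perturb chief-complaint
#'   entities; off by default (symptom text is where transcription noise
#'   lives in practice).
#' @param n_records Number of records to emit.
#' @param syndrome_skew Dirichlet-like skew for syndrome sampling; 0 means
#'   uniform, larger values concentrate mass on earlier syndromes.
#' @param n_homographs Number of symptom entity pairs forced to share one
#'   surface token. Homographs make the correct label depend on entity
#'   identity that the surface text alone cannot reveal, which is what the
#'   entity-embedding fusion is for.
#' @param seed Integer seed; all generation is deterministic given it.
#' @return A validated list of class `"synth_config"`.
#' @export
synth_config <- function(n_syndromes = 5,
                         n_symptom_vocab = 20,
                         n_chief_vocab = 10,
                         n_nature_labels = 5,
                         n_location_labels = 3,
                         symptoms_per_syndrome = 4,
                         chiefs_per_syndrome = 2,
                         natures_per_syndrome = 2,
                         locations_per_syndrome = 1,
                         noise_rate = 0,
                         noise_chief = FALSE,
                         n_records = 100,
                         syndrome_skew = 0,
                         n_homographs = 0,
                         seed = 1L) {
  cfg <- list(
    n_syndromes = as.integer(n_syndromes),
    n_symptom_vocab = as.integer(n_symptom_vocab),
    n_chief_vocab = as.integer(n_chief_vocab),
    n_nature_labels = as.integer(n_nature_labels),
    n_location_labels = as.integer(n_location_labels),
    symptoms_per_syndrome = as.integer(symptoms_per_syndrome),
    chiefs_per_syndrome = as.integer(chiefs_per_syndrome),
    natures_per_syndrome = as.integer(natures_per_syndrome),
    locations_per_syndrome = as.integer(locations_per_syndrome),
    noise_rate = as.numeric(noise_rate),
    noise_chief = isTRUE(noise_chief),
    n_records = as.integer(n_records),
    syndrome_skew = as.numeric(syndrome_skew),
    n_homographs = as.integer(n_homographs),
    seed = as.integer(seed)
  )
  pos <- c("n_syndromes", "n_symptom_vocab", "n_chief_vocab",
           "n_nature_labels", "n_location_labels", "symptoms_per_syndrome",
           "chiefs_per_syndrome", "natures_per_syndrome",
           "locations_per_syndrome", "n_records")
  for (f in pos)
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      config_error(sprintf("%s must be a positive integer (got %s)", f, cfg[[f]]))
  if (cfg$noise_rate < 0 || cfg$noise_rate > 1)
    config_error("noise_rate must lie in [0, 1]")
  if (cfg$symptoms_per_syndrome > cfg$n_symptom_vocab)
    config_error(sprintf(
      "symptoms_per_syndrome (%d) exceeds n_symptom_vocab (%d)",
      cfg$symptoms_per_syndrome, cfg$n_symptom_vocab))
  if (cfg$chiefs_per_syndrome > cfg$n_chief_vocab)
    config_error(sprintf(
      "chiefs_per_syndrome (%d) exceeds n_chief_vocab (%d)",
      cfg$chiefs_per_syndrome, cfg$n_chief_vocab))
  if (cfg$natures_per_syndrome > cfg$n_nature_labels)
    config_error(sprintf(
      "natures_per_syndrome (%d) exceeds n_nature_labels (%d)",
      cfg$natures_per_syndrome, cfg$n_nature_labels))
  if (cfg$locations_per_syndrome > cfg$n_location_labels)
    config_error(sprintf(
      "locations_per_syndrome (%d) exceeds n_location_labels (%d)",
      cfg$locations_per_syndrome, cfg$n_location_labels))
  if (cfg$n_homographs > floor(cfg$n_symptom_vocab / 2))
    config_error("n_homographs cannot exceed half the symptom vocabulary")
  class(cfg) <- "synth_config"
  cfg
}

pad_ids <- function(prefix, n) sprintf("%s_%03d", prefix, seq_len(n))

#' Generate a synthetic world
#'
#' Draws the latent syndrome table: for each syndrome a symptom set (without
#' replacement), a chief-complaint set, and non-empty nature and location
#' label sets. Symbolic tokens (`sym_001`, `cc_001`, `nat_001`, `loc_001`)
#' stand in for clinical surface strings; all downstream matching is
#' token-level, so the pipeline is script-agnostic.
#'
#' Each entity's surface form equals its id except for homograph pairs, where
#' two symptom entities share one ambiguous surface (`amb_k`).
#'
#' @param config A [synth_config()].
#' @return A list of class `"emr_world"` with elements `syndromes` (per-id
#'   list of symptom/chief/nature/location id vectors), `vocab` (per-category
#'   id vectors), `surface` (named map entity id -> surface token), and
#'   `config`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  vocab <- list(
    symptom = pad_ids("sym", config$n_symptom_vocab),
    chief = pad_ids("cc", config$n_chief_vocab),
    nature = pad_ids("nat", config$n_nature_labels),
    location = pad_ids("loc", config$n_location_labels),
    syndrome = pad_ids("syn", config$n_syndromes)
  )
  surface <- c(vocab$symptom, vocab$chief, vocab$nature, vocab$location)
  names(surface) <- surface
  if (config$n_homographs > 0) {
    # pair up the first 2k symptom entities onto shared surfaces
    for (k in seq_len(config$n_homographs)) {
      amb <- sprintf("amb_%03d", k)
      surface[vocab$symptom[2 * k - 1]] <- amb
      surface[vocab$symptom[2 * k]] <- amb
    }
  }
  syndromes <- lapply(seq_len(config$n_syndromes), function(i) {
    list(
      symptoms = sample(vocab$symptom, config$symptoms_per_syndrome),
      chiefs = sample(vocab$chief, config$chiefs_per_syndrome),
      natures = sample(vocab$nature, config$natures_per_syndrome),
      locations = sample(vocab$location, config$locations_per_syndrome)
    )
  })
  names(syndromes) <- vocab$syndrome
  world <- list(syndromes = syndromes, vocab = vocab, surface = surface,
                config = config)
  class(world) <- "emr_world"
  world
}

#' @export
print.emr_world <- function(x, ...) {
  cat("Synthetic EMR world:", length(x$syndromes), "syndromes,",
      length(x$vocab$symptom), "symptoms,",
      length(x$vocab$nature), "natures,",
      length(x$vocab$location), "locations\n")
  invisible(x)
}

# The five symptom text fields, in the conventional examination order.
SYMPTOM_FIELDS <- c("pulse", "tongue", "listening_smelling", "inspection",
                    "physical_exam")

syndrome_string <- function(world, syn_id) {
  s <- world$syndromes[[syn_id]]
  paste(c(sort(s$natures), sort(s$locations)), collapse = " ")
}

#' Sample EMR records from a world
#'
#' Each record picks a syndrome (uniformly, or with skew), writes its symptom
#' surfaces into the five symptom text fields (round-robin), its chief
#' entities (interleaved with filler tokens) into the chief complaint, and
#' attaches the syndrome's nature/location ids as gold labels. With
#' probability `noise_rate` one symptom token is replaced by a uniformly
#' random vocabulary symptom; gold labels are never perturbed.
#'
#' @param world An `emr_world`.
#' @param config The same [synth_config()] used to generate it.
#' @return A list of `emr_record` lists: `record_id`, `symptom_fields`
#'   (named list of field text), `chief_complaint`, `syndrome` (decomposable
#'   label string), `gold_natures`, `gold_locations`, `syndrome_id`, and
#'   `entity_hints` (gold surface -> entity linking, needed only when
#'   homographs make surface matching ambiguous).
#' @export
generate_records <- function(world, config = world$config) {
  stopifnot(inherits(world, "emr_world"), inherits(config, "synth_config"))
  set.seed(derive_seed(config$seed, "records"))
  n_syn <- length(world$syndromes)
  probs <- if (config$syndrome_skew > 0) {
    w <- exp(-config$syndrome_skew * (seq_len(n_syn) - 1))
    w / sum(w)
  } else rep(1 / n_syn, n_syn)
  filler <- sprintf("txt_%02d", 1:8)
  records <- vector("list", config$n_records)
  for (i in seq_len(config$n_records)) {
    syn_id <- sample(names(world$syndromes), 1, prob = probs)
    syn <- world$syndromes[[syn_id]]
    sym_entities <- syn$symptoms
    sym_surf <- unname(world$surface[sym_entities])
    if (config$noise_rate > 0 && stats::runif(1) < config$noise_rate) {
      j <- sample(length(sym_surf), 1)
      repl <- sample(world$vocab$symptom, 1)
      sym_entities[j] <- repl
      sym_surf[j] <- unname(world$surface[repl])
    }
    # distribute symptom tokens over the five fields round-robin
    fields <- stats::setNames(vector("list", length(SYMPTOM_FIELDS)),
                              SYMPTOM_FIELDS)
    for (j in seq_along(sym_surf)) {
      f <- SYMPTOM_FIELDS[((j - 1) %% length(SYMPTOM_FIELDS)) + 1]
      fields[[f]] <- c(fields[[f]], sym_surf[j])
    }
    fields <- lapply(fields, function(v) paste(v, collapse = " "))
    chief_entities <- syn$chiefs
    if (config$noise_chief && config$noise_rate > 0 &&
        stats::runif(1) < config$noise_rate) {
      j <- sample(length(chief_entities), 1)
      chief_entities[j] <- sample(world$vocab$chief, 1)
    }
    chief_surf <- unname(world$surface[chief_entities])
    chief <- paste(
      c(sample(filler, 1), chief_surf[1],
        if (length(chief_surf) > 1)
          as.vector(rbind(sample(filler, length(chief_surf) - 1, replace = TRUE),
                          chief_surf[-1]))),
      collapse = " ")
    hints <- stats::setNames(sym_entities, unname(world$surface[sym_entities]))
    rec <- list(
      record_id = sprintf("rec_%05d", i),
      symptom_fields = fields,
      chief_complaint = chief,
      syndrome = syndrome_string(world, syn_id),
      gold_natures = sort(syn$natures),
      gold_locations = sort(syn$locations),
      syndrome_id = syn_id,
      entity_hints = as.list(hints)
    )
    class(rec) <- "emr_record"
    records[[i]] <- rec
  }
  records
}

#' Split records into train and test sets under the label-coverage rule
#'
#' Splits at random, then (by default) enforces the rule that every gold
#' label occurring in the test set must also occur in the training set:
#' offending test records are moved back into training and reported.
#'
#' @param records List of `emr_record`s.
#' @param train_frac Fraction assigned to training before filtering.
#' @param enforce_label_rule Apply the coverage rule (default `TRUE`).
#' @param seed Integer seed for the shuffle.
#' @return List with `train`, `test`, and `rejected` (record ids moved out of
#'   the test set by the rule).
#' @export
split_records <- function(records, train_frac = 0.8,
                          enforce_label_rule = TRUE, seed = 1L) {
  stopifnot(length(records) >= 2, train_frac > 0, train_frac < 1)
  set.seed(derive_seed(seed, "split"))
  n <- length(records)
  idx <- sample.int(n)
  n_train <- max(1L, floor(train_frac * n))
  train_idx <- idx[seq_len(n_train)]
  test_idx <- idx[-seq_len(n_train)]
  rejected <- character(0)
  if (enforce_label_rule) {
    train_labels <- unique(unlist(lapply(records[train_idx], function(r)
      c(r$gold_natures, r$gold_locations))))
    keep <- vapply(test_idx, function(i) {
      all(c(records[[i]]$gold_natures, records[[i]]$gold_locations) %in%
            train_labels)
    }, logical(1))
    rejected <- vapply(records[test_idx[!keep]], `[[`, character(1),
                       "record_id")
    if (length(rejected))
      log_msg("split: moved %d record(s) with uncovered labels into training",
              length(rejected))
    train_idx <- c(train_idx, test_idx[!keep])
    test_idx <- test_idx[keep]
  }
  list(train = records[sort(train_idx)], test = records[sort(test_idx)],
       rejected = rejected)
}

#' Write records as line-delimited JSON
#'
#' One JSON object per line with named fields; the on-disk form round-trips
#' byte-identically through [read_records()] + [write_records()].
#'
#' @param records List of `emr_record`s.
#' @param path Output file path.
#' @export
write_records <- function(records, path) {
  lines <- vapply(records, function(r) {
    r <- unclass(r)
    jsonlite::toJSON(r, auto_unbox = TRUE, null = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read line-delimited JSON records
#' @param path File written by [write_records()].
#' @return List of `emr_record`s.
#' @export
read_records <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    r <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    r$symptom_fields <- as.list(r$symptom_fields)
    r$entity_hints <- as.list(r$entity_hints)
    r$gold_natures <- as.character(r$gold_natures)
    r$gold_locations <- as.character(r$gold_locations)
    class(r) <- "emr_record"
    r
  })
}

#' Write a world sidecar for oracle checks
#' @param world An `emr_world`.
#' @param path Output JSON path.
#' @export
write_world <- function(world, path) {
  obj <- list(syndromes = world$syndromes, vocab = world$vocab,
              surface = as.list(world$surface),
              config = unclass(world$config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a world sidecar
#' @param path JSON path written by [write_world()].
#' @return An `emr_world`.
#' @export
read_world <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  world <- list(
    syndromes = lapply(obj$syndromes, function(s) lapply(s, as.character)),
    vocab = lapply(obj$vocab, as.character),
    surface = unlist(obj$surface),
    config = do.call(synth_config, obj$config)
  )
  class(world) <- "emr_world"
  world
}

#' Lexicons implied by a synthetic world
#'
#' Builds the surface -> entity-id lexicons that the extraction and graph
#' construction stages need: symptom, chief-complaint, nature, and location.
#'
#' @param world An `emr_world`.
#' @return Named list of data frames with columns `surface`, `entity_id`.
#' @export
world_lexicons <- function(world) {
  sym <- data.frame(surface = unname(world$surface[world$vocab$symptom]),
                    entity_id = world$vocab$symptom, stringsAsFactors = FALSE)
  chief <- data.frame(surface = unname(world$surface[world$vocab$chief]),
                      entity_id = world$vocab$chief, stringsAsFactors = FALSE)
  nat <- data.frame(surface = world$vocab$nature,
                    entity_id = world$vocab$nature, stringsAsFactors = FALSE)
  loc <- data.frame(surface = world$vocab$location,
                    entity_id = world$vocab$location, stringsAsFactors = FALSE)
  list(symptom = sym, chief = chief, nature = nat, location = loc)
}

#' World where labels hinge on entity identity hidden from the surface text
#'
#' Builds pairs of syndromes that share every surface token: within a pair,
#' the two syndromes differ only in which homograph entity (two symptom
#' entities sharing one ambiguous surface) they carry, yet they own distinct
#' nature labels. A classifier that sees only surface characters cannot
#' separate the pair; one that fuses the linked entity's KG embedding can.
#' Used to probe the value of entity fusion.
#'
#' @param n_pairs Number of ambiguous syndrome pairs.
#' @param shared_per_syndrome Unambiguous symptoms shared by both syndromes
#'   of a pair.
#' @param n_records Records to plan for in the attached config.
#' @param seed Integer seed.
#' @return An `emr_world` whose config can be fed to [generate_records()].
#' @export
ambiguous_world <- function(n_pairs = 2, shared_per_syndrome = 2,
                            n_records = 120, seed = 1L) {
  stopifnot(n_pairs >= 1, shared_per_syndrome >= 1)
  n_syn <- 2L * n_pairs
  n_amb <- 2L * n_pairs
  n_shared <- n_pairs * shared_per_syndrome
  cfg <- synth_config(
    n_syndromes = n_syn,
    n_symptom_vocab = n_amb + n_shared,
    n_chief_vocab = n_pairs,
    n_nature_labels = n_syn,
    n_location_labels = n_pairs,
    symptoms_per_syndrome = 1L + shared_per_syndrome,
    chiefs_per_syndrome = 1L,
    natures_per_syndrome = 1L,
    locations_per_syndrome = 1L,
    noise_rate = 0,
    n_records = n_records,
    n_homographs = n_pairs,
    seed = seed
  )
  vocab <- list(
    symptom = pad_ids("sym", cfg$n_symptom_vocab),
    chief = pad_ids("cc", cfg$n_chief_vocab),
    nature = pad_ids("nat", cfg$n_nature_labels),
    location = pad_ids("loc", cfg$n_location_labels),
    syndrome = pad_ids("syn", n_syn)
  )
  surface <- c(vocab$symptom, vocab$chief, vocab$nature, vocab$location)
  names(surface) <- surface
  syndromes <- list()
  for (p in seq_len(n_pairs)) {
    amb <- sprintf("amb_%03d", p)
    e1 <- vocab$symptom[2 * p - 1]
    e2 <- vocab$symptom[2 * p]
    surface[e1] <- amb
    surface[e2] <- amb
    shared <- vocab$symptom[n_amb + ((p - 1) * shared_per_syndrome +
                                       seq_len(shared_per_syndrome))]
    chief <- vocab$chief[p]
    loc <- vocab$location[p]
    syndromes[[vocab$syndrome[2 * p - 1]]] <- list(
      symptoms = c(e1, shared), chiefs = chief,
      natures = vocab$nature[2 * p - 1], locations = loc)
    syndromes[[vocab$syndrome[2 * p]]] <- list(
      symptoms = c(e2, shared), chiefs = chief,
      natures = vocab$nature[2 * p], locations = loc)
  }
  world <- list(syndromes = syndromes, vocab = vocab, surface = surface,
                config = cfg)
  class(world) <- "emr_world"
  world
}
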