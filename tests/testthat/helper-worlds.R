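# Shared fixture builders (all generated in code, no data files).

tiny_world <- function(seed = 1L, ...) {
  cfg <- synth_config(n_syndromes = 3, n_symptom_vocab = 12,
                      symptoms_per_syndrome = 3, n_chief_vocab = 6,
                      chiefs_per_syndrome = 2, n_nature_labels = 4,
                      n_location_labels = 2, natures_per_syndrome = 2,
                      locations_per_syndrome = 1, n_records = 40,
                      seed = seed, ...)
  generate_world(cfg)
}

tiny_kg <- function(seed = 1L) {
  w <- tiny_world(seed)
  recs <- generate_records(w)
  build_kg(recs, world_lexicons(w))
}

# hand-written 5-entity graph whose embeddings can be made exact translations
toy_exact_kg <- function() {
  entities <- data.frame(
    entity_id = c("A", "B", "S", "N", "L"),
    category = c("symptom", "symptom", "syndrome", "nature", "location"),
    stringsAsFactors = FALSE)
  triples <- data.frame(
    head = c("A", "S", "S"),
    relation = c("symptom_syndrome", "syndrome_nature", "syndrome_location"),
    tail = c("S", "N", "L"),
    stringsAsFactors = FALSE)
  kgraph(entities, triples)
}

# embedding set in which every true triple is an exact translation and the
# decoy entity B sits far away
toy_exact_embeddings <- function(d = 4) {
  r_ss <- c(1, 0, rep(0, d - 2))
  r_sn <- c(0, 1, rep(0, d - 2))
  r_sl <- c(0.5, 0.5, rep(0, d - 2))
  A <- c(0.2, -0.3, rep(0, d - 2))
  S <- A + r_ss
  N <- S + r_sn
  L <- S + r_sl
  B <- c(9, 9, rep(9, d - 2))
  E <- rbind(A = A, B = B, S = S, N = N, L = L)
  R <- rbind(chief_complaint_syndrome = c(-1, 1, rep(0, d - 2)),
             symptom_syndrome = r_ss, syndrome_nature = r_sn,
             syndrome_location = r_sl)
  emb <- list(E = E, R = R, scorer = "transe_l2",
              config = kge_config(dim = d), loss_trace = numeric(0))
  class(emb) <- "embedding_set"
  emb
}

random_embeddings <- function(kg, d = 6, scorer = "transe_l2", seed = 1L) {
  set.seed(seed)
  E <- matrix(rnorm(nrow(kg$entities) * d), ncol = d,
              dimnames = list(kg$entities$entity_id, NULL))
  R <- matrix(rnorm(4 * d), ncol = d, dimnames = list(KG_RELATIONS, NULL))
  emb <- list(E = E, R = R, scorer = scorer, config = kge_config(dim = d),
              loss_trace = numeric(0))
  class(emb) <- "embedding_set"
  emb
}

truth_matrix <- function(records, label_space) {
  m <- t(vapply(records, function(r)
    as.numeric(label_space %in% c(r$gold_natures, r$gold_locations)),
    numeric(length(label_space))))
  colnames(m) <- label_space
  m
}
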