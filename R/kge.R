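# Knowledge-graph embedding: translational (TransE, L1/L2) and bilinear
# (DistMult, ComplEx) scorers, margin-ranking training with typed negative
# sampling, link-prediction evaluation, and the KG-only label baseline.

KGE_SCORERS <- c("transe_l1", "transe_l2", "distmult", "complex")

#' Training configuration for knowledge-graph embeddings
#'
#' Defaults follow the translational-embedding literature: dimension 100,
#' margin 1.0, L2 norm, one negative per positive, unit-norm entity vectors.
#'
#' @param dim Embedding dimension (even for the `complex` scorer).
#' @param scorer One of `"transe_l1"`, `"transe_l2"`, `"distmult"`,
#'   `"complex"`.
#' @param margin Margin of the ranking loss.
#' @param negatives Negatives sampled per positive triple.
#' @param epochs,batch_size,lr Optimization schedule (plain SGD).
#' @param seed Integer seed; training is deterministic given it.
#' @return List of class `"kge_config"`.
#' @export
kge_config <- function(dim = 100, scorer = "transe_l2", margin = 1,
                       negatives = 1, epochs = 200, batch_size = 64,
                       lr = 0.05, seed = 1L) {
  scorer <- match.arg(scorer, KGE_SCORERS)
  cfg <- list(dim = as.integer(dim), scorer = scorer,
              margin = as.numeric(margin), negatives = as.integer(negatives),
              epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              lr = as.numeric(lr), seed = as.integer(seed))
  if (cfg$dim < 1 || cfg$margin < 0 || cfg$negatives < 1 || cfg$epochs < 1 ||
      cfg$batch_size < 1 || cfg$lr <= 0)
    config_error("kge_config: dim/negatives/epochs/batch_size must be >= 1, margin >= 0, lr > 0")
  if (scorer == "complex" && cfg$dim %% 2 != 0)
    config_error("complex scorer needs an even dimension (real/imaginary halves)")
  class(cfg) <- "kge_config"
  cfg
}

#' Score a single triple under a given scorer
#'
#' Translational scorers return the negated distance `-||h + r - t||` (L1 or
#' L2), so a perfect translation scores 0, the maximum, and all imperfect
#' triples score below 0. DistMult returns the trilinear product
#' `sum(h * r * t)`; ComplEx the real part of the Hermitian trilinear product
#' with vectors split into real (first half) and imaginary (second half)
#' components. Higher is always more plausible.
#'
#' @param h,r,t Numeric vectors of equal dimension.
#' @param scorer Scorer tag.
#' @return Scalar plausibility score.
#' @export
#' @examples
#' score_triple(c(1, 0), c(0, 1), c(1, 1), "transe_l2")  # exact translation: 0
score_triple <- function(h, r, t, scorer = "transe_l2") {
  scorer <- match.arg(scorer, KGE_SCORERS)
  if (length(h) != length(r) || length(h) != length(t))
    stop(sprintf("dimension mismatch: |h|=%d |r|=%d |t|=%d",
                 length(h), length(r), length(t)))
  switch(scorer,
    transe_l1 = -sum(abs(h + r - t)),
    transe_l2 = -sqrt(sum((h + r - t)^2)),
    distmult = sum(h * r * t),
    complex = {
      m <- length(h) / 2
      re <- seq_len(m); im <- m + seq_len(m)
      sum(r[re] * (h[re] * t[re] + h[im] * t[im]) +
            r[im] * (h[re] * t[im] - h[im] * t[re]))
    })
}

# Batch scorer over row-matrices H, R, T (n x d).
score_rows <- function(H, R, T, scorer) {
  switch(scorer,
    transe_l1 = -rowSums(abs(H + R - T)),
    transe_l2 = -sqrt(rowSums((H + R - T)^2)),
    distmult = rowSums(H * R * T),
    complex = {
      m <- ncol(H) / 2
      re <- seq_len(m); im <- m + seq_len(m)
      rowSums(R[, re, drop = FALSE] *
                (H[, re, drop = FALSE] * T[, re, drop = FALSE] +
                 H[, im, drop = FALSE] * T[, im, drop = FALSE]) +
              R[, im, drop = FALSE] *
                (H[, re, drop = FALSE] * T[, im, drop = FALSE] -
                 H[, im, drop = FALSE] * T[, re, drop = FALSE]))
    })
}

triple_keys <- function(h, r, t) paste(h, r, t, sep = "\r")

#' Sample one corrupted (negative) triple
#'
#' Corrupts the head or the tail (fair coin) by a uniformly drawn entity of
#' the same category, resampling until the corrupted triple is absent from
#' the graph. Typed corruption respects the relation schema, so a corrupted
#' syndrome-nature tail is always a nature entity.
#'
#' @param triple One-row data frame or list with `head`, `relation`, `tail`.
#' @param kg A `kgraph`.
#' @param max_tries Bounded retries before giving up (all candidates true).
#' @return A list with `head`, `relation`, `tail`, `corrupted`
#'   (`"head"`/`"tail"`).
#' @export
negative_sample <- function(triple, kg, max_tries = 200) {
  truth <- triple_keys(kg$triples$head, kg$triples$relation, kg$triples$tail)
  sch <- REL_SCHEMA[[triple$relation]]
  feasible <- c("head", "tail")[vapply(c("head", "tail"), function(s)
    length(entities_of_category(kg, sch[[s]])) >= 2, logical(1))]
  if (length(feasible) == 0)
    stop(sprintf("cannot corrupt triple: fewer than 2 entities in both %s and %s",
                 sch[["head"]], sch[["tail"]]))
  for (i in seq_len(max_tries)) {
    slot <- if (length(feasible) == 1) feasible else
      feasible[1 + (stats::runif(1) >= 0.5)]
    pool <- entities_of_category(kg, sch[[slot]])
    cand <- triple
    cand[[slot]] <- sample(pool, 1)
    if (cand[[slot]] != triple[[slot]] &&
        !(triple_keys(cand$head, cand$relation, cand$tail) %in% truth))
      return(list(head = cand$head, relation = cand$relation,
                  tail = cand$tail, corrupted = slot))
  }
  stop("negative_sample: no corrupting entity found within retry budget ",
       "(all candidates are true triples)")
}

init_embeddings <- function(n, d) {
  b <- 6 / sqrt(d)
  matrix(stats::runif(n * d, -b, b), nrow = n, ncol = d)
}

unit_rows <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  nrm[nrm == 0] <- 1
  M / nrm
}

# Analytic gradients of the score wrt H, R, T rows (n x d matrices).
score_grad_rows <- function(H, R, T, scorer) {
  switch(scorer,
    transe_l1 = {
      diff <- H + R - T
      u <- sign(diff)               # d(-|x|)/dx = -sign(x); score = -||.||_1
      list(H = -u, R = -u, T = u)
    },
    transe_l2 = {
      diff <- H + R - T
      nrm <- sqrt(rowSums(diff^2))
      nrm[nrm == 0] <- 1
      u <- diff / nrm
      list(H = -u, R = -u, T = u)
    },
    distmult = list(H = R * T, R = H * T, T = H * R),
    complex = {
      m <- ncol(H) / 2
      re <- seq_len(m); im <- m + seq_len(m)
      Hre <- H[, re, drop = FALSE]; Him <- H[, im, drop = FALSE]
      Rre <- R[, re, drop = FALSE]; Rim <- R[, im, drop = FALSE]
      Tre <- T[, re, drop = FALSE]; Tim <- T[, im, drop = FALSE]
      gH <- cbind(Rre * Tre + Rim * Tim, Rre * Tim - Rim * Tre)
      gR <- cbind(Hre * Tre + Him * Tim, Hre * Tim - Him * Tre)
      gT <- cbind(Rre * Hre - Rim * Him, Rre * Him + Rim * Hre)
      list(H = gH, R = gR, T = gT)
    })
}

#' Train knowledge-graph embeddings by margin ranking
#'
#' Minimizes `max(0, margin - score(pos) + score(neg))` with plain SGD over
#' minibatches, one (or more) typed negatives per positive. Entity vectors
#' are renormalized to unit L2 norm at the start of every epoch. Training is
#' deterministic for a fixed seed.
#'
#' @param kg A non-empty `kgraph`.
#' @param config A [kge_config()].
#' @param triples Optional triple subset to train on (defaults to all of
#'   `kg$triples`); negatives are still rejected against the full graph.
#' @return List of class `"embedding_set"`: `E` (entities x dim, rownames =
#'   entity ids), `R` (relations x dim), `scorer`, `config`, and a per-epoch
#'   `loss_trace`.
#' @export
train_kge <- function(kg, config = kge_config(), triples = NULL) {
  stopifnot(inherits(kg, "kgraph"), inherits(config, "kge_config"))
  if (nrow(kg$triples) == 0) stop("cannot train on an empty knowledge graph")
  set.seed(config$seed)
  trip <- triples %||% kg$triples
  ents <- kg$entities$entity_id
  d <- config$dim
  E <- init_embeddings(length(ents), d)
  rownames(E) <- ents
  R <- unit_rows(init_embeddings(length(KG_RELATIONS), d))
  rownames(R) <- KG_RELATIONS

  hi <- match(trip$head, ents)
  ti <- match(trip$tail, ents)
  ri <- match(trip$relation, KG_RELATIONS)
  truth <- triple_keys(kg$triples$head, kg$triples$relation, kg$triples$tail)

  cat_idx <- lapply(KG_CATEGORIES, function(cat)
    which(kg$entities$category == cat))
  names(cat_idx) <- KG_CATEGORIES
  head_cat <- vapply(trip$relation, function(r) REL_SCHEMA[[r]][["head"]],
                     character(1))
  tail_cat <- vapply(trip$relation, function(r) REL_SCHEMA[[r]][["tail"]],
                     character(1))
  translational <- config$scorer %in% c("transe_l1", "transe_l2")

  n <- nrow(trip)
  loss_trace <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    if (translational) E <- unit_rows(E)
    perm <- sample.int(n)
    epoch_loss <- 0
    for (b_start in seq(1, n, by = config$batch_size)) {
      idx <- perm[b_start:min(b_start + config$batch_size - 1L, n)]
      idx <- rep(idx, config$negatives)
      bh <- hi[idx]; bt <- ti[idx]; br <- ri[idx]
      # typed corruption: head or tail, same category, reject true triples;
      # slots whose category pool cannot yield a distinct entity are avoided
      slot_head <- stats::runif(length(idx)) < 0.5
      pool_n <- vapply(cat_idx, length, integer(1))
      slot_head[pool_n[head_cat[idx]] < 2] <- FALSE
      slot_head[pool_n[tail_cat[idx]] < 2] <- TRUE
      nh <- bh; nt <- bt
      draw <- function(cats) vapply(cats, function(cat) {
        pool <- cat_idx[[cat]]
        pool[sample.int(length(pool), 1)]
      }, integer(1))
      nh[slot_head] <- draw(head_cat[idx][slot_head])
      nt[!slot_head] <- draw(tail_cat[idx][!slot_head])
      for (tries in 1:50) {
        bad <- triple_keys(ents[nh], KG_RELATIONS[br], ents[nt]) %in% truth
        if (!any(bad)) break
        redo_head <- slot_head & bad
        redo_tail <- !slot_head & bad
        if (any(redo_head)) nh[redo_head] <- draw(head_cat[idx][redo_head])
        if (any(redo_tail)) nt[redo_tail] <- draw(tail_cat[idx][redo_tail])
      }
      keep <- !(triple_keys(ents[nh], KG_RELATIONS[br], ents[nt]) %in% truth)
      if (!any(keep)) next
      bh <- bh[keep]; bt <- bt[keep]; br <- br[keep]
      nh <- nh[keep]; nt <- nt[keep]

      Hp <- E[bh, , drop = FALSE]; Tp <- E[bt, , drop = FALSE]
      Rm <- R[br, , drop = FALSE]
      Hn <- E[nh, , drop = FALSE]; Tn <- E[nt, , drop = FALSE]
      sp <- score_rows(Hp, Rm, Tp, config$scorer)
      sn <- score_rows(Hn, Rm, Tn, config$scorer)
      viol <- config$margin - sp + sn
      active <- viol > 0
      epoch_loss <- epoch_loss + sum(pmax(viol, 0))
      if (!any(active)) next
      gp <- score_grad_rows(Hp[active, , drop = FALSE],
                            Rm[active, , drop = FALSE],
                            Tp[active, , drop = FALSE], config$scorer)
      gn <- score_grad_rows(Hn[active, , drop = FALSE],
                            Rm[active, , drop = FALSE],
                            Tn[active, , drop = FALSE], config$scorer)
      # dL/d(pos score) = -1, dL/d(neg score) = +1 on active pairs
      upd <- function(M, rows, G) {
        agg <- rowsum(G, group = rows)
        r <- as.integer(rownames(agg))
        M[r, ] <- M[r, ] - config$lr * agg
        M
      }
      E <- upd(E, bh[active], -gp$H)
      E <- upd(E, bt[active], -gp$T)
      E <- upd(E, nh[active], gn$H)
      E <- upd(E, nt[active], gn$T)
      R <- upd(R, br[active], gn$R - gp$R)
    }
    loss_trace[epoch] <- epoch_loss / n
  }
  if (translational) E <- unit_rows(E)
  emb <- list(E = E, R = R, scorer = config$scorer, config = config,
              loss_trace = loss_trace)
  class(emb) <- "embedding_set"
  emb
}

#' @export
print.embedding_set <- function(x, ...) {
  cat("Embedding set:", nrow(x$E), "entities,", nrow(x$R), "relations, dim",
      ncol(x$E), "scorer", x$scorer, "\n")
  invisible(x)
}

emb_vec <- function(emb, id, what = "entity") {
  M <- if (what == "entity") emb$E else emb$R
  if (!id %in% rownames(M))
    stop(sprintf("%s '%s' has no embedding", what, id))
  M[id, ]
}

#' Rank the true entity among candidates for a link-prediction query
#'
#' For a query `(h, r, ?)` or `(?, r, t)`, scores every candidate entity in
#' the open slot and returns the rank of the true completion. Ties share a
#' mid-rank (1 + number strictly better + half the number of equal-scoring
#' others), making the metric stable under candidate permutation. In
#' `filtered` mode, candidates completing *other* known-true triples are
#' removed before ranking.
#'
#' @param h,r,t The true triple's components.
#' @param slot Which slot is open: `"head"` or `"tail"`.
#' @param emb An `embedding_set`.
#' @param kg The `kgraph` (for candidate categories and filtering).
#' @param mode `"filtered"` (default) or `"raw"`.
#' @param restrict_category Rank only entities of the open slot's schema
#'   category (default); `FALSE` ranks all entities.
#' @param candidates Optional explicit candidate id vector (must contain the
#'   truth).
#' @return The (possibly half-integer) rank of the true entity.
#' @export
rank_entity <- function(h, r, t, slot = c("tail", "head"), emb, kg,
                        mode = c("filtered", "raw"),
                        restrict_category = TRUE, candidates = NULL) {
  slot <- match.arg(slot)
  mode <- match.arg(mode)
  truth_id <- if (slot == "tail") t else h
  if (is.null(candidates)) {
    candidates <- if (restrict_category)
      entities_of_category(kg, REL_SCHEMA[[r]][[slot]])
    else kg$entities$entity_id
  }
  if (!truth_id %in% candidates)
    stop(sprintf("true entity '%s' is not among the candidates", truth_id))
  if (mode == "filtered") {
    other <- if (slot == "tail") {
      kg$triples$tail[kg$triples$head == h & kg$triples$relation == r]
    } else {
      kg$triples$head[kg$triples$tail == t & kg$triples$relation == r]
    }
    candidates <- setdiff(candidates, setdiff(other, truth_id))
  }
  miss <- setdiff(candidates, rownames(emb$E))
  if (length(miss))
    stop("candidates without embeddings: ", paste(utils::head(miss, 5),
                                                  collapse = ", "))
  H <- if (slot == "tail") {
    matrix(emb_vec(emb, h), nrow = length(candidates), ncol = ncol(emb$E),
           byrow = TRUE)
  } else emb$E[candidates, , drop = FALSE]
  T_ <- if (slot == "tail") emb$E[candidates, , drop = FALSE] else
    matrix(emb_vec(emb, t), nrow = length(candidates), ncol = ncol(emb$E),
           byrow = TRUE)
  Rm <- matrix(emb_vec(emb, r, "relation"), nrow = length(candidates),
               ncol = ncol(emb$R), byrow = TRUE)
  sc <- score_rows(H, Rm, T_, emb$scorer)
  s_true <- sc[match(truth_id, candidates)]
  others <- sc[-match(truth_id, candidates)]
  1 + sum(others > s_true) + 0.5 * sum(others == s_true)
}

#' Evaluate link prediction over a triple set
#'
#' Both the head and the tail query of every test triple are ranked and
#' pooled; the report carries MRR (mean reciprocal rank), MR (mean rank),
#' and Hits@N for N in `hits_at`.
#'
#' @param test Data frame of test triples (`head`, `relation`, `tail`).
#' @param emb An `embedding_set`.
#' @param kg The `kgraph` used for candidates/filtering.
#' @param mode `"filtered"` (default) or `"raw"`.
#' @param hits_at Integer vector of N values.
#' @param restrict_category Passed to [rank_entity()].
#' @return List of class `"linkpred_report"`: `mrr`, `mr`, `hits` (named),
#'   `mode`, `n_queries`, `ranks`.
#' @export
evaluate_link_prediction <- function(test, emb, kg,
                                     mode = c("filtered", "raw"),
                                     hits_at = c(1, 10, 100),
                                     restrict_category = TRUE) {
  mode <- match.arg(mode)
  if (is.null(test) || nrow(test) == 0) stop("empty test set")
  ranks <- numeric(0)
  for (i in seq_len(nrow(test))) {
    for (slot in c("tail", "head")) {
      ranks <- c(ranks, rank_entity(test$head[i], test$relation[i],
                                    test$tail[i], slot = slot, emb = emb,
                                    kg = kg, mode = mode,
                                    restrict_category = restrict_category))
    }
  }
  hits <- vapply(hits_at, function(nn) mean(ranks <= nn), numeric(1))
  names(hits) <- paste0("hits_at_", hits_at)
  rep <- list(mrr = mean(1 / ranks), mr = mean(ranks), hits = hits,
              mode = mode, n_queries = length(ranks), ranks = ranks)
  class(rep) <- "linkpred_report"
  rep
}

#' @export
print.linkpred_report <- function(x, ...) {
  cat(sprintf("Link prediction (%s, %d queries): MRR %.4f  MR %.1f\n",
              x$mode, x$n_queries, x$mrr, x$mr))
  for (nm in names(x$hits))
    cat(sprintf("  %-12s %.4f\n", sub("hits_at_", "Hits@", nm), x$hits[[nm]]))
  invisible(x)
}

#' Knowledge-graph-only label prediction baseline
#'
#' Predicts nature/location labels from the graph alone, without any text
#' model: for each label, the plausibility of reaching it from a record's
#' entities through a syndrome is the two-hop score
#' `max over syndromes s of min(score(e, rel_e, s), score(s, rel_label, L))`,
#' aggregated over the record's entities (mean by default). The full ranked
#' score vector is returned so the multilabel metric suite applies.
#'
#' @param record_entities Character vector of entity ids found in a record.
#' @param emb An `embedding_set`.
#' @param kg The `kgraph`.
#' @param label_space Label entity ids (defaults to all nature and location
#'   entities).
#' @param agg Aggregation across record entities: `"mean"` (default),
#'   `"max"`, or `"sum"`.
#' @return Named numeric score vector over `label_space`.
#' @export
kg_baseline_predict <- function(record_entities, emb, kg, label_space = NULL,
                                agg = c("mean", "max", "sum")) {
  agg <- match.arg(agg)
  if (is.null(label_space))
    label_space <- c(entities_of_category(kg, "nature"),
                     entities_of_category(kg, "location"))
  cat_of <- stats::setNames(kg$entities$category, kg$entities$entity_id)
  ok <- record_entities[record_entities %in% rownames(emb$E) &
                          cat_of[record_entities] %in%
                          c("symptom", "chief_complaint")]
  if (length(ok) == 0) {
    warning("no record entity is linkable to the graph; returning uniform scores")
    return(stats::setNames(rep(0, length(label_space)), label_space))
  }
  syndromes <- entities_of_category(kg, "syndrome")
  d <- ncol(emb$E)
  rel_of_ent <- ifelse(cat_of[ok] == "chief_complaint",
                       "chief_complaint_syndrome", "symptom_syndrome")
  rel_of_lab <- ifelse(cat_of[label_space] == "nature",
                       "syndrome_nature", "syndrome_location")
  # hop 1: entity -> syndrome  (n_ent x n_syn)
  S1 <- matrix(NA_real_, length(ok), length(syndromes))
  for (j in seq_along(syndromes)) {
    T_ <- matrix(emb$E[syndromes[j], ], length(ok), d, byrow = TRUE)
    S1[, j] <- score_rows(emb$E[ok, , drop = FALSE],
                          emb$R[rel_of_ent, , drop = FALSE], T_, emb$scorer)
  }
  # hop 2: syndrome -> label  (n_syn x n_lab)
  S2 <- matrix(NA_real_, length(syndromes), length(label_space))
  for (j in seq_along(label_space)) {
    T_ <- matrix(emb$E[label_space[j], ], length(syndromes), d, byrow = TRUE)
    S2[, j] <- score_rows(emb$E[syndromes, , drop = FALSE],
                          matrix(emb$R[rel_of_lab[j], ], length(syndromes),
                                 d, byrow = TRUE), T_, emb$scorer)
  }
  # per entity e and label L: max over s of min(S1[e,s], S2[s,L])
  per_ent <- matrix(-Inf, length(ok), length(label_space))
  for (s in seq_along(syndromes)) {
    two_hop <- outer(S1[, s], S2[s, ], pmin)
    per_ent <- pmax(per_ent, two_hop)
  }
  scores <- switch(agg,
                   mean = colMeans(per_ent),
                   max = apply(per_ent, 2, max),
                   sum = colSums(per_ent))
  stats::setNames(scores, label_space)
}

#' Persist / load an embedding set as text files
#'
#' Entity and relation vectors are written as tab-separated matrices with an
#' id-order manifest column; the training config goes into a JSON sidecar.
#'
#' @param emb An `embedding_set`.
#' @param dir Output directory.
#' @return The directory (write) or an `embedding_set` (read).
#' @export
write_embeddings <- function(emb, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  we <- function(M, path) {
    df <- data.frame(id = rownames(M), M, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  we(emb$E, file.path(dir, "entity_vectors.tsv"))
  we(emb$R, file.path(dir, "relation_vectors.tsv"))
  jsonlite::write_json(
    c(unclass(emb$config), list(loss_trace = emb$loss_trace)),
    file.path(dir, "kge_config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(dir) {
  re <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE)
    M <- as.matrix(df[, -1, drop = FALSE])
    dimnames(M) <- list(df$id, NULL)
    M
  }
  cfgj <- jsonlite::fromJSON(file.path(dir, "kge_config.json"))
  loss <- cfgj$loss_trace
  cfgj$loss_trace <- NULL
  cfg <- do.call(kge_config, cfgj)
  emb <- list(E = re(file.path(dir, "entity_vectors.tsv")),
              R = re(file.path(dir, "relation_vectors.tsv")),
              scorer = cfg$scorer, config = cfg, loss_trace = loss)
  class(emb) <- "embedding_set"
  emb
}
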