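# Character-level text encoder with entity-embedding fusion and a linear
# multilabel head, trained end-to-end by backpropagation written out
# explicitly (reverse-mode for every block), so the whole model is plain R
# matrices and deterministic for a fixed seed.
#
# Dataflow per record: tokens -> encoder -> entity fusion (add each linked
# entity's KG vector onto the hidden states of the characters it spans) ->
# attention integration of the CLS state with pooled symptom/chief span
# vectors -> linear head over the integrated CLS representation.

#' Classifier / encoder configuration
#'
#' The encoder is a small configurable transformer standing in for a
#' pretrained character-level language model: same contract (per-character
#' hidden states, CLS pooling), desk-scale size. Any encoder honouring that
#' contract can be substituted.
#'
#' @param hidden_dim Hidden width (divisible by `n_heads`).
#' @param n_layers Encoder layers.
#' @param n_heads Attention heads.
#' @param ffn_dim Feed-forward width.
#' @param max_len Maximum input length in tokens.
#' @param epochs,batch_size,lr Adam schedule.
#' @param fusion Enable entity-embedding fusion (ablation switch).
#' @param integrate Enable the attention-integration block; when off the
#'   head reads the CLS state directly.
#' @param seed Integer seed.
#' @return List of class `"clf_config"`.
#' @export
clf_config <- function(hidden_dim = 32, n_layers = 1, n_heads = 2,
                       ffn_dim = 64, max_len = 64, epochs = 30,
                       batch_size = 8, lr = 5e-3, fusion = TRUE,
                       integrate = TRUE, seed = 1L) {
  cfg <- list(hidden_dim = as.integer(hidden_dim),
              n_layers = as.integer(n_layers),
              n_heads = as.integer(n_heads), ffn_dim = as.integer(ffn_dim),
              max_len = as.integer(max_len), epochs = as.integer(epochs),
              batch_size = as.integer(batch_size), lr = as.numeric(lr),
              fusion = isTRUE(fusion), integrate = isTRUE(integrate),
              seed = as.integer(seed))
  if (cfg$hidden_dim %% cfg$n_heads != 0)
    config_error("hidden_dim must be divisible by n_heads")
  if (cfg$max_len < 4) config_error("max_len must be at least 4")
  class(cfg) <- "clf_config"
  cfg
}

rmat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

new_params <- function(vocab_size, n_labels, d_e, cfg) {
  d <- cfg$hidden_dim
  sd <- 1 / sqrt(d)
  att_block <- function() list(Wq = rmat(d, d, sd), Wk = rmat(d, d, sd),
                               Wv = rmat(d, d, sd), Wo = rmat(d, d, sd))
  layers <- lapply(seq_len(cfg$n_layers), function(i)
    list(att = att_block(), W1 = rmat(d, cfg$ffn_dim, sd),
         b1 = numeric(cfg$ffn_dim), W2 = rmat(cfg$ffn_dim, d,
                                              1 / sqrt(cfg$ffn_dim)),
         b2 = numeric(d)))
  proj <- if (d_e == d) diag(d) else rmat(d_e, d, 1 / sqrt(d_e))
  list(Emb = rmat(vocab_size, d, sd), Pos = rmat(cfg$max_len, d, sd),
       layers = layers, proj = proj, Ws = rmat(d, d, sd),
       integ = att_block(), Whead = rmat(d, n_labels, sd),
       bhead = numeric(n_labels))
}

# ---- parameter-tree utilities (params/grads share one nested shape) -------

tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(e) tree_map(f, e)) else f(x)
}
tree_map2 <- function(f, x, y) {
  if (is.list(x)) Map(function(a, b) tree_map2(f, a, b), x, y) else f(x, y)
}
tree_zero <- function(x) tree_map(function(a) a * 0, x)

# ---- attention primitives -------------------------------------------------

softmax_rows <- function(M) {
  Z <- exp(M - apply(M, 1, max))
  Z / rowSums(Z)
}

mha_forward <- function(X, W, nh) {
  d <- ncol(X)
  dh <- d / nh
  Q <- X %*% W$Wq; K <- X %*% W$Wk; V <- X %*% W$Wv
  A <- vector("list", nh)
  Hcat <- matrix(0, nrow(X), d)
  for (h in seq_len(nh)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    Sc <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dh)
    A[[h]] <- softmax_rows(Sc)
    Hcat[, cols] <- A[[h]] %*% V[, cols, drop = FALSE]
  }
  list(O = Hcat %*% W$Wo, X = X, Q = Q, K = K, V = V, A = A, Hcat = Hcat)
}

mha_backward <- function(dO, cache, W, nh) {
  d <- ncol(cache$X)
  dh <- d / nh
  dWo <- t(cache$Hcat) %*% dO
  dHcat <- dO %*% t(W$Wo)
  dQ <- matrix(0, nrow(cache$X), d)
  dK <- dQ; dV <- dQ
  for (h in seq_len(nh)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    Ah <- cache$A[[h]]
    dHead <- dHcat[, cols, drop = FALSE]
    dV[, cols] <- t(Ah) %*% dHead
    dA <- dHead %*% t(cache$V[, cols, drop = FALSE])
    dSc <- Ah * (dA - rowSums(dA * Ah))
    dQ[, cols] <- dSc %*% cache$K[, cols, drop = FALSE] / sqrt(dh)
    dK[, cols] <- t(dSc) %*% cache$Q[, cols, drop = FALSE] / sqrt(dh)
  }
  dX <- dQ %*% t(W$Wq) + dK %*% t(W$Wk) + dV %*% t(W$Wv)
  list(dX = dX,
       dW = list(Wq = t(cache$X) %*% dQ, Wk = t(cache$X) %*% dK,
                 Wv = t(cache$X) %*% dV, Wo = dWo))
}

# ---- encoder --------------------------------------------------------------

encoder_forward <- function(ids, params, cfg) {
  X <- params$Emb[ids, , drop = FALSE] + params$Pos[seq_along(ids), ,
                                                    drop = FALSE]
  caches <- vector("list", cfg$n_layers)
  for (li in seq_len(cfg$n_layers)) {
    L <- params$layers[[li]]
    att <- mha_forward(X, L$att, cfg$n_heads)
    X1 <- X + att$O
    P <- sweep(X1 %*% L$W1, 2, L$b1, "+")
    Rl <- pmax(P, 0)
    Fo <- sweep(Rl %*% L$W2, 2, L$b2, "+")
    X2 <- X1 + Fo
    caches[[li]] <- list(att = att, X1 = X1, P = P, Rl = Rl)
    X <- X2
  }
  list(H = X, caches = caches, ids = ids)
}

encoder_backward <- function(dH, fwd, params, cfg, grads) {
  dX <- dH
  for (li in rev(seq_len(cfg$n_layers))) {
    L <- params$layers[[li]]
    cc <- caches_li <- fwd$caches[[li]]
    # FFN residual
    dF <- dX
    grads$layers[[li]]$W2 <- grads$layers[[li]]$W2 + t(cc$Rl) %*% dF
    grads$layers[[li]]$b2 <- grads$layers[[li]]$b2 + colSums(dF)
    dRl <- dF %*% t(L$W2)
    dP <- dRl * (cc$P > 0)
    grads$layers[[li]]$W1 <- grads$layers[[li]]$W1 + t(cc$X1) %*% dP
    grads$layers[[li]]$b1 <- grads$layers[[li]]$b1 + colSums(dP)
    dX1 <- dX + dP %*% t(L$W1)
    # attention residual
    mb <- mha_backward(dX1, cc$att, L$att, cfg$n_heads)
    grads$layers[[li]]$att <- tree_map2(`+`, grads$layers[[li]]$att, mb$dW)
    dX <- dX1 + mb$dX
  }
  # accumulate embedding/position grads row by row (ids may repeat)
  agg <- rowsum(dX, group = fwd$ids)
  rid <- as.integer(rownames(agg))
  grads$Emb[rid, ] <- grads$Emb[rid, ] + agg
  grads$Pos[seq_len(nrow(dX)), ] <- grads$Pos[seq_len(nrow(dX)), ] + dX
  grads
}

#' Encode an input sequence into per-token hidden states
#'
#' Deterministic forward pass of the character-level encoder. Tokens must be
#' in the model vocabulary.
#'
#' @param seq An `input_sequence`.
#' @param model A `fusion_model` (or a bare params/config pair).
#' @return Matrix (tokens x hidden_dim) of hidden states.
#' @export
encode <- function(seq, model) {
  ids <- match(seq$tokens, model$vocab)
  if (anyNA(ids))
    stop("token(s) outside vocabulary: ",
         paste(utils::head(seq$tokens[is.na(ids)], 5), collapse = ", "))
  encoder_forward(ids, model$params, model$config)$H
}

# ---- fusion ---------------------------------------------------------------

sentinel_vector <- function(key, d_e, seed, cache) {
  if (!is.null(cache[[key]])) return(cache[[key]])
  # draw from a key-derived stream without disturbing the caller's RNG state
  has_rs <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_rs) old <- get(".Random.seed", envir = globalenv())
  set.seed(derive_seed(seed, paste0("sentinel:", key)))
  v <- stats::rnorm(d_e, sd = 1 / sqrt(d_e))
  if (has_rs) assign(".Random.seed", old, envir = globalenv())
  cache[[key]] <- v
  v
}

span_entity_vectors <- function(seq, emb, d_e, seed, cache) {
  n <- nrow(seq$spans)
  V <- matrix(0, n, d_e)
  if (n == 0) return(V)
  for (k in seq_len(n)) {
    eid <- seq$spans$entity_id[k]
    V[k, ] <- if (!identical(eid, SENTINEL_ENTITY) &&
                  !is.null(emb) && eid %in% rownames(emb$E)) {
      emb$E[eid, ]
    } else {
      key <- if (identical(eid, SENTINEL_ENTITY)) {
        paste(seq$tokens[seq$spans$start[k]:(seq$spans$start[k] +
                                               seq$spans$length[k] - 1L)],
              collapse = " ")
      } else eid
      sentinel_vector(key, d_e, seed, cache)
    }
  }
  V
}

#' Fuse entity embeddings into per-token hidden states
#'
#' Implements the entity/character fusion rule: for each entity span, the
#' projected entity vector is added to the hidden state of every character
#' the span covers. Tokens under no span are returned bit-identical. Spans
#' whose entity has no embedding (or carries the sentinel id for unlinked
#' mentions) receive a seeded random vector, cached per surface so the same
#' unseen mention always draws the same vector within a run.
#'
#' @param hidden Matrix (tokens x hidden_dim) from [encode()].
#' @param spans Span data frame (`entity_id`, `start`, `length`).
#' @param emb An `embedding_set` (or `NULL` to force sentinels).
#' @param projector Matrix (d_e x hidden_dim) mapping entity vectors into
#'   the hidden space; identity when dimensions match and `NULL` is given.
#' @param seed Seed for sentinel vectors.
#' @param cache Environment caching sentinel vectors across calls.
#' @param tokens Optional token vector (for sentinel cache keys).
#' @return Matrix of fused hidden states, same shape as `hidden`.
#' @export
fuse_entities <- function(hidden, spans, emb, projector = NULL, seed = 1L,
                          cache = new.env(parent = emptyenv()),
                          tokens = NULL) {
  if (nrow(spans) == 0) return(hidden)
  if (any(spans$start < 1 | spans$start + spans$length - 1 > nrow(hidden)))
    stop("span out of range for the hidden-state matrix")
  d_e <- if (!is.null(emb)) ncol(emb$E) else ncol(hidden)
  if (is.null(projector)) {
    if (d_e != ncol(hidden))
      stop("projector required when entity and hidden dimensions differ")
    projector <- diag(d_e)
  }
  seq_like <- list(spans = spans, tokens = tokens %||%
                     as.character(seq_len(nrow(hidden))))
  V <- span_entity_vectors(seq_like, emb, d_e, seed, cache)
  Vp <- V %*% projector
  for (k in seq_len(nrow(spans))) {
    rows <- spans$start[k]:(spans$start[k] + spans$length[k] - 1L)
    hidden[rows, ] <- hidden[rows, ] +
      matrix(Vp[k, ], length(rows), ncol(hidden), byrow = TRUE)
  }
  hidden
}

# ---- attention integration ------------------------------------------------

integrate_forward <- function(C, Svecs, Cvecs, params, nh) {
  Z <- rbind(C, Svecs, Cvecs)
  Xi <- Z %*% params$Ws
  att <- mha_forward(Xi, params$integ, nh)
  list(Cprime = att$O[1, ], Z = Z, Xi = Xi, att = att)
}

#' Integrate chief-complaint and symptom information into the CLS state
#'
#' Builds the sequence `[C; S_1..M; Cc_1..N]`, projects it with the shared
#' input projection, runs one multi-head self-attention block (per-head
#' query/key/value projections, heads concatenated and projected by the
#' output matrix), and returns the output at the `C` position.
#'
#' @param C Hidden vector at the CLS position.
#' @param S Matrix (M x hidden_dim) of pooled symptom span vectors (may have
#'   zero rows).
#' @param Cc Matrix (N x hidden_dim) of pooled chief-complaint span vectors.
#' @param params List with `Ws` and `integ` (Wq/Wk/Wv/Wo) blocks, e.g.
#'   `model$params`.
#' @param n_heads Number of attention heads.
#' @return The integrated representation `C'` (length hidden_dim).
#' @export
attention_integrate <- function(C, S, Cc, params, n_heads = 1) {
  S <- if (is.null(S)) matrix(0, 0, length(C)) else rbind(S)
  Cc <- if (is.null(Cc)) matrix(0, 0, length(C)) else rbind(Cc)
  if (nrow(S) + nrow(Cc) + 1 < 1) stop("need at least the C vector")
  if (ncol(S) != length(C) || ncol(Cc) != length(C))
    stop("dimension mismatch between C and S/Cc vectors")
  integrate_forward(matrix(C, 1), S, Cc, params, n_heads)$Cprime
}

# ---- full model forward/backward -----------------------------------------

# prep: per-record precomputed pieces (ids, spans, span entity vectors, y)
model_forward <- function(prep, params, cfg, want_cache = FALSE) {
  fwd <- encoder_forward(prep$ids, params, cfg)
  H <- fwd$H
  Hf <- H
  if (cfg$fusion && nrow(prep$spans) > 0) {
    Vp <- prep$V %*% params$proj
    for (k in seq_len(nrow(prep$spans))) {
      rows <- prep$rows[[k]]
      Hf[rows, ] <- Hf[rows, ] + matrix(Vp[k, ], length(rows), ncol(H),
                                        byrow = TRUE)
    }
  }
  C <- Hf[1, ]
  if (cfg$integrate) {
    pool <- function(which_seg) {
      ks <- which(prep$spans$segment == which_seg)
      if (length(ks) == 0) return(matrix(0, 0, ncol(Hf)))
      do.call(rbind, lapply(ks, function(k) colMeans(Hf[prep$rows[[k]], ,
                                                        drop = FALSE])))
    }
    Sv <- pool("symptom")
    Cv <- pool("chief")
    integ <- integrate_forward(C, Sv, Cv, params, cfg$n_heads)
    Cp <- integ$Cprime
  } else {
    integ <- NULL
    Cp <- C
  }
  logits <- drop(Cp %*% params$Whead) + params$bhead
  out <- list(logits = logits, Cprime = Cp)
  if (want_cache)
    out$cache <- list(fwd = fwd, H = H, Hf = Hf, integ = integ)
  out
}

bce_loss <- function(logits, y) {
  # numerically stable: log(1+exp(-|z|)) + max(z,0) - z*y, averaged
  z <- logits
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

model_backward <- function(prep, params, cfg, out, grads) {
  z <- out$logits
  y <- prep$y
  n_lab <- length(z)
  dz <- (sigmoid(z) - y) / n_lab
  Cp <- out$Cprime
  grads$Whead <- grads$Whead + outer(Cp, dz)
  grads$bhead <- grads$bhead + dz
  dCp <- drop(params$Whead %*% dz)
  Hf <- out$cache$Hf
  dHf <- matrix(0, nrow(Hf), ncol(Hf))
  if (cfg$integrate) {
    integ <- out$cache$integ
    dO <- matrix(0, nrow(integ$Xi), ncol(integ$Xi))
    dO[1, ] <- dCp
    mb <- mha_backward(dO, integ$att, params$integ, cfg$n_heads)
    grads$integ <- tree_map2(`+`, grads$integ, mb$dW)
    dXi <- mb$dX
    grads$Ws <- grads$Ws + t(integ$Z) %*% dXi
    dZ <- dXi %*% t(params$Ws)
    # row 1 -> CLS; remaining rows -> mean-pooled span token rows
    dHf[1, ] <- dHf[1, ] + dZ[1, ]
    ks <- c(which(prep$spans$segment == "symptom"),
            which(prep$spans$segment == "chief"))
    for (j in seq_along(ks)) {
      rows <- prep$rows[[ks[j]]]
      dHf[rows, ] <- dHf[rows, ] +
        matrix(dZ[1 + j, ] / length(rows), length(rows), ncol(Hf),
               byrow = TRUE)
    }
  } else {
    dHf[1, ] <- dHf[1, ] + dCp
  }
  # fusion backward: identity into H; projector grad from span additions
  if (cfg$fusion && nrow(prep$spans) > 0) {
    for (k in seq_len(nrow(prep$spans))) {
      rows <- prep$rows[[k]]
      dsum <- colSums(dHf[rows, , drop = FALSE])
      grads$proj <- grads$proj + outer(prep$V[k, ], dsum)
    }
  }
  encoder_backward(dHf, out$cache$fwd, params, cfg, grads)
}

# ---- Adam -----------------------------------------------------------------

adam_step <- function(params, grads, state, lr, t, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$m <- tree_map2(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) b2 * v + (1 - b2) * g^2, state$v,
                       grads)
  mhat <- tree_map(function(m) m / (1 - b1^t), state$m)
  vhat <- tree_map(function(v) v / (1 - b2^t), state$v)
  params <- tree_map2(function(p, u) p - u,
                      params,
                      tree_map2(function(m, v) lr * m / (sqrt(v) + eps),
                                mhat, vhat))
  list(params = params, state = state)
}

# ---- training / prediction ------------------------------------------------

label_space_of <- function(kg) {
  sort(c(entities_of_category(kg, "nature"),
         entities_of_category(kg, "location")))
}

record_truth <- function(record, label_space) {
  as.numeric(label_space %in% c(record$gold_natures, record$gold_locations))
}

prep_sequence <- function(seq, vocab, label_space, record, emb, d_e, seed,
                          cache) {
  ids <- match(seq$tokens, vocab)
  if (anyNA(ids))
    stop("token(s) outside vocabulary: ",
         paste(utils::head(seq$tokens[is.na(ids)], 5), collapse = ", "))
  spans <- seq$spans
  rows <- lapply(seq_len(nrow(spans)), function(k)
    spans$start[k]:(spans$start[k] + spans$length[k] - 1L))
  V <- span_entity_vectors(seq, emb, d_e, seed, cache)
  y <- if (!is.null(record)) record_truth(record, label_space) else NULL
  list(ids = ids, spans = spans, rows = rows, V = V, y = y,
       record_id = if (!is.null(record)) record$record_id else NA_character_)
}

build_vocab <- function(seq_list, kg) {
  toks <- unique(unlist(lapply(seq_list, `[[`, "tokens")))
  surf_toks <- unique(unlist(lapply(unname(kg_surfaces(kg)), tokenize_text)))
  unique(c(CLS_TOKEN, SEP_TOKEN, UNK_TOKEN, sort(unique(c(toks, surf_toks)))))
}

#' Train the fusion classifier
#'
#' Minimizes per-label binary cross-entropy with logits over the training
#' records, by minibatch Adam with analytic gradients through the head, the
#' attention-integration block, the entity fusion, and the encoder. Entity
#' vectors from the embedding set are frozen inputs; their projection into
#' the hidden space is trained. Deterministic for a fixed seed.
#'
#' @param records Training records (list of `emr_record`s).
#' @param kg The `kgraph` (fixes the label space and entity surfaces).
#' @param emb An `embedding_set` from [train_kge()], or `NULL` to run with
#'   sentinel vectors only.
#' @param config A [clf_config()].
#' @param label_space Optional explicit label id vector (defaults to the
#'   graph's nature + location entities).
#' @param validation Optional record list; per-epoch validation P@1 is
#'   logged.
#' @return A `fusion_model`: `params`, `vocab`, `label_space`, `config`,
#'   `history` (per-epoch mean training loss, and validation P@1 if
#'   requested).
#' @export
train_classifier <- function(records, kg, emb, config = clf_config(),
                             label_space = NULL, validation = NULL) {
  stopifnot(inherits(config, "clf_config"))
  label_space <- label_space %||% label_space_of(kg)
  for (r in records) {
    extra <- setdiff(c(r$gold_natures, r$gold_locations), label_space)
    if (length(extra))
      stop(sprintf("record %s carries labels outside the label space: %s",
                   r$record_id, paste(extra, collapse = ", ")))
  }
  set.seed(config$seed)
  seqs <- lapply(records, build_input_sequence, kg = kg,
                 max_length = config$max_len)
  vocab <- build_vocab(seqs, kg)
  d_e <- if (!is.null(emb)) ncol(emb$E) else config$hidden_dim
  params <- new_params(length(vocab), length(label_space), d_e, config)
  cache <- new.env(parent = emptyenv())
  preps <- Map(function(s, r) prep_sequence(s, vocab, label_space, r, emb,
                                            d_e, config$seed, cache),
               seqs, records)
  val_preps <- NULL
  if (!is.null(validation)) {
    vseqs <- lapply(validation, build_input_sequence, kg = kg,
                    max_length = config$max_len)
    val_preps <- Map(function(s, r) prep_sequence(s, vocab, label_space, r,
                                                  emb, d_e, config$seed,
                                                  cache),
                     vseqs, validation)
  }
  state <- list(m = tree_zero(params), v = tree_zero(params))
  t_step <- 0
  n <- length(preps)
  history <- list(loss = numeric(config$epochs),
                  val_p1 = rep(NA_real_, config$epochs))
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    epoch_loss <- 0
    for (b_start in seq(1, n, by = config$batch_size)) {
      idx <- perm[b_start:min(b_start + config$batch_size - 1L, n)]
      grads <- tree_zero(params)
      for (i in idx) {
        out <- model_forward(preps[[i]], params, config, want_cache = TRUE)
        epoch_loss <- epoch_loss + bce_loss(out$logits, preps[[i]]$y)
        grads <- model_backward(preps[[i]], params, config, out, grads)
      }
      grads <- tree_map(function(g) g / length(idx), grads)
      t_step <- t_step + 1
      st <- adam_step(params, grads, state, config$lr, t_step)
      params <- st$params
      state <- st$state
    }
    history$loss[epoch] <- epoch_loss / n
    if (!is.null(val_preps)) {
      sc <- t(vapply(val_preps, function(p)
        model_forward(p, params, config)$logits, numeric(length(label_space))))
      tr <- t(vapply(val_preps, `[[`, numeric(length(label_space)), "y"))
      history$val_p1[epoch] <- precision_at_k(sc, tr, 1)
      log_msg("epoch %d: loss %.4f  val P@1 %.3f", epoch,
              history$loss[epoch], history$val_p1[epoch])
    } else {
      log_msg("epoch %d: loss %.4f", epoch, history$loss[epoch])
    }
  }
  model <- list(params = params, vocab = vocab, label_space = label_space,
                config = config, history = history, d_e = d_e,
                sentinel_cache = cache, emb_scorer = emb$scorer %||% NA)
  class(model) <- "fusion_model"
  model
}

#' @export
print.fusion_model <- function(x, ...) {
  cat("Fusion classifier:", length(x$vocab), "tokens,",
      length(x$label_space), "labels, hidden", x$config$hidden_dim,
      if (x$config$fusion) "(entity fusion on)" else "(entity fusion off)",
      "\n")
  invisible(x)
}

#' Score records with a trained fusion model
#'
#' @param object A `fusion_model`.
#' @param records List of `emr_record`s.
#' @param kg The `kgraph` used at training time.
#' @param emb The `embedding_set` used at training time (or `NULL`).
#' @param ... Unused.
#' @return Matrix (records x labels) of raw label logits, rownames = record
#'   ids, colnames = label ids.
#' @export
predict.fusion_model <- function(object, records, kg, emb = NULL, ...) {
  seqs <- lapply(records, build_input_sequence, kg = kg,
                 max_length = object$config$max_len)
  preps <- Map(function(s, r) prep_sequence(s, object$vocab,
                                            object$label_space, r, emb,
                                            object$d_e, object$config$seed,
                                            object$sentinel_cache),
               seqs, records)
  sc <- t(vapply(preps, function(p)
    model_forward(p, object$params, object$config)$logits,
    numeric(length(object$label_space))))
  rownames(sc) <- vapply(records, `[[`, character(1), "record_id")
  colnames(sc) <- object$label_space
  sc
}

#' Linear multilabel output layer
#'
#' Maps a pooled sequence representation to one raw score per label;
#' sigmoid is applied only at loss/threshold time, so the returned scores
#' are directly usable by the ranking metrics.
#'
#' @param pooled Numeric vector (hidden_dim) -- the integrated CLS state.
#' @param head List with weight matrix `W` (hidden_dim x n_labels) and bias
#'   `b` (n_labels).
#' @return Numeric score vector of length `n_labels`.
#' @export
classify_scores <- function(pooled, head) {
  drop(pooled %*% head$W) + head$b
}

# scalar loss for a single prepared record -- used by the gradient checker
model_loss_fn <- function(prep, params, cfg) {
  out <- model_forward(prep, params, cfg)
  bce_loss(out$logits, prep$y)
}

#' Save / load a fusion model as a JSON checkpoint
#'
#' All parameter blocks are serialized at maximum decimal precision together
#' with the vocabulary, label space and configuration; a reloaded model
#' reproduces predictions to the precision of the decimal representation
#' (about 1e-15 relative).
#'
#' @param model A `fusion_model`.
#' @param path Checkpoint file path (`.json`).
#' @return `path` (save) or a `fusion_model` (load).
#' @export
save_model <- function(model, path) {
  obj <- list(params = model$params, vocab = model$vocab,
              label_space = model$label_space,
              config = unclass(model$config), d_e = model$d_e,
              history = model$history)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  model <- list(params = obj$params, vocab = obj$vocab,
                label_space = obj$label_space,
                config = do.call(clf_config, obj$config),
                d_e = obj$d_e, history = obj$history,
                sentinel_cache = new.env(parent = emptyenv()))
  class(model) <- "fusion_model"
  model
}
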