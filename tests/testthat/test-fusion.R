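toy_model <- function(vocab = c("[CLS]", "[SEP]", "[UNK]", "a", "b", "c"),
                      n_labels = 4, d = 4, d_e = 4, seed = 9, ...) {
  cfg <- clf_config(hidden_dim = d, n_layers = 1, n_heads = 2, ffn_dim = 6,
                    max_len = 10, seed = seed, ...)
  set.seed(seed)
  params <- syndromeKG:::new_params(length(vocab), n_labels, d_e, cfg)
  structure(list(params = params, vocab = vocab,
                 label_space = paste0("lab", seq_len(n_labels)),
                 config = cfg, d_e = d_e,
                 sentinel_cache = new.env(parent = emptyenv())),
            class = "fusion_model")
}

toy_seq <- function(tokens = c("[CLS]", "a", "b", "[UNK]", "[SEP]"),
                    spans = data.frame(entity_id = "e1", start = 2L,
                                       length = 2L, segment = "symptom",
                                       stringsAsFactors = FALSE)) {
  structure(list(tokens = tokens, spans = spans, max_length = 10),
            class = "input_sequence")
}

test_that("encoding is deterministic, shape-preserving, and vocab-checked", {
  m <- toy_model()
  s <- toy_seq()
  H1 <- encode(s, m)
  H2 <- encode(s, m)
  expect_identical(H1, H2)
  expect_equal(dim(H1), c(length(s$tokens), m$config$hidden_dim))
  bad <- toy_seq(tokens = c("[CLS]", "zzz", "[SEP]"))
  expect_error(encode(bad, m), "outside vocabulary")
})

test_that("a hand-computed forward pass matches the encoder on a 4-token input", {
  # single layer, single head; all projections identity, FFN weights zero:
  # attention output row i is sum_j softmax(X X^T / sqrt(d))_ij X_j, and the
  # residual adds X back. We recompute that by hand.
  cfg <- clf_config(hidden_dim = 2, n_layers = 1, n_heads = 1, ffn_dim = 2,
                    max_len = 8, seed = 1)
  vocab <- c("[CLS]", "x", "y", "[SEP]")
  set.seed(1)
  params <- syndromeKG:::new_params(length(vocab), 2, 2, cfg)
  I2 <- diag(2)
  params$layers[[1]]$att <- list(Wq = I2, Wk = I2, Wv = I2, Wo = I2)
  params$layers[[1]]$W1 <- matrix(0, 2, 2)
  params$layers[[1]]$W2 <- matrix(0, 2, 2)
  params$layers[[1]]$b1 <- c(0, 0)
  params$layers[[1]]$b2 <- c(0, 0)
  ids <- c(1, 2, 3, 4)
  X <- params$Emb[ids, ] + params$Pos[1:4, ]
  Sc <- X %*% t(X) / sqrt(2)
  A <- t(apply(Sc, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  expected <- X + A %*% X
  got <- syndromeKG:::encoder_forward(ids, params, cfg)$H
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("attention integration reduces to a hand softmax on identical inputs", {
  d <- 2
  params <- list(Ws = diag(d),
                 integ = list(Wq = diag(d), Wk = diag(d), Wv = diag(d),
                              Wo = diag(d)))
  v <- c(0.3, -0.7)
  # all three rows equal v: attention weights are uniform regardless of
  # scores, so the output at the C position is exactly v
  Cp <- attention_integrate(v, rbind(v), rbind(v), params, n_heads = 1)
  expect_equal(Cp, v, tolerance = 1e-12)
  # permuting the symptom vectors never changes the integrated state
  set.seed(3)
  S <- matrix(rnorm(6), 3, 2)
  p2 <- list(Ws = matrix(rnorm(4), 2), integ = list(Wq = matrix(rnorm(4), 2),
             Wk = matrix(rnorm(4), 2), Wv = matrix(rnorm(4), 2),
             Wo = matrix(rnorm(4), 2)))
  C <- rnorm(2)
  out1 <- attention_integrate(C, S, NULL, p2, n_heads = 1)
  out2 <- attention_integrate(C, S[c(3, 1, 2), ], NULL, p2, n_heads = 1)
  expect_equal(out1, out2, tolerance = 1e-12)
  expect_error(attention_integrate(C, matrix(0, 1, 3), NULL, p2, 1),
               "dimension mismatch")
})

test_that("entity fusion shifts exactly the covered positions", {
  set.seed(8)
  H <- matrix(rnorm(20), 5, 4)
  emb <- structure(list(E = matrix(rnorm(8), 2, 4,
                                   dimnames = list(c("e1", "e2"), NULL)),
                        R = matrix(0, 4, 4,
                                   dimnames = list(KG_RELATIONS, NULL)),
                        scorer = "transe_l2"), class = "embedding_set")
  spans <- data.frame(entity_id = "e1", start = 2L, length = 2L,
                      segment = "symptom", stringsAsFactors = FALSE)
  Hf <- fuse_entities(H, spans, emb)
  expect_identical(Hf[c(1, 4, 5), ], H[c(1, 4, 5), ])  # untouched rows
  expect_equal(Hf[2, ], H[2, ] + emb$E["e1", ])
  expect_equal(Hf[3, ], H[3, ] + emb$E["e1", ])
  # zero spans: identity
  expect_identical(fuse_entities(H, spans[0, ], emb), H)
  # two disjoint spans commute
  spans2 <- rbind(spans, data.frame(entity_id = "e2", start = 4L,
                                    length = 1L, segment = "chief"))
  out12 <- fuse_entities(H, spans2, emb)
  out21 <- fuse_entities(H, spans2[c(2, 1), ], emb)
  expect_equal(out12, out21)
  bad <- data.frame(entity_id = "e1", start = 5L, length = 3L,
                    segment = "symptom")
  expect_error(fuse_entities(H, bad, emb), "span out of range")
})

test_that("sentinel spans draw seeded vectors cached per surface", {
  H <- matrix(0, 3, 4)
  spans <- data.frame(entity_id = syndromeKG:::SENTINEL_ENTITY, start = 2L,
                      length = 1L, segment = "symptom",
                      stringsAsFactors = FALSE)
  cache <- new.env(parent = emptyenv())
  h1 <- fuse_entities(H, spans, NULL, seed = 5, cache = cache,
                      tokens = c("[CLS]", "mys", "[SEP]"))
  h2 <- fuse_entities(H, spans, NULL, seed = 5, cache = cache,
                      tokens = c("[CLS]", "mys", "[SEP]"))
  expect_identical(h1, h2)
  expect_false(all(h1[2, ] == 0))
})

test_that("the linear head matches a hand matrix-vector product", {
  head <- list(W = matrix(0, 3, 4), b = numeric(4))
  expect_equal(classify_scores(c(1, 2, 3), head), rep(0, 4))
  W <- matrix(1:12, 3, 4)
  b <- c(0.5, -0.5, 0, 1)
  x <- c(2, -1, 0.5)
  expect_equal(classify_scores(x, list(W = W, b = b)),
               as.numeric(x %*% W) + b)
})

test_that("analytic gradients match central finite differences", {
  cfg <- clf_config(hidden_dim = 4, n_layers = 1, n_heads = 2, ffn_dim = 6,
                    max_len = 8, fusion = TRUE, integrate = TRUE, seed = 9)
  vocab <- c("[CLS]", "[SEP]", "[UNK]", "a", "b")
  set.seed(42)
  params <- syndromeKG:::new_params(length(vocab), 4, 4, cfg)
  spans <- data.frame(entity_id = "e1", start = 2L, length = 2L,
                      segment = "symptom", stringsAsFactors = FALSE)
  prep <- list(ids = c(1L, 4L, 5L, 2L), spans = spans, rows = list(2:3),
               V = matrix(rnorm(4), 1), y = c(1, 0, 1, 0))
  out <- syndromeKG:::model_forward(prep, params, cfg, want_cache = TRUE)
  grads <- syndromeKG:::tree_zero(params)
  grads <- syndromeKG:::model_backward(prep, params, cfg, out, grads)
  eps <- 1e-5
  check_block <- function(get, set, g) {
    p <- get(params)
    for (i in seq_along(p)) {
      pp <- params
      q <- p; q[i] <- p[i] + eps
      pp <- set(pp, q)
      lp <- syndromeKG:::model_loss_fn(prep, pp, cfg)
      q[i] <- p[i] - eps
      pp <- set(pp, q)
      lm <- syndromeKG:::model_loss_fn(prep, pp, cfg)
      num <- (lp - lm) / (2 * eps)
      expect_lt(abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i])), 1e-4)
    }
  }
  check_block(function(p) p$Whead, function(p, v) { p$Whead <- v; p },
              grads$Whead)
  check_block(function(p) p$proj, function(p, v) { p$proj <- v; p },
              grads$proj)
  check_block(function(p) p$Ws, function(p, v) { p$Ws <- v; p }, grads$Ws)
  check_block(function(p) p$integ$Wq,
              function(p, v) { p$integ$Wq <- v; p }, grads$integ$Wq)
  check_block(function(p) p$layers[[1]]$att$Wk,
              function(p, v) { p$layers[[1]]$att$Wk <- v; p },
              grads$layers[[1]]$att$Wk)
  check_block(function(p) p$layers[[1]]$W1,
              function(p, v) { p$layers[[1]]$W1 <- v; p },
              grads$layers[[1]]$W1)
  check_block(function(p) p$Emb, function(p, v) { p$Emb <- v; p },
              grads$Emb)
})

test_that("classifier training is deterministic and rejects foreign labels", {
  w <- tiny_world(12)
  cfg <- w$config
  cfg$n_records <- 30L
  recs <- generate_records(w, cfg)
  kg <- build_kg(recs, world_lexicons(w))
  emb <- train_kge(kg, kge_config(dim = 8, epochs = 15, seed = 2))
  ccfg <- clf_config(hidden_dim = 8, ffn_dim = 16, epochs = 2, seed = 5)
  m1 <- train_classifier(recs, kg, emb, ccfg)
  m2 <- train_classifier(recs, kg, emb, ccfg)
  expect_identical(m1$params$Whead, m2$params$Whead)
  expect_identical(m1$params$Emb, m2$params$Emb)
  bad <- recs
  bad[[1]]$gold_natures <- c(bad[[1]]$gold_natures, "nat_999")
  expect_error(train_classifier(bad, kg, emb, ccfg),
               "outside the label space")
  sc <- predict(m1, recs[1:3], kg, emb)
  expect_equal(dim(sc), c(3, length(m1$label_space)))
  expect_identical(rownames(sc), vapply(recs[1:3], `[[`, character(1),
                                        "record_id"))
})

test_that("model checkpoints reload to matching predictions", {
  w <- tiny_world(14)
  cfg <- w$config
  cfg$n_records <- 25L
  recs <- generate_records(w, cfg)
  kg <- build_kg(recs, world_lexicons(w))
  emb <- train_kge(kg, kge_config(dim = 8, epochs = 10, seed = 2))
  m <- train_classifier(recs, kg, emb,
                        clf_config(hidden_dim = 8, ffn_dim = 12, epochs = 2,
                                   seed = 3))
  f <- tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(m2$vocab, m$vocab)
  expect_identical(m2$label_space, m$label_space)
  s1 <- predict(m, recs[1:4], kg, emb)
  s2 <- predict(m2, recs[1:4], kg, emb)
  expect_equal(s1, s2, tolerance = 1e-12)
})
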