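test_that("scorers match hand evaluations and symmetry properties", {
  # exact translation scores 0, the maximum of the translational scorer
  expect_equal(score_triple(c(1, 0), c(0, 1), c(1, 1), "transe_l2"), 0)
  expect_equal(score_triple(c(1, 0), c(0, 0), c(0, 1), "transe_l1"), -2)
  set.seed(1)
  for (i in 1:20) {
    h <- rnorm(4); r <- rnorm(4); t <- rnorm(4)
    expect_lte(score_triple(h, r, t, "transe_l2"),
               score_triple(h, r, h + r, "transe_l2"))
    # DistMult is symmetric in head and tail
    expect_equal(score_triple(h, r, t, "distmult"),
                 score_triple(t, r, h, "distmult"))
  }
  # ComplEx real-part product against a direct complex-arithmetic evaluation
  h <- rnorm(6); r <- rnorm(6); t <- rnorm(6)
  hc <- complex(real = h[1:3], imaginary = h[4:6])
  rc <- complex(real = r[1:3], imaginary = r[4:6])
  tc <- complex(real = t[1:3], imaginary = t[4:6])
  expect_equal(score_triple(h, r, t, "complex"),
               Re(sum(hc * rc * Conj(tc))))
  expect_error(score_triple(c(1, 2), c(1, 2, 3), c(1, 2), "transe_l2"),
               "dimension mismatch")
})

test_that("negative sampling respects categories and rejects true triples", {
  kg <- tiny_kg(3)
  set.seed(4)
  truth <- paste(kg$triples$head, kg$triples$relation, kg$triples$tail)
  cat_of <- stats::setNames(kg$entities$category, kg$entities$entity_id)
  n_head <- 0
  for (i in 1:500) {
    j <- sample(nrow(kg$triples), 1)
    neg <- negative_sample(kg$triples[j, ], kg)
    expect_false(paste(neg$head, neg$relation, neg$tail) %in% truth)
    sch <- syndromeKG:::REL_SCHEMA[[neg$relation]]
    expect_identical(unname(cat_of[neg$head]), unname(sch[["head"]]))
    expect_identical(unname(cat_of[neg$tail]), unname(sch[["tail"]]))
    if (neg$corrupted == "head") n_head <- n_head + 1
  }
  # head/tail corruption is a fair coin (4-sigma binomial band)
  expect_lt(abs(n_head / 500 - 0.5), 4 * sqrt(0.25 / 500))
})

test_that("training separates true triples from corruptions, deterministically", {
  kg <- tiny_kg(3)
  cfg <- kge_config(dim = 16, epochs = 80, lr = 0.05, seed = 9)
  emb1 <- train_kge(kg, cfg)
  emb2 <- train_kge(kg, cfg)
  expect_identical(emb1$E, emb2$E)
  expect_identical(emb1$R, emb2$R)
  tr <- kg$triples
  s_true <- vapply(seq_len(nrow(tr)), function(i)
    score_triple(emb1$E[tr$head[i], ], emb1$R[tr$relation[i], ],
                 emb1$E[tr$tail[i], ], emb1$scorer), numeric(1))
  set.seed(2)
  s_neg <- vapply(1:200, function(i) {
    j <- sample(nrow(tr), 1)
    n <- negative_sample(tr[j, ], kg)
    score_triple(emb1$E[n$head, ], emb1$R[n$relation, ], emb1$E[n$tail, ],
                 emb1$scorer)
  }, numeric(1))
  expect_gt(mean(s_true), mean(s_neg))
  # loss decreases overall (first quarter vs last quarter of the trace)
  q <- length(emb1$loss_trace) %/% 4
  expect_lt(mean(tail(emb1$loss_trace, q)), mean(head(emb1$loss_trace, q)))
})

test_that("bilinear comparators train end to end", {
  kg <- tiny_kg(6)
  for (sc in c("distmult", "complex")) {
    emb <- train_kge(kg, kge_config(dim = 16, scorer = sc, epochs = 40,
                                    lr = 0.05, seed = 3))
    rep <- evaluate_link_prediction(kg$triples[1:10, ], emb, kg,
                                    mode = "filtered")
    expect_true(is.finite(rep$mrr) && rep$mrr >= 0 && rep$mrr <= 1)
    expect_gte(rep$mr, 1)
  }
})

test_that("an exact-translation embedding ranks the truth first", {
  kg <- toy_exact_kg()
  emb <- toy_exact_embeddings()
  for (i in seq_len(nrow(kg$triples))) {
    for (slot in c("tail", "head")) {
      rk <- rank_entity(kg$triples$head[i], kg$triples$relation[i],
                        kg$triples$tail[i], slot = slot, emb = emb, kg = kg,
                        mode = "raw")
      expect_equal(rk, 1)
    }
  }
  rep <- evaluate_link_prediction(kg$triples, emb, kg, mode = "raw")
  expect_equal(rep$mrr, 1)
  expect_equal(rep$mr, 1)
  expect_equal(unname(rep$hits["hits_at_1"]), 1)
})

test_that("random embeddings give the uniform mean rank", {
  # 1 truth among 9 other candidates: expected rank (10 + 1)/2 = 5.5
  ents <- data.frame(entity_id = c("syn", paste0("n", 1:10)),
                     category = c("syndrome", rep("nature", 10)))
  tri <- data.frame(head = "syn", relation = "syndrome_nature", tail = "n1")
  kg <- kgraph(ents, tri)
  ranks <- vapply(1:800, function(s) {
    emb <- random_embeddings(kg, d = 4, seed = s)
    rank_entity("syn", "syndrome_nature", "n1", slot = "tail", emb = emb,
                kg = kg, mode = "raw")
  }, numeric(1))
  expect_lt(abs(mean(ranks) - 5.5), 0.3)
})

test_that("filtered ranks never exceed raw ranks", {
  kg <- tiny_kg(11)
  emb <- random_embeddings(kg, d = 8, seed = 5)
  for (i in seq_len(min(nrow(kg$triples), 25))) {
    for (slot in c("tail", "head")) {
      args <- list(kg$triples$head[i], kg$triples$relation[i],
                   kg$triples$tail[i], slot = slot, emb = emb, kg = kg)
      rk_f <- do.call(rank_entity, c(args, mode = "filtered"))
      rk_r <- do.call(rank_entity, c(args, mode = "raw"))
      expect_lte(rk_f, rk_r)
    }
  }
  rep_f <- evaluate_link_prediction(kg$triples, emb, kg, mode = "filtered")
  rep_r <- evaluate_link_prediction(kg$triples, emb, kg, mode = "raw")
  expect_gte(rep_f$mrr, rep_r$mrr)
  # hits are monotone in n
  expect_true(all(diff(rep_f$hits) >= 0))
  expect_gte(rep_f$mrr, unname(rep_f$hits["hits_at_1"]))
})

test_that("rank aggregation follows the reciprocal-rank definitions", {
  # hand-built ranks 1, 2, 4 -> mrr = (1 + 1/2 + 1/4)/3, mr = 7/3
  ranks <- c(1, 2, 4)
  expect_equal(mean(1 / ranks), (1 + 1 / 2 + 1 / 4) / 3)
  # drive the same numbers through the evaluator with a crafted embedding:
  # candidates at controlled distances from h + r
  kg <- toy_exact_kg()
  emb <- toy_exact_embeddings()
  rep <- evaluate_link_prediction(kg$triples[1, , drop = FALSE], emb, kg,
                                  mode = "raw")
  expect_equal(rep$n_queries, 2)
  expect_error(evaluate_link_prediction(kg$triples[0, ], emb, kg),
               "empty test")
})

test_that("the KG-only baseline recovers a planted syndrome's labels", {
  # single-syndrome world with exact-translation embeddings: the syndrome's
  # nature/location must outrank the decoys
  ents <- data.frame(
    entity_id = c("s1", "s2", "syn", "n1", "n2", "l1", "l2"),
    category = c("symptom", "symptom", "syndrome", "nature", "nature",
                 "location", "location"))
  tri <- data.frame(
    head = c("s1", "s2", "syn", "syn"),
    relation = c("symptom_syndrome", "symptom_syndrome", "syndrome_nature",
                 "syndrome_location"),
    tail = c("syn", "syn", "n1", "l1"))
  kg <- kgraph(ents, tri)
  d <- 4
  r_ss <- c(1, 0, 0, 0); r_sn <- c(0, 1, 0, 0); r_sl <- c(0, 0, 1, 0)
  syn <- c(0.5, 0, 0, 0)
  E <- rbind(s1 = syn - r_ss, s2 = syn - r_ss + 0.01, syn = syn,
             n1 = syn + r_sn, n2 = c(5, 5, 5, 5),
             l1 = syn + r_sl, l2 = c(-5, 5, -5, 5))
  R <- rbind(chief_complaint_syndrome = r_ss, symptom_syndrome = r_ss,
             syndrome_nature = r_sn, syndrome_location = r_sl)
  emb <- structure(list(E = E, R = R, scorer = "transe_l2",
                        config = kge_config(dim = d),
                        loss_trace = numeric(0)), class = "embedding_set")
  sc <- kg_baseline_predict(c("s1", "s2"), emb, kg)
  expect_true(all(sc[c("n1", "l1")] > max(sc[c("n2", "l2")])))
  # order of record entities is irrelevant under mean aggregation
  expect_identical(sc, kg_baseline_predict(c("s2", "s1"), emb, kg))
  # unlinkable entities degrade to uniform scores with a warning
  expect_warning(u <- kg_baseline_predict(c("ghost"), emb, kg),
                 "no record entity")
  expect_true(all(u == u[1]))
})

test_that("embedding persistence round-trips", {
  kg <- tiny_kg(2)
  emb <- train_kge(kg, kge_config(dim = 8, epochs = 10, seed = 2))
  dir <- tempfile()
  write_embeddings(emb, dir)
  emb2 <- read_embeddings(dir)
  expect_equal(emb2$E, emb$E, tolerance = 1e-12)
  expect_equal(emb2$R, emb$R, tolerance = 1e-12)
  expect_identical(emb2$scorer, emb$scorer)
})
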