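# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately take the slow, literal route.

# position of each label in the descending ranking, ties broken by lower
# index first (computed per label, no sorting)
oracle_positions <- function(s) {
  vapply(seq_along(s), function(l)
    1L + sum(s > s[l]) + sum(s[seq_len(l - 1L)] == s[l]), integer(1))
}

oracle_p_at_k <- function(s, y, k) {
  pos <- oracle_positions(s)
  sum(y[pos <= k]) / k
}

oracle_ap <- function(s, y) {
  pos <- oracle_positions(s)
  n_pos <- sum(y)
  ap <- 0
  r_prev <- 0
  for (depth in seq_along(s)) {
    pred <- pos <= depth
    p <- sum(y[pred]) / depth
    r <- sum(y[pred]) / n_pos
    ap <- ap + (r - r_prev) * p
    r_prev <- r
  }
  ap
}

oracle_rloss <- function(s, y) {
  viol <- 0
  tot <- 0
  for (i in which(y == 1)) for (j in which(y == 0)) {
    tot <- tot + 1
    if (s[i] <= s[j]) viol <- viol + 1
  }
  viol / tot
}

oracle_hamming <- function(s, y, threshold = 0.5) {
  pred <- as.numeric(1 / (1 + exp(-s)) >= threshold)
  mean(pred != y)
}

# full re-scoring link-prediction oracle; inlines the scoring arithmetic
oracle_score <- function(h, r, t, scorer) {
  switch(scorer,
    transe_l1 = -sum(abs(h + r - t)),
    transe_l2 = -sqrt(sum((h + r - t)^2)),
    distmult = sum(h * r * t),
    complex = {
      m <- length(h) / 2
      hr <- h[1:m]; hi <- h[(m + 1):(2 * m)]
      rr <- r[1:m]; ri <- r[(m + 1):(2 * m)]
      tr <- t[1:m]; ti <- t[(m + 1):(2 * m)]
      sum(rr * hr * tr + rr * hi * ti + ri * hr * ti - ri * hi * tr)
    })
}

oracle_linkpred <- function(test, emb, kg, mode) {
  cat_of <- stats::setNames(kg$entities$category, kg$entities$entity_id)
  schema <- list(chief_complaint_syndrome = c("chief_complaint", "syndrome"),
                 symptom_syndrome = c("symptom", "syndrome"),
                 syndrome_nature = c("syndrome", "nature"),
                 syndrome_location = c("syndrome", "location"))
  ranks <- numeric(0)
  for (i in seq_len(nrow(test))) {
    h <- test$head[i]; r <- test$relation[i]; t <- test$tail[i]
    for (slot in c("tail", "head")) {
      slot_cat <- schema[[r]][if (slot == "head") 1 else 2]
      cand <- kg$entities$entity_id[kg$entities$category == slot_cat]
      if (mode == "filtered") {
        truth_id <- if (slot == "tail") t else h
        if (slot == "tail") {
          known <- kg$triples$tail[kg$triples$head == h &
                                     kg$triples$relation == r]
        } else {
          known <- kg$triples$head[kg$triples$tail == t &
                                     kg$triples$relation == r]
        }
        cand <- setdiff(cand, setdiff(known, truth_id))
      }
      sc <- vapply(cand, function(cid) {
        hh <- if (slot == "head") emb$E[cid, ] else emb$E[h, ]
        tt <- if (slot == "tail") emb$E[cid, ] else emb$E[t, ]
        oracle_score(hh, emb$R[r, ], tt, emb$scorer)
      }, numeric(1))
      truth_id <- if (slot == "tail") t else h
      st <- sc[[truth_id]]
      others <- sc[names(sc) != truth_id]
      ranks <- c(ranks, 1 + sum(others > st) + 0.5 * sum(others == st))
    }
  }
  list(mrr = mean(1 / ranks), mr = mean(ranks),
       hits = c(hits_at_1 = mean(ranks <= 1), hits_at_10 = mean(ranks <= 10),
                hits_at_100 = mean(ranks <= 100)),
       ranks = ranks)
}

# greedy longest-match oracle over explicit span enumeration
oracle_longest_match <- function(tokens, surfaces) {
  surf_tok <- lapply(surfaces, function(s)
    strsplit(s, "[[:space:]]+")[[1]])
  spans <- list()
  for (i in seq_along(tokens)) {
    for (si in seq_along(surfaces)) {
      L <- length(surf_tok[[si]])
      if (i + L - 1 <= length(tokens) &&
          identical(tokens[i:(i + L - 1)], surf_tok[[si]])) {
        spans[[length(spans) + 1]] <- list(start = i, len = L,
                                           surface = surfaces[si])
      }
    }
  }
  out <- list()
  pos <- 1L
  while (pos <= length(tokens)) {
    here <- Filter(function(sp) sp$start == pos, spans)
    if (length(here)) {
      best <- here[[which.max(vapply(here, `[[`, numeric(1), "len"))]]
      out[[length(out) + 1]] <- best
      pos <- pos + best$len
    } else {
      pos <- pos + 1L
    }
  }
  out
}
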