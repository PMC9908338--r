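# End-to-end orchestration: synth -> split -> build-kg -> train-kge ->
# train-clf -> evaluate, plus the KG-only baseline, with one global seed
# threaded through every stochastic stage and a manifest of artifacts.

#' Assemble a run configuration
#'
#' One configuration drives a full run. Stage configs default to desk-scale
#' settings; any field can be overridden. Stage toggles allow a KG-baseline
#' only run or a fusion on/off ablation pair.
#'
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param out_dir Output directory for artifacts (`NULL` = keep in memory).
#' @param synth A [synth_config()] (its own `seed` is overridden by the
#'   derived stage seed).
#' @param world Optional pre-built `emr_world`; overrides `synth`.
#' @param kge A [kge_config()].
#' @param clf A [clf_config()].
#' @param train_frac Train fraction of the record split.
#' @param eval_kge Evaluate link prediction on a held-out triple fraction.
#' @param kge_holdout Fraction of triples held out for link-prediction
#'   evaluation (entities are kept covered by training triples).
#' @param run_kg_baseline,run_classifier Stage toggles.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, out_dir = NULL,
                       synth = synth_config(), world = NULL,
                       kge = kge_config(dim = 32, epochs = 150),
                       clf = clf_config(),
                       train_frac = 0.8, eval_kge = TRUE,
                       kge_holdout = 0.1, run_kg_baseline = TRUE,
                       run_classifier = TRUE) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir, synth = synth,
              world = world, kge = kge, clf = clf,
              train_frac = train_frac, eval_kge = isTRUE(eval_kge),
              kge_holdout = kge_holdout,
              run_kg_baseline = isTRUE(run_kg_baseline),
              run_classifier = isTRUE(run_classifier))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Top-level keys `seed`, `out_dir`, `train_frac`, `eval_kge`,
#' `kge_holdout`, `run_kg_baseline`, `run_classifier`, plus nested `synth`,
#' `kge`, `clf` blocks whose fields are passed to the respective config
#' constructors.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("seed", "out_dir", "train_frac", "eval_kge", "kge_holdout",
              "run_kg_baseline", "run_classifier"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$synth)) args$synth <- do.call(synth_config, y$synth)
  if (!is.null(y$kge)) args$kge <- do.call(kge_config, y$kge)
  if (!is.null(y$clf)) args$clf <- do.call(clf_config, y$clf)
  do.call(run_config, args)
}

# Hold out a triple fraction while keeping every entity covered by at least
# one training triple (otherwise held-out entities would have untrained,
# meaningless vectors).
holdout_triples <- function(kg, frac, seed) {
  set.seed(derive_seed(seed, "kge-holdout"))
  trip <- kg$triples
  n <- nrow(trip)
  want <- max(1L, floor(frac * n))
  perm <- sample.int(n)
  deg <- table(c(trip$head, trip$tail))
  test_idx <- integer(0)
  for (i in perm) {
    if (length(test_idx) >= want) break
    h <- trip$head[i]; t <- trip$tail[i]
    if (deg[[h]] > 1 && deg[[t]] > 1) {
      test_idx <- c(test_idx, i)
      deg[[h]] <- deg[[h]] - 1L
      deg[[t]] <- deg[[t]] - 1L
    }
  }
  if (length(test_idx) == 0)
    return(list(train = trip, test = trip[0, , drop = FALSE]))
  list(train = trip[-test_idx, , drop = FALSE],
       test = trip[test_idx, , drop = FALSE])
}

record_kg_entities <- function(record, kg) {
  surfaces <- kg_surfaces(kg)
  surf_to_id <- stats::setNames(names(surfaces), unname(surfaces))
  ids <- character(0)
  for (f in record$symptom_fields) {
    for (tok in tokenize_text(f)) {
      eid <- if (!is.null(record$entity_hints) &&
                 tok %in% names(record$entity_hints))
        as.character(record$entity_hints[[tok]])
      else unname(surf_to_id[tok])
      if (!is.na(eid)) ids <- c(ids, eid)
    }
  }
  for (tok in tokenize_text(record$chief_complaint %||% "")) {
    eid <- unname(surf_to_id[tok])
    if (!is.na(eid)) ids <- c(ids, eid)
  }
  unique(ids)
}

#' Run the full pipeline on a synthetic world
#'
#' Executes the enabled stages in dependency order: generate (or accept) a
#' world, sample and split records, build the knowledge graph from the
#' training records, train embeddings, optionally evaluate link prediction
#' on a held-out triple split, train the fusion classifier, score the test
#' records, and run the KG-only baseline. Returns a manifest with every
#' artifact and metric report; re-running with the same config reproduces
#' the reports exactly.
#'
#' @param config A [run_config()].
#' @return List of class `"run_report"`: `world`, `records`, `split`, `kg`,
#'   `emb`, `linkpred` (if enabled), `model`, `metrics` (classifier metric
#'   report), `kg_baseline` (baseline metric report), `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  manifest <- list(seed = config$seed, stages = character(0))
  stage <- function(nm) {
    manifest$stages <<- c(manifest$stages, nm)
    log_msg("stage: %s", nm)
  }

  stage("synth")
  world <- config$world
  if (is.null(world)) {
    scfg <- config$synth
    scfg$seed <- derive_seed(config$seed, "world")
    world <- generate_world(scfg)
  }
  rcfg <- world$config
  rcfg$seed <- derive_seed(config$seed, "records")
  records <- generate_records(world, rcfg)
  split <- split_records(records, train_frac = config$train_frac,
                         seed = config$seed)
  if (length(split$test) == 0)
    stop("empty test split; increase n_records or lower train_frac")

  stage("build-kg")
  lex <- world_lexicons(world)
  kg <- build_kg(split$train, lex)

  stage("train-kge")
  kcfg <- config$kge
  kcfg$seed <- derive_seed(config$seed, "kge")
  linkpred <- NULL
  if (config$eval_kge) {
    ho <- holdout_triples(kg, config$kge_holdout, config$seed)
    emb <- train_kge(kg, kcfg, triples = ho$train)
    if (nrow(ho$test) > 0) {
      stage("eval-kge")
      linkpred <- evaluate_link_prediction(ho$test, emb, kg,
                                           mode = "filtered")
    }
  } else {
    emb <- train_kge(kg, kcfg)
  }

  model <- NULL
  metrics <- NULL
  if (config$run_classifier) {
    stage("train-clf")
    ccfg <- config$clf
    ccfg$seed <- derive_seed(config$seed, "clf")
    model <- train_classifier(split$train, kg, emb, ccfg)
    stage("evaluate")
    scores <- predict(model, split$test, kg, emb)
    truths <- t(vapply(split$test, record_truth,
                       numeric(length(model$label_space)),
                       label_space = model$label_space))
    colnames(truths) <- model$label_space
    metrics <- evaluate_batch(scores, truths)
  }

  kg_baseline <- NULL
  if (config$run_kg_baseline) {
    stage("kg-baseline")
    label_space <- label_space_of(kg)
    bscores <- t(vapply(split$test, function(r)
      kg_baseline_predict(record_kg_entities(r, kg), emb, kg,
                          label_space = label_space),
      numeric(length(label_space))))
    btruths <- t(vapply(split$test, record_truth,
                        numeric(length(label_space)),
                        label_space = label_space))
    colnames(btruths) <- label_space
    kg_baseline <- evaluate_batch(bscores, btruths)
  }

  manifest$n_records <- length(records)
  manifest$n_train <- length(split$train)
  manifest$n_test <- length(split$test)
  manifest$n_rejected <- length(split$rejected)
  manifest$kg_stats <- kg_stats(kg)
  manifest$elapsed_s <- proc.time()[["elapsed"]] - t0

  report <- list(world = world, records = records, split = split, kg = kg,
                 emb = emb, linkpred = linkpred, model = model,
                 metrics = metrics, kg_baseline = kg_baseline,
                 manifest = manifest)
  class(report) <- "run_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_world(world, file.path(config$out_dir, "world.json"))
    write_records(records, file.path(config$out_dir, "records.jsonl"))
    write_kgraph(kg, config$out_dir)
    write_embeddings(emb, config$out_dir)
    jsonlite::write_json(report_summary(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# plain-list summary of the numeric outcomes (JSON-stable)
report_summary <- function(report) {
  strip <- function(m) {
    if (is.null(m)) return(NULL)
    list(p_at_k = as.list(m$p_at_k),
         hamming_loss = m$hamming_loss,
         average_precision = m$average_precision,
         label_ranking_loss = m$label_ranking_loss)
  }
  out <- list(
    seed = report$manifest$seed,
    n_train = report$manifest$n_train,
    n_test = report$manifest$n_test,
    classifier = strip(report$metrics),
    kg_baseline = strip(report$kg_baseline)
  )
  if (!is.null(report$linkpred))
    out$linkpred <- list(mrr = report$linkpred$mrr, mr = report$linkpred$mr,
                         hits = as.list(report$linkpred$hits),
                         mode = report$linkpred$mode)
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed", x$manifest$seed, "):",
      x$manifest$n_train, "train /", x$manifest$n_test, "test records\n")
  if (!is.null(x$linkpred)) print(x$linkpred)
  if (!is.null(x$metrics)) { cat("Classifier:\n"); print(x$metrics) }
  if (!is.null(x$kg_baseline)) { cat("KG baseline:\n"); print(x$kg_baseline) }
  invisible(x)
}
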