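#' End-to-end pipeline configuration
#'
#' A single declarative configuration for the full mining run:
#' preprocess -> topic dictionary -> topic-enhanced embedding ->
#' risk-factor classification -> review-augmented clustering ->
#' per-category keywords. Every stage can be switched off; downstream
#' stages then reuse artifacts already present in `out_dir` or refuse
#' to run. All stage seeds derive deterministically from the single
#' `seed`.
#'
#' Without an input corpus the pipeline runs on a synthetic
#' planted-topic corpus (`synthetic`), which is how the package is
#' exercised end-to-end without any external data.
#'
#' @param out_dir Output directory for artifacts and the manifest.
#' @param seed Global RNG seed.
#' @param stages Named logical list switching stages on/off.
#' @param comments_path Optional TSV of real comments (columns
#'   `post_id`, `comment_id`, `text`); `NULL` = synthetic corpus.
#' @param labeled_path Optional TSV (`text`, `label`) of annotated
#'   comments for classifier training; `NULL` with a synthetic corpus
#'   samples `n_labeled` ground-truth-labelled comments.
#' @param synthetic A [generator_config()].
#' @param cleaning A [cleaning_config()].
#' @param topicdict List: `seeds_per_topic`, `topn`, `iterations`.
#' @param embed A [training_config()].
#' @param classify A [classifier_config()].
#' @param n_labeled Size of the labelled subset sampled from a
#'   synthetic corpus.
#' @param cluster List: `theta` (similarity threshold in (0,1)) and
#'   `review` (run the automatic singleton review).
#' @param keywords List: `n` keywords per category, `window_size`.
#' @return An object of class `tr_pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            stages = list(preprocess = TRUE, topicdict = TRUE,
                                          embed = TRUE, classify = TRUE,
                                          cluster = TRUE, keywords = TRUE),
                            comments_path = NULL,
                            labeled_path = NULL,
                            synthetic = generator_config(seed = seed),
                            cleaning = cleaning_config(),
                            topicdict = list(seeds_per_topic = 5L, topn = 5L,
                                             iterations = 3L),
                            embed = training_config(dim = 50L, seed = seed),
                            classify = classifier_config(max_len = 32L, seed = seed),
                            n_labeled = 400L,
                            cluster = list(theta = 0.5, review = TRUE),
                            keywords = list(n = 10L, window_size = 5L)) {
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
         comments_path = comments_path, labeled_path = labeled_path,
         synthetic = synthetic, cleaning = cleaning, topicdict = topicdict,
         embed = embed, classify = classify, n_labeled = as.integer(n_labeled),
         cluster = cluster, keywords = keywords),
    class = "tr_pipeline_config"
  )
}

#' Validate a pipeline configuration
#'
#' Static checks before a run: missing input paths, invariant
#' violations (a negative `lambda`, a similarity threshold outside
#' (0, 1), a dropout of 1, ...) and stage-dependency problems (e.g. the
#' classifier stage enabled while the embedding stage is disabled and
#' no vector file is present). An empty result means the configuration
#' is valid.
#'
#' @param cfg A [pipeline_config()].
#' @return A tibble of diagnostics (`field`, `message`); zero rows when
#'   valid.
#' @export
validate_config <- function(cfg) {
  diags <- list()
  note <- function(field, message) {
    diags[[length(diags) + 1L]] <<- tibble(field = field, message = message)
  }
  if (!is.null(cfg$comments_path) && !file.exists(cfg$comments_path)) {
    note("comments_path", sprintf("input file '%s' does not exist", cfg$comments_path))
  }
  if (!is.null(cfg$labeled_path) && !file.exists(cfg$labeled_path)) {
    note("labeled_path", sprintf("labelled file '%s' does not exist", cfg$labeled_path))
  }
  if (cfg$embed$lambda < 0) note("embed$lambda", "lambda must be non-negative")
  th <- cfg$cluster$theta
  if (is.null(th) || th <= 0 || th >= 1) {
    note("cluster$theta", "similarity threshold theta must lie in (0, 1)")
  }
  if (cfg$topicdict$topn < 0) note("topicdict$topn", "topn must be >= 0")
  if (cfg$keywords$n <= 0) note("keywords$n", "keyword count must be positive")
  on <- function(s) isTRUE(cfg$stages[[s]])
  artifact <- function(f) file.exists(file.path(cfg$out_dir, f))
  if (on("topicdict") && !on("preprocess") && !artifact("comments.jsonl")) {
    note("stages", "topicdict stage needs the preprocess stage or an existing comments.jsonl")
  }
  if (on("classify") && !on("embed") && !artifact("vectors.txt")) {
    note("stages", "classify stage needs the embed stage or an existing vectors.txt")
  }
  if (on("cluster") && !on("classify") && !artifact("flagged.tsv")) {
    note("stages", "cluster stage needs the classify stage or an existing flagged.tsv")
  }
  if (on("keywords") && !on("cluster") && !artifact("assignments.tsv")) {
    note("stages", "keywords stage needs the cluster stage or an existing assignments.tsv")
  }
  if (length(diags) == 0L) {
    return(tibble(field = character(), message = character()))
  }
  bind_rows(diags)
}

write_jsonl <- function(rows, path) {
  lines <- vapply(rows, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, null = "null", digits = NA))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
}

read_comments_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  rows <- lapply(lines, jsonlite::fromJSON)
  tibble(
    comment_id = map_chr(rows, "comment_id"),
    post_id = map_chr(rows, function(r) r$post_id %||% NA_character_),
    text = map_chr(rows, "text"),
    tokens = map(rows, function(r) as.character(unlist(r$tokens))),
    label = map_int(rows, function(r) {
      if (is.null(r$label)) NA_integer_ else as.integer(r$label)
    })
  )
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

manifest_update <- function(out_dir, stage, files, manifest) {
  hashes <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(hashes) <- files
  manifest$stages[[stage]] <- list(outputs = files, md5 = hashes)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' Run the end-to-end mining pipeline
#'
#' Executes the enabled stages in order, writing each stage's artifacts
#' (plain-text formats throughout) and an MD5 manifest into
#' `cfg$out_dir`. Every stage reads its inputs from the previous
#' stage's files, so a resumed run over completed stages produces
#' byte-identical downstream artifacts. With `resume = TRUE`, stages
#' already listed in the manifest are skipped after their artifact
#' hashes are verified; a mismatch (a stale manifest) aborts the run.
#'
#' @param cfg A [pipeline_config()].
#' @param resume Reuse completed stages recorded in the manifest.
#' @return The manifest, invisibly (a list with per-stage outputs and
#'   MD5 hashes).
#' @export
run_pipeline <- function(cfg, resume = FALSE) {
  diags <- validate_config(cfg)
  if (nrow(diags) > 0L) {
    abort(paste0("invalid pipeline configuration:\n",
                 paste(sprintf("- %s: %s", diags$field, diags$message), collapse = "\n")))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  manifest <- list(seed = cfg$seed, stages = stats::setNames(list(), character()))
  if (resume && file.exists(manifest_path)) {
    manifest <- jsonlite::read_json(manifest_path)
    for (stage in names(manifest$stages)) {
      rec <- manifest$stages[[stage]]
      for (f in rec$outputs) {
        h <- unname(tools::md5sum(file.path(cfg$out_dir, f)))
        if (is.na(h) || !identical(h, rec$md5[[f]])) {
          abort(sprintf("stale manifest: artifact '%s' of stage '%s' changed or is missing", f, stage))
        }
      }
    }
  }
  done <- function(stage) resume && stage %in% names(manifest$stages)
  run_stage <- function(stage, fn) {
    if (!isTRUE(cfg$stages[[stage]]) || done(stage)) return(invisible(NULL))
    files <- tryCatch(fn(), error = function(e) {
      abort(sprintf("pipeline halted at stage '%s': %s", stage, conditionMessage(e)))
    })
    manifest <<- manifest_update(cfg$out_dir, stage, files, manifest)
  }
  out <- function(f) file.path(cfg$out_dir, f)

  run_stage("preprocess", function() {
    if (is.null(cfg$comments_path)) {
      gen <- generate_corpus(cfg$synthetic)
      comments <- tokenize_comments(gen$comments, cfg$cleaning)
      truth_file <- "truth.json"
      jsonlite::write_json(gen$truth, out(truth_file), auto_unbox = TRUE,
                           pretty = TRUE, na = "null")
    } else {
      raw <- utils::read.delim(cfg$comments_path, sep = "\t", header = TRUE,
                               colClasses = "character", quote = "")
      comments <- tokenize_comments(as_tibble(raw), cfg$cleaning)
      comments$label <- NA_integer_
      truth_file <- NULL
    }
    kept <- filter_ultrashort(comments, cfg$cleaning)$kept
    vocab <- build_vocab(kept)
    rows <- lapply(seq_len(nrow(kept)), function(i) {
      list(comment_id = kept$comment_id[[i]],
           post_id = if ("post_id" %in% names(kept)) kept$post_id[[i]] else NULL,
           text = kept$text[[i]], tokens = as.list(kept$tokens[[i]]),
           label = if (is.na(kept$label[[i]])) NULL else kept$label[[i]])
    })
    write_jsonl(rows, out("comments.jsonl"))
    write_tsv_plain(as.data.frame(vocab), out("vocab.tsv"))
    c("comments.jsonl", "vocab.tsv", truth_file)
  })

  run_stage("topicdict", function() {
    comments <- read_comments_jsonl(out("comments.jsonl"))
    sg_cfg <- cfg$embed
    sg_cfg$lambda <- 0
    sg_cfg$seed <- derive_seed(cfg$seed, 1L)
    sg <- train_skipgram(comments, config = sg_cfg)
    phrases <- generate_seed_phrases(cfg$synthetic,
                                     k_per_topic = cfg$topicdict$seeds_per_topic)
    dict <- topic_dictionary()
    for (topic_id in names(phrases)) {
      seeds <- seeds_from_phrases(phrases[[topic_id]])
      expanded <- expand_topic(seeds, sg, topn = cfg$topicdict$topn,
                               iterations = cfg$topicdict$iterations)
      dict <- assign_weights(dict, expanded, topic_id = topic_id, risk = TRUE)
    }
    entries <- split(stats::setNames(as.list(dict$entries$weight), dict$entries$word),
                     dict$entries$topic)
    jsonlite::write_json(entries, out("dictionary.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    writeLines(unlist(lapply(phrases, unlist)), out("seeds.txt"), useBytes = TRUE)
    c("dictionary.json", "seeds.txt")
  })

  run_stage("embed", function() {
    comments <- read_comments_jsonl(out("comments.jsonl"))
    dict <- topic_dictionary()
    if (file.exists(out("dictionary.json"))) {
      entries <- jsonlite::read_json(out("dictionary.json"))
      for (topic_id in names(entries)) {
        dict <- assign_weights(dict, names(entries[[topic_id]]),
                               topic_id = topic_id, risk = TRUE)
      }
    }
    em_cfg <- cfg$embed
    em_cfg$seed <- derive_seed(cfg$seed, 2L)
    model <- train_embeddings(comments, dict = dict, config = em_cfg)
    write_word2vec(model, out("vectors.txt"))
    write_tsv_plain(as.data.frame(model$loss_curve), out("loss_curve.csv"))
    c("vectors.txt", "loss_curve.csv")
  })

  run_stage("classify", function() {
    comments <- read_comments_jsonl(out("comments.jsonl"))
    model <- read_word2vec(out("vectors.txt"))
    if (!is.null(cfg$labeled_path)) {
      raw <- utils::read.delim(cfg$labeled_path, sep = "\t", header = TRUE, quote = "")
      labeled <- tokenize_comments(tibble(text = as.character(raw$text)), cfg$cleaning)
      labeled$label <- as.integer(raw$label)
    } else {
      pool <- comments[!is.na(comments$label), , drop = FALSE]
      n_lab <- min(cfg$n_labeled, nrow(pool))
      withr::with_seed(derive_seed(cfg$seed, 3L), {
        labeled <- pool[sample.int(nrow(pool), n_lab), , drop = FALSE]
      })
    }
    cl_cfg <- cfg$classify
    cl_cfg$seed <- derive_seed(cfg$seed, 4L)
    split_test <- seq_len(nrow(labeled)) %% 10L == 0L
    fit <- train_classifier(labeled[!split_test, , drop = FALSE], model, cl_cfg)
    metrics <- evaluate_classifier(fit, labeled[split_test, , drop = FALSE], model)
    jsonlite::write_json(as.list(metrics), out("metrics.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    flagged <- predict_corpus(fit, comments, model)
    write_tsv_plain(
      data.frame(comment_id = flagged$comment_id,
                 probability = sprintf("%.6f", flagged$.prob)),
      out("flagged.tsv")
    )
    c("metrics.json", "flagged.tsv")
  })

  run_stage("cluster", function() {
    comments <- read_comments_jsonl(out("comments.jsonl"))
    model <- read_word2vec(out("vectors.txt"))
    flagged_ids <- utils::read.delim(out("flagged.tsv"), sep = "\t",
                                     colClasses = "character")$comment_id
    flagged <- comments[comments$comment_id %in% flagged_ids, , drop = FALSE]
    docs <- doc_vectors(flagged, model)
    clusters <- single_pass(docs, theta = cfg$cluster$theta)
    if (isTRUE(cfg$cluster$review)) clusters <- review_pass(clusters)
    write_tsv_plain(as.data.frame(clusters$assignments), out("assignments.tsv"))
    report <- review_report(clusters, flagged, model = model)
    jsonlite::write_json(report, out("cluster_report.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    c("assignments.tsv", "cluster_report.json")
  })

  run_stage("keywords", function() {
    comments <- read_comments_jsonl(out("comments.jsonl"))
    asg <- utils::read.delim(out("assignments.tsv"), sep = "\t")
    asg$comment_id <- as.character(asg$comment_id)
    rows <- lapply(sort(unique(asg$category)), function(cid) {
      ids <- asg$comment_id[asg$category == cid]
      toks <- unlist(comments$tokens[match(ids, comments$comment_id)])
      kw <- top_keywords(toks, n = cfg$keywords$n,
                         window_size = cfg$keywords$window_size)
      data.frame(category = cid, rank = kw$rank, word = kw$word,
                 weight = sprintf("%.6f", kw$weight))
    })
    write_tsv_plain(do.call(rbind, rows), out("keywords.tsv"))
    c("keywords.tsv")
  })

  invisible(manifest)
}
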