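# shared fixtures built in code

# wrap a hand-built vector matrix (rownames = words) as a usable model
toy_embedding <- function(W) {
  vocab <- tibble::tibble(word = rownames(W),
                          index = seq_len(nrow(W)) - 1L,
                          count = 1L)
  structure(
    list(vocab = vocab, W_in = W, W_out = matrix(0, nrow(W), ncol(W)),
         W_topic = NULL, topics = character(),
         config = list(dim = ncol(W), lambda = 0, negative = 0L),
         trained = TRUE, loss_curve = tibble::tibble()),
    class = "tr_embedding"
  )
}

# 6-word, 2-d hand-built embedding with a known cosine structure
toy_six_words <- function() {
  W <- rbind(
    sun    = c(1.00, 0.00),
    warm   = c(0.95, 0.10),
    heat   = c(0.90, 0.25),
    rain   = c(0.00, 1.00),
    damp   = c(0.10, 0.95),
    pollen = c(0.70, 0.70)
  )
  toy_embedding(W)
}

# a small word-indexed corpus over a fixed vocabulary, every comment
# at least min_len tokens; returns list(comments, vocab)
toy_corpus <- function(n_comments, vocab_size, min_len = 3L, max_len = 8L, seed = 1L) {
  words <- sprintf("w%02d", seq_len(vocab_size))
  withr::with_seed(seed, {
    tokens <- lapply(seq_len(n_comments), function(i) {
      sample(words, sample(min_len:max_len, 1L), replace = TRUE)
    })
  })
  tibble::tibble(
    comment_id = sprintf("c%03d", seq_len(n_comments)),
    text = vapply(tokens, paste, character(1), collapse = " "),
    tokens = tokens
  )
}

# an initialized (untrained) small model with fixed random output
# matrices, for loss/gradient tests
toy_topic_model <- function(words = c("a", "b", "c", "d", "e"),
                            dict = NULL, d = 4L, window = 2L,
                            negative = 0L, seed = 5L) {
  vocab <- build_vocab(list(words))
  cfg <- training_config(dim = d, window = window, seed = seed,
                         negative = negative)
  model <- withr::with_seed(seed, topicrisk:::new_embedding_model(vocab, cfg, dict))
  withr::with_seed(seed + 1L, {
    model$W_out <- matrix(stats::rnorm(nrow(vocab) * d, sd = 0.3), nrow(vocab), d)
    if (!is.null(model$W_topic)) {
      model$W_topic <- matrix(stats::rnorm(nrow(model$W_topic) * d, sd = 0.3),
                              nrow(model$W_topic), d)
    }
  })
  model$trained <- TRUE
  model
}

# two-topic dictionary over the toy 5-word vocabulary
toy_dict <- function() {
  dict <- topic_dictionary(default_weight = 1, risk_weight = 2)
  dict <- assign_weights(dict, c("a", "b"), "t1", risk = TRUE)
  assign_weights(dict, "c", "t2", risk = FALSE)
}

relative_error <- function(x, y) abs(x - y) / pmax(1e-8, abs(x) + abs(y))

# scaled-down pipeline configuration so end-to-end tests stay fast
tiny_pipeline <- function(dir, seed = 5) {
  pipeline_config(
    out_dir = dir, seed = seed,
    synthetic = generator_config(n_comments = 300, seed = seed),
    embed = training_config(dim = 24, epochs = 3, seed = seed),
    classify = classifier_config(max_len = 20, kernel_sizes = c(2L, 3L),
                                 filters_per_size = 16L, epochs = 5L, seed = seed),
    n_labeled = 150
  )
}

# finite-difference gradient of L_s with respect to every parameter
fd_gradients <- function(windows, model, lambda, negatives = NULL, eps = 1e-6) {
  out <- list()
  for (mat in c("W_in", "W_out", "W_topic")) {
    if (is.null(model[[mat]])) { out[[mat]] <- NULL; next }
    G <- model[[mat]] * 0
    for (i in seq_along(G)) {
      mp <- model; mp[[mat]][i] <- mp[[mat]][i] + eps
      mm <- model; mm[[mat]][i] <- mm[[mat]][i] - eps
      G[i] <- (topics_loss(windows, mp, lambda = lambda, negatives = negatives)$L_s -
                 topics_loss(windows, mm, lambda = lambda, negatives = negatives)$L_s) / (2 * eps)
    }
    out[[mat]] <- G
  }
  out
}
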