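make_labeled <- function(n = 40, seed = 61, risk_fraction = 0.5) {
  generate_labeled_set(generator_config(
    n_comments = n, words_per_topic = 10, background_vocab_size = 30,
    risk_fraction = risk_fraction, ultrashort_fraction = 0, seed = seed
  ))
}

small_cnn_cfg <- function(epochs = 8L, dropout = 0.2, ...) {
  classifier_config(max_len = 16L, kernel_sizes = c(2L, 3L),
                    filters_per_size = 8L, dropout = dropout, epochs = epochs,
                    batch_size = 16L, seed = 7L, ...)
}

test_that("vectorize_comment pads, truncates and zeroes OOV tokens", {
  m <- toy_six_words()
  cfg <- classifier_config(max_len = 5, kernel_sizes = 2)
  X <- vectorize_comment(c("sun", "rain", "pollen"), m, cfg)
  expect_identical(dim(X), c(5L, 2L))
  expect_identical(X[4, ], c(0, 0))
  expect_identical(X[5, ], c(0, 0))
  expect_identical(vectorize_comment(character(), m, cfg), matrix(0, 5, 2))
  # rows equal the stored vectors, checked row by row
  for (i in 1:3) {
    expect_identical(X[i, ], unname(m$W_in[c("sun", "rain", "pollen")[i], ]))
  }
  # OOV row is zero; truncation keeps the first max_len tokens
  X2 <- vectorize_comment(c("sun", "unknown_word", "rain"), m, cfg)
  expect_identical(X2[2, ], c(0, 0))
  X3 <- vectorize_comment(rep(c("sun", "rain"), 5), m, cfg)
  expect_identical(X3, vectorize_comment(rep(c("sun", "rain"), 5)[1:5], m, cfg))
})

test_that("forward pass: zero input with zero affine layer gives 0.5", {
  cfg <- classifier_config(max_len = 4, kernel_sizes = 2, filters_per_size = 3)
  params <- withr::with_seed(1, topicrisk:::init_cnn_params(2, cfg))
  params$W <- matrix(0, 2, 3)
  params$b <- c(0, 0)
  expect_equal(cnn_forward(matrix(0, 4, 2), params, cfg), 0.5)
})

test_that("forward pass probabilities are normalized and padding-invariant", {
  m <- toy_six_words()
  cfg16 <- classifier_config(max_len = 16, kernel_sizes = c(2, 3),
                             filters_per_size = 4)
  cfg24 <- classifier_config(max_len = 24, kernel_sizes = c(2, 3),
                             filters_per_size = 4)
  params <- withr::with_seed(2, topicrisk:::init_cnn_params(2, cfg16))
  withr::with_seed(3, {
    for (rep in 1:10) {
      tokens <- sample(rownames(m$W_in), sample(2:8, 1), replace = TRUE)
      A <- array(0, c(1, 16, 2)); A[1, , ] <- vectorize_comment(tokens, m, cfg16)
      fw <- topicrisk:::cnn_forward_batch(A, params, cfg16)
      expect_equal(unname(rowSums(fw$probs)), 1, tolerance = 1e-12)
      # same parameters, longer zero padding: identical probability
      p16 <- cnn_forward(vectorize_comment(tokens, m, cfg16), params, cfg16)
      p24 <- cnn_forward(vectorize_comment(tokens, m, cfg24), params, cfg24)
      expect_equal(p16, p24, tolerance = 1e-12)
    }
  })
})

test_that("hand-set single-filter convolution matches hand arithmetic", {
  cfg <- classifier_config(max_len = 2, kernel_sizes = 1, filters_per_size = 1)
  # input 2x2 matrix, kernel size 1 over d = 2, one filter
  X <- rbind(c(1, 2), c(3, -1))
  params <- list(
    kernels = list(matrix(c(0.5, -0.25), 2, 1)),  # filter weights (d x 1)
    biases = list(0.1),
    W = matrix(c(0, 1), 2, 1),  # logit_0 = 0, logit_1 = pooled feature
    b = c(0, 0)
  )
  # positions: x1.w = 1*0.5 - 2*0.25 = 0; x2.w = 3*0.5 + 1*0.25 = 1.75
  # + bias 0.1 -> ReLU -> max pool = 1.85; softmax(0, 1.85)
  expect_equal(cnn_forward(X, params, cfg),
               exp(1.85) / (1 + exp(1.85)), tolerance = 1e-12)
})

test_that("training overfits a separable set, is deterministic, inverts with labels", {
  lab <- make_labeled(n = 20, seed = 67)
  emb <- train_embeddings(lab$comments, dict = lab$dictionary,
                          config = training_config(dim = 16, epochs = 5, seed = 67))
  cfg <- small_cnn_cfg(epochs = 50L, dropout = 0)
  fit <- train_classifier(lab$comments, emb, cfg)
  train_metrics <- evaluate_classifier(fit, lab$comments, emb)
  expect_equal(train_metrics$accuracy, 1.0)

  fit2 <- train_classifier(lab$comments, emb, cfg)
  expect_identical(fit$params, fit2$params)

  inverted <- lab$comments
  inverted$label <- 1L - inverted$label
  fit_inv <- train_classifier(inverted, emb, cfg)
  inv_metrics <- evaluate_classifier(fit_inv, lab$comments, emb)
  expect_lte(inv_metrics$recall, 0.1)

  single <- lab$comments[lab$comments$label == 1L, ]
  expect_error(train_classifier(single, emb, cfg), "both classes")
})

test_that("metric identities follow the confusion-count formulas", {
  r <- metrics_report(tp = 8, fp = 2, fn = 1, tn = 9)
  expect_equal(round(r$precision, 3), 0.800)
  expect_equal(round(r$recall, 3), 0.889)
  expect_equal(round(r$accuracy, 3), 0.850)
  expect_equal(round(r$f1, 3), 0.842)
  perfect <- metrics_report(tp = 10, fp = 0, fn = 0, tn = 10)
  expect_true(all(c(perfect$accuracy, perfect$precision,
                    perfect$recall, perfect$f1) == 1))
})

test_that("an all-positive predictor on balanced data has recall 1, precision 0.5", {
  lab <- make_labeled(n = 20, seed = 71)
  emb <- train_embeddings(lab$comments, dict = lab$dictionary,
                          config = training_config(dim = 8, epochs = 2, seed = 71))
  fit <- train_classifier(lab$comments, emb, small_cnn_cfg(epochs = 2L))
  fit$config$decision_threshold <- 1e-12   # flags everything
  r <- evaluate_classifier(fit, lab$comments, emb)
  expect_equal(r$recall, 1.0)
  expect_equal(r$precision, 0.5)
})

test_that("cross-validation partitions are stratified and metrics average", {
  lab <- make_labeled(n = 100, seed = 73)
  emb <- train_embeddings(lab$comments, dict = lab$dictionary,
                          config = training_config(dim = 12, epochs = 3, seed = 73))
  cfg <- small_cnn_cfg(epochs = 3L)
  cv <- cross_validate(lab$comments, emb, cfg, folds = 10)
  expect_identical(nrow(cv$folds), 10L)
  # every item validated exactly once -> fold confusion counts total n
  n_validated <- sum(cv$folds$TP + cv$folds$FP + cv$folds$FN + cv$folds$TN)
  expect_identical(n_validated, 100L)
  # balanced 100 items, 10 folds: 10 per fold, 5 positives each (+/- 1)
  per_fold <- cv$folds$TP + cv$folds$FP + cv$folds$FN + cv$folds$TN
  expect_true(all(per_fold == 10))
  pos_per_fold <- cv$folds$TP + cv$folds$FN
  expect_true(all(abs(pos_per_fold - 5) <= 1))
  expect_equal(cv$mean$accuracy, mean(cv$folds$accuracy))
  expect_equal(cv$mean$recall, mean(cv$folds$recall))
  expect_error(cross_validate(lab$comments, emb, cfg, folds = 1), ">= 2")
})

test_that("predict_corpus thresholds probabilities and recovers the positive fraction", {
  lab <- make_labeled(n = 150, seed = 79, risk_fraction = 0.3)
  emb <- train_embeddings(lab$comments, dict = lab$dictionary,
                          config = training_config(dim = 16, epochs = 4, seed = 79))
  fit <- train_classifier(lab$comments[lab$comments$split == "train", ], emb,
                          small_cnn_cfg(epochs = 10L))
  all_flagged <- predict_corpus(fit, lab$comments, emb, threshold = 0)
  expect_identical(nrow(all_flagged), nrow(lab$comments))
  top_only <- predict_corpus(fit, lab$comments, emb, threshold = 1)
  expect_true(all(top_only$.prob >= 1))
  flagged <- predict_corpus(fit, lab$comments, emb)
  expect_lte(nrow(flagged), nrow(lab$comments))
  frac <- nrow(flagged) / nrow(lab$comments)
  expect_lt(abs(frac - 0.3), 0.1)
})
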