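test_that("training windows enumerate contexts within the sliding window", {
  v <- build_vocab(list(c("a", "b", "c", "d")))
  idx <- match(c("a", "b", "c", "d"), v$word)
  w <- generate_training_windows(c("a", "b", "c", "d"), window = 1, vocab = v)
  expect_identical(w$center, idx)
  expect_identical(w$contexts,
                   list(idx[2], idx[c(1, 3)], idx[c(2, 4)], idx[3]))

  single <- generate_training_windows("a", window = 2, vocab = v)
  expect_identical(nrow(single), 1L)
  expect_length(single$contexts[[1]], 0)

  # 200-token fixture vs brute-force enumeration at c = 2
  withr::with_seed(31, tokens <- sample(sprintf("w%02d", 1:25), 200, replace = TRUE))
  v2 <- build_vocab(list(tokens))
  w2 <- generate_training_windows(tokens, window = 2, vocab = v2)
  expected <- oracle_windows(match(tokens, v2$word), 2)
  for (i in seq_along(expected)) {
    expect_identical(sort(w2$contexts[[i]]), sort(expected[i][[1]]))
  }
})

test_that("loss decomposes as L_s = L_cont + lambda * L_topic", {
  dict <- toy_dict()
  model <- toy_topic_model(dict = dict)
  v <- model$vocab
  w <- generate_training_windows(c("a", "c", "e", "b", "a", "d"), window = 2,
                                 vocab = v, dict = dict)
  l0 <- topics_loss(w, model, lambda = 0)
  expect_identical(l0$L_s, l0$L_cont)
  for (lam in c(0.5, 2)) {
    l <- topics_loss(w, model, lambda = lam)
    expect_identical(l$L_s, l$L_cont + lam * l$L_topic)
    expect_gte(l$L_topic, 0)
  }
  # centres all outside the dictionary: topic loss is zero, not an error
  w_bg <- generate_training_windows(c("d", "e", "d"), window = 1,
                                    vocab = v, dict = dict)
  l_bg <- topics_loss(w_bg, model, lambda = 1)
  expect_identical(l_bg$L_topic, 0)
  expect_identical(l_bg$L_s, l_bg$L_cont)
})

test_that("uniform two-word model yields ln 2 per context pair", {
  vocab <- build_vocab(list(c("x", "y", "x", "y")))
  cfg <- training_config(dim = 3, window = 1, seed = 1, negative = 0)
  model <- withr::with_seed(1, topicrisk:::new_embedding_model(vocab, cfg))
  model$W_out <- matrix(0, 2, 3)  # uniform softmax over 2 outcomes
  model$trained <- TRUE
  w <- generate_training_windows(c("x", "y", "x"), window = 1, vocab = vocab)
  expect_equal(topics_loss(w, model)$L_cont, log(2))
})

test_that("analytic gradients match central finite differences", {
  dict <- toy_dict()
  model <- toy_topic_model(dict = dict)
  w <- generate_training_windows(c("a", "c", "e", "b", "a", "d"), window = 2,
                                 vocab = model$vocab, dict = dict)
  for (lam in c(0, 0.5, 2)) {
    g <- topics_gradients(w, model, lambda = lam)
    fd <- fd_gradients(w, model, lambda = lam)
    for (mat in names(fd)) {
      expect_lt(max(relative_error(g[[mat]], fd[[mat]])), 1e-4)
    }
    if (lam == 0) expect_true(all(g$W_topic == 0))
  }
})

test_that("negative-sampling gradients match finite differences with fixed noise", {
  words <- letters[1:7]
  dict <- topic_dictionary()
  dict <- assign_weights(dict, c("a", "b"), "t1", risk = TRUE)
  model <- toy_topic_model(words = words, dict = dict, negative = 3L)
  w <- generate_training_windows(c("a", "c", "e", "b", "g", "d"), window = 2,
                                 vocab = model$vocab, dict = dict)
  npairs <- sum(lengths(w$contexts))
  withr::with_seed(41, negs <- matrix(sample.int(7, npairs * 3, TRUE), npairs, 3))
  g <- topics_gradients(w, model, lambda = 1, negatives = negs)
  fd <- fd_gradients(w, model, lambda = 1, negatives = negs)
  for (mat in names(fd)) {
    expect_lt(max(relative_error(g[[mat]], fd[[mat]])), 1e-4)
  }
})

test_that("a zero-context batch contributes nothing to context gradients", {
  dict <- toy_dict()
  model <- toy_topic_model(dict = dict)
  w <- generate_training_windows("a", window = 2, vocab = model$vocab, dict = dict)
  expect_length(w$contexts[[1]], 0)
  g <- topics_gradients(w, model, lambda = 1)
  expect_true(all(g$W_out == 0))
  expect_false(all(g$W_topic == 0))  # topic task still active for "a"
  # batch with neither pairs nor labels errors
  w_none <- generate_training_windows("e", window = 2, vocab = model$vocab, dict = dict)
  expect_error(topics_loss(w_none, model), "no context pairs")
})

test_that("TopicS with lambda 0 matches the plain Skip-gram baseline exactly", {
  corpus <- toy_corpus(60, vocab_size = 20, seed = 43)
  dict <- topic_dictionary()
  dict <- assign_weights(dict, c("w01", "w02", "w03"), "t1", risk = TRUE)
  cfg <- training_config(dim = 8, window = 2, epochs = 2, seed = 43,
                         lambda = 0, negative = 0)
  m_dict <- train_embeddings(corpus, dict = dict, config = cfg)
  m_plain <- train_skipgram(corpus, config = cfg)
  expect_identical(m_dict$W_in, m_plain$W_in)
  expect_identical(m_dict$W_out, m_plain$W_out)
  expect_identical(m_dict$loss_curve$L_s, m_plain$loss_curve$L_s)
})

test_that("training is bitwise deterministic and loss decreases", {
  corpus <- toy_corpus(80, vocab_size = 25, min_len = 4, seed = 47)
  dict <- topic_dictionary()
  dict <- assign_weights(dict, sprintf("w%02d", 1:5), "t1", risk = TRUE)
  cfg <- training_config(dim = 10, window = 2, epochs = 5, seed = 47,
                         learning_rate = 0.3)
  m1 <- train_embeddings(corpus, dict = dict, config = cfg)
  m2 <- train_embeddings(corpus, dict = dict, config = cfg)
  expect_identical(m1$W_in, m2$W_in)
  expect_identical(m1$loss_curve, m2$loss_curve)
  expect_true(all(diff(m1$loss_curve$L_s) <= 0))
  # exact decomposition at every logged epoch
  expect_identical(m1$loss_curve$L_s,
                   m1$loss_curve$L_cont + cfg$lambda * m1$loss_curve$L_topic)
})

test_that("most_similar ranks by cosine with deterministic tie-breaks", {
  W <- rbind(a = c(1, 0), b = c(1, 0), c = c(0, 1), d = c(2, 0))
  model <- toy_embedding(W)
  ms <- most_similar(model, "a", topn = 3)
  expect_identical(ms$word[1:2], c("b", "d"))  # cosine 1 both; tie by index
  expect_equal(ms$similarity[1:2], c(1, 1))
  expect_equal(ms$similarity[ms$word == "c"], 0)
  expect_error(most_similar(model, "zzz"), "vocabulary")

  # full ranking on the 6-word fixture vs exhaustive cosine table
  m6 <- toy_six_words()
  W6 <- m6$W_in
  for (w in rownames(W6)) {
    sims <- apply(W6, 1, function(r) {
      sum(r * W6[w, ]) / sqrt(sum(r^2) * sum(W6[w, ]^2))
    })
    sims[w] <- -Inf
    expected <- names(sort(sims, decreasing = TRUE))
    expect_identical(most_similar(m6, w, topn = 5)$word, expected[1:5])
  }
})

test_that("word2vec text round trip preserves words and vectors", {
  corpus <- toy_corpus(20, vocab_size = 10, seed = 53)
  m <- train_skipgram(corpus, config = training_config(dim = 6, epochs = 1, seed = 3))
  path <- withr::local_tempfile(fileext = ".txt")
  write_word2vec(m, path)
  m2 <- read_word2vec(path)
  expect_identical(rownames(m2$W_in), rownames(m$W_in))
  expect_equal(unname(m2$W_in), unname(m$W_in), tolerance = 1e-7)
  expect_identical(readLines(path, n = 1), sprintf("%d %d", nrow(m$W_in), 6))
})
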