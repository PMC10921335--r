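#' Training configuration for the topic-enhanced Skip-gram model
#'
#' The embedding is trained with two prediction tasks sharing one input
#' matrix: the classic Skip-gram task (predict each context word within
#' a +/- `window` sliding window of the centre word) and a topic task
#' (predict the centre word's topic from the topic dictionary). The
#' combined objective is `L_s = L_cont + lambda * L_topic`; `lambda = 0`
#' reduces the model exactly to plain Skip-gram.
#'
#' `L_cont` uses the full softmax over the vocabulary when
#' `negative = 0` and the negative-sampling objective (noise drawn from
#' the unigram distribution raised to 0.75) when `negative > 0`. By
#' default (`negative = NULL`) the full softmax is used for
#' vocabularies up to 5000 words and 5 negative samples beyond that.
#'
#' @param dim Embedding dimension (commonly swept over 100–400 on real
#'   corpora; small synthetic corpora are well served by 50–100).
#' @param window Context window half-width `c` (>= 1).
#' @param lambda Weight balancing the topic loss against the context
#'   loss (>= 0).
#' @param learning_rate Initial SGD learning rate; decays linearly per
#'   epoch to 1% of its initial value. The default 0.5 suits the
#'   per-comment batch updates used here (each step is the mean
#'   gradient over a comment's windows, so steps are far smaller than
#'   classic per-pair Skip-gram updates at equal rates).
#' @param epochs Number of passes over the corpus.
#' @param negative Number of negative samples per context pair (0 =
#'   full softmax); `NULL` selects automatically by vocabulary size.
#' @param min_count Minimum corpus frequency for vocabulary inclusion.
#' @param include_background If `TRUE`, the topic task uses K+1 classes
#'   and centre words absent from the dictionary are trained toward a
#'   background class at the dictionary default weight; if `FALSE`
#'   (default) such words simply contribute no topic loss.
#' @param seed RNG seed; training is bitwise-deterministic given the
#'   seed.
#' @return An object of class `tr_training_config`.
#' @export
training_config <- function(dim = 100L, window = 5L, lambda = 1.0,
                            learning_rate = 0.5, epochs = 5L,
                            negative = NULL, min_count = 1L,
                            include_background = FALSE, seed = 1L) {
  if (dim < 1 || window < 1 || epochs < 1) abort("dim, window and epochs must be >= 1")
  if (lambda < 0) abort("lambda must be non-negative")
  if (learning_rate <= 0) abort("learning_rate must be positive")
  if (!is.null(negative) && negative < 0) abort("negative must be >= 0")
  structure(
    list(dim = as.integer(dim), window = as.integer(window), lambda = lambda,
         learning_rate = learning_rate, epochs = as.integer(epochs),
         negative = if (is.null(negative)) NULL else as.integer(negative),
         min_count = as.integer(min_count),
         include_background = isTRUE(include_background),
         seed = as.integer(seed)),
    class = "tr_training_config"
  )
}

# enumerate (position, context-position) pairs for a sequence of length L
window_pairs <- function(L, window) {
  if (L < 2L) return(list(pos = integer(), ctxpos = integer()))
  i <- integer(); j <- integer()
  for (off in seq_len(min(window, L - 1L))) {
    a <- seq_len(L - off)
    i <- c(i, a, a + off)
    j <- c(j, a + off, a)
  }
  o <- order(i, j)
  list(pos = i[o], ctxpos = j[o])
}

#' Enumerate Skip-gram training windows
#'
#' Slides a window of half-width `window` over a token sequence and
#' emits one training example per position: the centre word, its
#' context words (positions within distance `window`, truncated at the
#' sequence ends), and — when a topic dictionary is supplied — the
#' centre word's topic label and dictionary weight.
#'
#' @param tokens Character vector (resolved against `vocab`) or
#'   1-based integer index vector.
#' @param window Window half-width.
#' @param vocab A `tr_vocab`, required when `tokens` is character.
#' @param dict Optional [topic_dictionary()] used to resolve topic
#'   labels.
#' @return A tibble with columns `center` (int index), `contexts` (list
#'   of int indices), `topic` (int topic index or `NA`), `weight`.
#' @examples
#' v <- build_vocab(list(c("a", "b", "c", "d")))
#' generate_training_windows(c("a", "b", "c", "d"), window = 1, vocab = v)
#' @export
generate_training_windows <- function(tokens, window = 5L, vocab = NULL, dict = NULL) {
  if (is.character(tokens)) {
    if (is.null(vocab)) abort("vocab is required to index character tokens")
    idx <- match(tokens, vocab$word)
    words <- tokens[!is.na(idx)]
    idx <- idx[!is.na(idx)]
  } else {
    idx <- as.integer(tokens)
    words <- if (!is.null(vocab)) vocab$word[idx] else as.character(idx)
  }
  L <- length(idx)
  if (L == 0L) {
    return(tibble(center = integer(), contexts = list(), topic = integer(), weight = numeric()))
  }
  wp <- window_pairs(L, window)
  contexts <- unname(split(idx[wp$ctxpos], factor(wp$pos, levels = seq_len(L))))
  topic <- rep(NA_integer_, L)
  weight <- rep(NA_real_, L)
  if (!is.null(dict) && nrow(dict$entries)) {
    topic <- dict_topic_index(dict, words)
    weight <- dict_weight(dict, words)
  }
  tibble(center = idx, contexts = contexts, topic = topic, weight = weight)
}

# Shared loss/gradient core. centers/topic/tweight are per-position
# vectors; (pos, ctx) index the context pairs. Returns losses and, when
# want_grad, gradients of L_s (input rows aggregated by vocabulary row,
# context-output either dense or row-sparse, topic-output dense).
topics_core <- function(centers, pos, ctx, topic, tweight,
                        W_in, W_out, W_topic, lambda, negative,
                        noise = NULL, negatives = NULL, want_grad = TRUE) {
  V <- nrow(W_out); d <- ncol(W_in)
  L <- length(centers)
  npairs <- length(pos)
  H <- W_in[centers, , drop = FALSE]
  dH <- if (want_grad) matrix(0, L, d) else NULL
  L_cont <- 0
  grad_out <- NULL; out_rows <- NULL

  if (npairs > 0L) {
    if (negative == 0L) {
      S <- H %*% t(W_out)
      lse <- log_sum_exp_rows(S)
      nctx <- tabulate(pos, nbins = L)
      L_cont <- (sum(lse * nctx) - sum(S[cbind(pos, ctx)])) / npairs
      if (want_grad) {
        P <- exp(S - lse)
        Cnt <- matrix(tabulate((pos - 1L) * V + ctx, nbins = L * V), L, V, byrow = TRUE)
        dS <- (P * nctx - Cnt) / npairs
        grad_out <- crossprod(dS, H)
        dH <- dH + dS %*% W_out
      }
    } else {
      k <- negative
      if (is.null(negatives)) {
        negatives <- matrix(sample.int(V, npairs * k, replace = TRUE, prob = noise),
                            npairs, k)
      }
      h <- H[pos, , drop = FALSE]
      u_pos <- W_out[ctx, , drop = FALSE]
      s_pos <- rowSums(h * u_pos)
      pair_of_neg <- rep(seq_len(npairs), times = k)
      u_neg <- W_out[as.vector(negatives), , drop = FALSE]
      s_neg <- rowSums(h[pair_of_neg, , drop = FALSE] * u_neg)
      L_cont <- (sum(-stats::plogis(s_pos, log.p = TRUE)) +
                   sum(-stats::plogis(-s_neg, log.p = TRUE))) / npairs
      if (want_grad) {
        g_pos <- (stats::plogis(s_pos) - 1) / npairs
        g_neg <- stats::plogis(s_neg) / npairs
        idx_all <- c(ctx, as.vector(negatives))
        coef_all <- c(g_pos, g_neg)
        H_all <- rbind(h, h[pair_of_neg, , drop = FALSE])
        agg <- rowsum(coef_all * H_all, idx_all)
        out_rows <- as.integer(rownames(agg))
        grad_out <- agg
        dh_pair <- g_pos * u_pos + rowsum(g_neg * u_neg, pair_of_neg)
        dH_pairs <- rowsum(dh_pair, pos)
        rows <- as.integer(rownames(dH_pairs))
        dH[rows, ] <- dH[rows, ] + dH_pairs
      }
    }
  }

  L_topic <- 0
  grad_topic <- NULL
  n_lab <- 0L
  if (!is.null(W_topic) && lambda >= 0) {
    has <- !is.na(topic)
    n_lab <- sum(has)
    if (n_lab > 0L) {
      Ht <- H[has, , drop = FALSE]
      lab <- topic[has]
      w <- tweight[has]
      St <- Ht %*% t(W_topic)
      lseT <- log_sum_exp_rows(St)
      L_topic <- sum(w * (lseT - St[cbind(seq_len(n_lab), lab)])) / n_lab
      if (want_grad && lambda > 0) {
        Pt <- exp(St - lseT)
        dSt <- (w / n_lab) * Pt
        dSt[cbind(seq_len(n_lab), lab)] <- dSt[cbind(seq_len(n_lab), lab)] - w / n_lab
        grad_topic <- lambda * crossprod(dSt, Ht)
        dH[has, ] <- dH[has, ] + lambda * (dSt %*% W_topic)
      }
    }
  }

  res <- list(L_cont = L_cont, L_topic = L_topic,
              L_s = L_cont + lambda * L_topic,
              n_pairs = npairs, n_labeled = n_lab)
  if (want_grad) {
    agg_in <- rowsum(dH, centers)
    res$grad_in <- agg_in
    res$grad_in_rows <- as.integer(rownames(agg_in))
    res$grad_out <- grad_out
    res$grad_out_rows <- out_rows   # NULL means dense over all rows
    res$grad_topic <- grad_topic
  }
  res
}

windows_to_core <- function(windows) {
  centers <- windows$center
  nctx <- lengths(windows$contexts)
  pos <- rep(seq_along(centers), nctx)
  ctx <- unlist(windows$contexts, use.names = FALSE)
  list(centers = centers, pos = pos, ctx = as.integer(ctx),
       topic = windows$topic, tweight = windows$weight)
}

#' Joint context + topic loss on a batch of training windows
#'
#' Computes the two loss components of the topic-enhanced Skip-gram
#' objective on a batch: `L_cont`, the mean negative log-likelihood of
#' each context word given its centre word (full softmax or negative
#' sampling per the model's configuration), and `L_topic`, the mean
#' dictionary-weight-scaled negative log-likelihood of the true topic
#' of each dictionary centre word. `L_s = L_cont + lambda * L_topic`
#' holds exactly. A batch whose centres all lie outside the dictionary
#' has `L_topic = 0`; a batch with no context pairs at all is an error.
#'
#' @param windows A window tibble from [generate_training_windows()].
#' @param model A `tr_embedding` model (trained or freshly initialized).
#' @param lambda Overrides the model's configured lambda when given.
#' @param negatives Optional pre-drawn negative-sample matrix
#'   (`n_pairs` x `k`), for reproducible loss under negative sampling.
#' @return A one-row tibble: `L_cont`, `L_topic`, `L_s`, `n_pairs`,
#'   `n_labeled`.
#' @export
topics_loss <- function(windows, model, lambda = NULL, negatives = NULL) {
  cd <- windows_to_core(windows)
  if (length(cd$pos) == 0L && all(is.na(cd$topic))) {
    abort("batch has no context pairs (and no topic labels)")
  }
  lambda <- lambda %||% model$config$lambda
  res <- topics_core(cd$centers, cd$pos, cd$ctx, cd$topic, cd$tweight,
                     model$W_in, model$W_out, model$W_topic,
                     lambda = lambda, negative = model_negative(model),
                     noise = model$noise, negatives = negatives,
                     want_grad = FALSE)
  tibble(L_cont = res$L_cont, L_topic = res$L_topic, L_s = res$L_s,
         n_pairs = res$n_pairs, n_labeled = res$n_labeled)
}

#' Analytic gradients of the joint loss
#'
#' Gradients of `L_s` with respect to the input, context-output and
#' topic-output matrices on a batch of windows, as full dense matrices
#' (zero rows for untouched parameters). A single step of size
#' `-learning_rate * gradient` decreases `L_s` for sufficiently small
#' steps on a fixed batch.
#'
#' @inheritParams topics_loss
#' @return A list of matrices `W_in`, `W_out`, `W_topic` (the last
#'   `NULL` when the model has no topic task).
#' @export
topics_gradients <- function(windows, model, lambda = NULL, negatives = NULL) {
  cd <- windows_to_core(windows)
  if (length(cd$pos) == 0L && all(is.na(cd$topic))) {
    abort("batch has no context pairs (and no topic labels)")
  }
  lambda <- lambda %||% model$config$lambda
  res <- topics_core(cd$centers, cd$pos, cd$ctx, cd$topic, cd$tweight,
                     model$W_in, model$W_out, model$W_topic,
                     lambda = lambda, negative = model_negative(model),
                     noise = model$noise, negatives = negatives,
                     want_grad = TRUE)
  g_in <- matrix(0, nrow(model$W_in), ncol(model$W_in))
  g_in[res$grad_in_rows, ] <- res$grad_in
  g_out <- matrix(0, nrow(model$W_out), ncol(model$W_out))
  if (!is.null(res$grad_out)) {
    if (is.null(res$grad_out_rows)) g_out <- g_out + res$grad_out
    else g_out[res$grad_out_rows, ] <- res$grad_out
  }
  g_topic <- NULL
  if (!is.null(model$W_topic)) {
    g_topic <- matrix(0, nrow(model$W_topic), ncol(model$W_topic))
    if (!is.null(res$grad_topic)) g_topic <- g_topic + res$grad_topic
  }
  list(W_in = g_in, W_out = g_out, W_topic = g_topic)
}

model_negative <- function(model) {
  neg <- model$config$negative
  if (is.null(neg)) neg <- if (nrow(model$W_in) <= 5000L) 0L else 5L
  neg
}

new_embedding_model <- function(vocab, config, dict = NULL) {
  V <- nrow(vocab); d <- config$dim
  topics <- character()
  K <- 0L
  topic_of <- rep(NA_integer_, V)
  weight_of <- rep(NA_real_, V)
  if (!is.null(dict) && nrow(dict$entries)) {
    topics <- dict_topics(dict)
    K <- length(topics)
    topic_of <- dict_topic_index(dict, vocab$word)
    weight_of <- dict_weight(dict, vocab$word)
    if (config$include_background) {
      topics <- c(topics, ".background")
      topic_of[is.na(topic_of)] <- K + 1L
      weight_of[is.na(weight_of)] <- dict$default_weight
      K <- K + 1L
    }
  }
  W_in <- matrix(stats::runif(V * d, -0.5 / d, 0.5 / d), V, d)
  rownames(W_in) <- vocab$word
  noise <- vocab$count^0.75
  noise <- noise / sum(noise)
  structure(
    list(vocab = vocab, W_in = W_in, W_out = matrix(0, V, d),
         W_topic = if (K > 0) matrix(0, K, d) else NULL,
         topics = topics, topic_of = topic_of, weight_of = weight_of,
         noise = noise, config = config, trained = FALSE,
         loss_curve = tibble()),
    class = "tr_embedding"
  )
}

#' Train topic-enhanced Skip-gram word embeddings
#'
#' Slides a +/- `window` context window over every comment, and for each
#' comment takes one SGD step on the mean joint loss of its windows:
#' context prediction (`L_cont`) plus `lambda` times topic prediction
#' (`L_topic`) for centre words present in the topic dictionary, each
#' topic term scaled by the word's dictionary weight. With
#' `lambda = 0` (or no dictionary) this is plain Skip-gram; the
#' parameter trajectory is then identical to a baseline with no topic
#' task at all.
#'
#' The input matrix rows are the exported word vectors. Training is
#' deterministic given `config$seed` (identical seeds give bitwise
#' identical parameters and loss curves).
#'
#' @param comments Tibble with a `tokens` list-column, or a list of
#'   character token vectors.
#' @param dict Optional [topic_dictionary()] providing topic labels.
#' @param config A [training_config()].
#' @param vocab Optional prebuilt `tr_vocab`; built from `comments`
#'   (with `config$min_count`) when omitted.
#' @return A `tr_embedding` model: vocabulary, the three parameter
#'   matrices, per-epoch loss curve (`epoch`, `L_cont`, `L_topic`,
#'   `L_s`), and configuration.
#' @export
train_embeddings <- function(comments, dict = NULL, config = training_config(),
                             vocab = NULL) {
  tokens <- if (is.data.frame(comments)) comments$tokens else comments
  if (length(tokens) == 0L) abort("empty corpus")
  vocab <- vocab %||% build_vocab(tokens, min_count = config$min_count)
  model <- NULL
  V <- nrow(vocab)
  negative <- config$negative
  if (is.null(negative)) negative <- if (V <= 5000L) 0L else 5L
  if (negative > 0L && V < negative + 1L) {
    abort("vocabulary smaller than negative_samples + 1")
  }

  sequences <- map(tokens, function(tk) {
    idx <- match(tk, vocab$word)
    as.integer(idx[!is.na(idx)])
  })
  sequences <- sequences[lengths(sequences) > 0L]
  if (length(sequences) == 0L) abort("no in-vocabulary tokens to train on")

  prep <- map(sequences, function(s) {
    wp <- window_pairs(length(s), config$window)
    list(s = s, pos = wp$pos, ctx = s[wp$ctxpos])
  })

  withr::with_seed(config$seed, {
    model <- new_embedding_model(vocab, config, dict)
    W_in <- model$W_in; W_out <- model$W_out; W_topic <- model$W_topic
    topic_of <- model$topic_of; weight_of <- model$weight_of
    use_topic <- !is.null(W_topic) && config$lambda > 0
    curve <- vector("list", config$epochs)
    for (epoch in seq_len(config$epochs)) {
      lr <- max(config$learning_rate * (1 - (epoch - 1) / config$epochs),
                config$learning_rate * 0.01)
      tot_cont <- 0; tot_topic <- 0; tot_pairs <- 0; tot_lab <- 0
      for (pc in prep) {
        s <- pc$s
        res <- topics_core(
          centers = s, pos = pc$pos, ctx = pc$ctx,
          topic = if (use_topic) topic_of[s] else rep(NA_integer_, length(s)),
          tweight = if (use_topic) weight_of[s] else rep(NA_real_, length(s)),
          W_in = W_in, W_out = W_out,
          W_topic = if (use_topic) W_topic else NULL,
          lambda = config$lambda, negative = negative, noise = model$noise
        )
        if (res$n_pairs == 0L && res$n_labeled == 0L) next
        W_in[res$grad_in_rows, ] <- W_in[res$grad_in_rows, ] - lr * res$grad_in
        if (!is.null(res$grad_out)) {
          if (is.null(res$grad_out_rows)) W_out <- W_out - lr * res$grad_out
          else W_out[res$grad_out_rows, ] <- W_out[res$grad_out_rows, ] - lr * res$grad_out
        }
        if (!is.null(res$grad_topic)) W_topic <- W_topic - lr * res$grad_topic
        tot_cont <- tot_cont + res$L_cont * res$n_pairs
        tot_topic <- tot_topic + res$L_topic * res$n_labeled
        tot_pairs <- tot_pairs + res$n_pairs
        tot_lab <- tot_lab + res$n_labeled
      }
      e_cont <- if (tot_pairs > 0) tot_cont / tot_pairs else 0
      e_topic <- if (tot_lab > 0) tot_topic / tot_lab else 0
      curve[[epoch]] <- tibble(epoch = epoch, L_cont = e_cont, L_topic = e_topic,
                               L_s = e_cont + config$lambda * e_topic, lr = lr)
    }
    model$W_in <- W_in; model$W_out <- W_out; model$W_topic <- W_topic
    model$loss_curve <- bind_rows(curve)
    model$trained <- TRUE
  })
  model
}

#' Train a plain Skip-gram baseline
#'
#' Convenience wrapper: [train_embeddings()] without a topic dictionary
#' (equivalently, `lambda = 0`).
#'
#' @inheritParams train_embeddings
#' @export
train_skipgram <- function(comments, config = training_config(lambda = 0),
                           vocab = NULL) {
  config$lambda <- 0
  train_embeddings(comments, dict = NULL, config = config, vocab = vocab)
}

#' @export
print.tr_embedding <- function(x, ...) {
  cat(sprintf("<embedding model: |V| = %d, d = %d, lambda = %g, %s>\n",
              nrow(x$W_in), ncol(x$W_in), x$config$lambda %||% 0,
              if (isTRUE(x$trained)) "trained" else "untrained"))
  invisible(x)
}

#' Nearest vocabulary neighbours by cosine similarity
#'
#' Ranks all other vocabulary words by cosine similarity of their input
#' vectors to the query word's vector; ties are broken by vocabulary
#' index (rank order), making the ranking deterministic.
#'
#' @param model A `tr_embedding`.
#' @param word Query word (must be in the vocabulary).
#' @param topn Number of neighbours to return.
#' @return A tibble (`word`, `similarity`) in descending similarity.
#' @export
most_similar <- function(model, word, topn = 10L) {
  i <- match(word, rownames(model$W_in))
  if (is.na(i)) abort(sprintf("word '%s' is not in the vocabulary", word))
  sims <- cosine_to(model$W_in, model$W_in[i, ])
  sims[i] <- -Inf
  ord <- order(-sims, seq_along(sims))
  keep <- utils::head(ord, topn)
  tibble(word = rownames(model$W_in)[keep], similarity = sims[keep])
}

#' Export word vectors in word2vec text format
#'
#' Writes the standard header line `"V d"` followed by one
#' `word v1 ... vd` line per vocabulary word, in rank order.
#'
#' @param model A `tr_embedding`.
#' @param path Output file path.
#' @export
write_word2vec <- function(model, path) {
  W <- model$W_in
  header <- sprintf("%d %d", nrow(W), ncol(W))
  body <- vapply(seq_len(nrow(W)), function(i) {
    paste(rownames(W)[i], paste(sprintf("%.9g", W[i, ]), collapse = " "))
  }, character(1))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read word vectors from word2vec text format
#'
#' @param path Path to a word2vec text file (header `"V d"`).
#' @return A `tr_embedding` holding the vectors as its input matrix
#'   (sufficient for similarity queries, expansion and document
#'   vectors; it cannot be trained further).
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hd <- as.integer(strsplit(lines[[1]], " ", fixed = TRUE)[[1]])
  V <- hd[[1]]; d <- hd[[2]]
  parts <- strsplit(lines[-1], " ", fixed = TRUE)
  words <- vapply(parts, `[[`, character(1), 1L)
  W <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(d)))
  rownames(W) <- words
  vocab <- tibble(word = words, index = seq_len(V) - 1L, count = NA_integer_)
  structure(
    list(vocab = vocab, W_in = W, W_out = NULL, W_topic = NULL,
         topics = character(), config = list(dim = d), trained = TRUE,
         loss_curve = tibble()),
    class = "tr_embedding"
  )
}
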