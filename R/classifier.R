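#' Configuration for the convolutional risk-factor classifier
#'
#' A TextCNN: the comment is embedded as a `max_len` x `d` matrix, and
#' convolutional kernels of several widths (n-gram sizes) slide over
#' the token axis across the full vector width; ReLU activations are
#' globally max-pooled per filter, pooled features are concatenated,
#' and an affine layer with a 2-class softmax yields the probability
#' that the comment reports a risk factor.
#'
#' Defaults follow standard TextCNN practice: kernel widths 2/3/4 with
#' 64 filters each, dropout 0.5 on the pooled features, Adam at 1e-3,
#' 10 epochs, decision threshold 0.5 (lower it for recall-oriented
#' deployments).
#'
#' @param max_len Tokens kept per comment (longer comments truncated at
#'   the tail, shorter zero-padded).
#' @param kernel_sizes Integer vector of n-gram widths (each <=
#'   `max_len`).
#' @param filters_per_size Number of filters per kernel width.
#' @param dropout Dropout probability on pooled features in `[0, 1)`.
#' @param epochs,learning_rate,batch_size Adam training schedule.
#' @param decision_threshold Probability cut for flagging a comment.
#' @param seed RNG seed; training is deterministic given the seed.
#' @return An object of class `tr_classifier_config`.
#' @export
classifier_config <- function(max_len = 64L, kernel_sizes = c(2L, 3L, 4L),
                              filters_per_size = 64L, dropout = 0.5,
                              epochs = 10L, learning_rate = 1e-3,
                              batch_size = 32L, decision_threshold = 0.5,
                              seed = 1L) {
  if (any(kernel_sizes > max_len)) abort("kernel_sizes must not exceed max_len")
  if (dropout < 0 || dropout >= 1) abort("dropout must be in [0, 1)")
  if (decision_threshold <= 0 || decision_threshold > 1) {
    abort("decision_threshold must be in (0, 1]")
  }
  structure(
    list(max_len = as.integer(max_len), kernel_sizes = as.integer(kernel_sizes),
         filters_per_size = as.integer(filters_per_size), dropout = dropout,
         epochs = as.integer(epochs), learning_rate = learning_rate,
         batch_size = as.integer(batch_size),
         decision_threshold = decision_threshold, seed = as.integer(seed)),
    class = "tr_classifier_config"
  )
}

#' Embed a comment as a fixed-size matrix
#'
#' Row i is the embedding vector of token i. Sequences longer than
#' `max_len` are truncated at the tail; shorter ones are padded with
#' zero rows; out-of-vocabulary tokens map to a zero row, keeping the
#' classifier a pure consumer of the embedding.
#'
#' @param tokens Character vector of tokens (possibly empty).
#' @param model A trained `tr_embedding`.
#' @param cfg A [classifier_config()].
#' @return A `max_len` x `d` numeric matrix.
#' @export
vectorize_comment <- function(tokens, model, cfg) {
  if (!isTRUE(model$trained)) abort("embedding model must be trained")
  d <- ncol(model$W_in)
  X <- matrix(0, cfg$max_len, d)
  if (length(tokens)) {
    tokens <- utils::head(tokens, cfg$max_len)
    idx <- match(tokens, rownames(model$W_in))
    ok <- !is.na(idx)
    if (any(ok)) X[which(ok), ] <- model$W_in[idx[ok], , drop = FALSE]
  }
  X
}

# stack comments into a B x max_len x d array
vectorize_batch <- function(token_list, model, cfg) {
  d <- ncol(model$W_in)
  B <- length(token_list)
  A <- array(0, c(B, cfg$max_len, d))
  for (b in seq_len(B)) A[b, , ] <- vectorize_comment(token_list[[b]], model, cfg)
  A
}

init_cnn_params <- function(d, cfg) {
  ks <- cfg$kernel_sizes
  f <- cfg$filters_per_size
  kernels <- lapply(ks, function(k) {
    r <- sqrt(6 / (k * d + f))
    matrix(stats::runif(k * d * f, -r, r), k * d, f)
  })
  biases <- lapply(ks, function(k) numeric(f))
  f_tot <- f * length(ks)
  r2 <- sqrt(6 / (f_tot + 2))
  list(kernels = kernels, biases = biases,
       W = matrix(stats::runif(2 * f_tot, -r2, r2), 2, f_tot),
       b = numeric(2))
}

# forward pass over a batch array; returns probabilities and, when
# keep = TRUE, every intermediate needed for backprop
cnn_forward_batch <- function(A, params, cfg, dropmask = NULL, keep = FALSE) {
  B <- dim(A)[1]; L <- dim(A)[2]; d <- dim(A)[3]
  feats <- NULL
  cache <- list()
  for (ki in seq_along(cfg$kernel_sizes)) {
    k <- cfg$kernel_sizes[[ki]]
    P <- L - k + 1L
    Xc <- matrix(0, B * P, k * d)
    for (o in 0:(k - 1L)) {
      Xc[, (o * d + 1L):((o + 1L) * d)] <- matrix(A[, (1L + o):(P + o), , drop = FALSE], B * P, d)
    }
    Z <- Xc %*% params$kernels[[ki]]
    Z <- sweep(Z, 2L, params$biases[[ki]], "+")
    Zr <- pmax(Z, 0)
    f <- ncol(Z)
    pooled <- matrix(-Inf, B, f)
    amax <- matrix(1L, B, f)
    for (p in seq_len(P)) {
      rows <- (p - 1L) * B + seq_len(B)
      zp <- Zr[rows, , drop = FALSE]
      better <- zp > pooled
      pooled[better] <- zp[better]
      amax[better] <- p
    }
    feats <- cbind(feats, pooled)
    if (keep) cache[[ki]] <- list(Xc = Xc, Z = Z, amax = amax, P = P)
  }
  if (!is.null(dropmask)) feats_d <- feats * dropmask else feats_d <- feats
  logits <- feats_d %*% t(params$W)
  logits <- sweep(logits, 2L, params$b, "+")
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  out <- list(probs = probs, p1 = probs[, 2L])
  if (keep) {
    out$feats <- feats; out$feats_d <- feats_d; out$cache <- cache
  }
  out
}

#' Forward pass of the convolutional classifier
#'
#' @param X A `max_len` x `d` matrix from [vectorize_comment()].
#' @param params CNN parameters (from [train_classifier()] or
#'   hand-built with the same structure).
#' @param cfg The [classifier_config()] the parameters were built with.
#' @return `P(label = 1)`, a probability in `[0, 1]`.
#' @export
cnn_forward <- function(X, params, cfg) {
  d <- ncol(X)
  if (nrow(X) != cfg$max_len) abort("input matrix must have max_len rows")
  if (nrow(params$kernels[[1]]) != cfg$kernel_sizes[[1]] * d) {
    abort("input width does not match classifier parameters")
  }
  A <- array(0, c(1L, nrow(X), d))
  A[1, , ] <- X
  cnn_forward_batch(A, params, cfg)$p1
}

cnn_backward_batch <- function(A, y, params, cfg, dropmask = NULL) {
  fw <- cnn_forward_batch(A, params, cfg, dropmask = dropmask, keep = TRUE)
  B <- dim(A)[1]
  Y <- cbind(1 - y, y)
  dlogits <- (fw$probs - Y) / B
  loss <- -sum(log(pmax(fw$probs[cbind(seq_len(B), y + 1L)], 1e-12))) / B
  gW <- crossprod(dlogits, fw$feats_d)
  gb <- colSums(dlogits)
  dfeats <- dlogits %*% params$W
  if (!is.null(dropmask)) dfeats <- dfeats * dropmask
  f <- cfg$filters_per_size
  gk <- vector("list", length(cfg$kernel_sizes))
  gbias <- vector("list", length(cfg$kernel_sizes))
  for (ki in seq_along(cfg$kernel_sizes)) {
    cc <- fw$cache[[ki]]
    cols <- (ki - 1L) * f + seq_len(f)
    dpool <- dfeats[, cols, drop = FALSE]
    dZ <- matrix(0, B * cc$P, f)
    r_vec <- rep(seq_len(B), f) + (as.vector(cc$amax) - 1L) * B
    dZ[cbind(r_vec, rep(seq_len(f), each = B))] <- as.vector(dpool)
    dZ[cc$Z <= 0] <- 0
    gk[[ki]] <- crossprod(cc$Xc, dZ)
    gbias[[ki]] <- colSums(dZ)
  }
  list(loss = loss, grads = list(kernels = gk, biases = gbias, W = gW, b = gb))
}

adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^state$t)
    vhat <- v / (1 - beta2^state$t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      upd(p, g, m, v)
    }
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}

#' Train the convolutional risk-factor classifier
#'
#' Minimizes the 2-class cross-entropy with Adam over seeded
#' mini-batches; embedding rows are frozen (the embedding is trained
#' separately and consumed here). Dropout is applied to the pooled
#' feature vector during training only. Deterministic given
#' `cfg$seed`.
#'
#' @param data Tibble with `tokens` (list-column) and `label` (0/1);
#'   both classes must be present.
#' @param model A trained `tr_embedding`.
#' @param cfg A [classifier_config()].
#' @return An object of class `tr_textcnn`: parameters, config, the
#'   embedding dimension and a per-epoch training-loss tibble.
#' @export
train_classifier <- function(data, model, cfg = classifier_config()) {
  labels <- as.integer(data$label)
  if (any(is.na(labels))) abort("all training comments must be labelled")
  if (length(unique(labels)) < 2L) abort("training data must contain both classes")
  d <- ncol(model$W_in)
  A <- vectorize_batch(data$tokens, model, cfg)
  n <- length(labels)
  f_tot <- cfg$filters_per_size * length(cfg$kernel_sizes)
  curve <- vector("list", cfg$epochs)
  params <- NULL
  withr::with_seed(cfg$seed, {
    params <- init_cnn_params(d, cfg)
    opt <- adam_init(params)
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      tot <- 0; nb <- 0
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        Ab <- A[idx, , , drop = FALSE]
        mask <- NULL
        if (cfg$dropout > 0) {
          mask <- matrix(stats::rbinom(length(idx) * f_tot, 1L, 1 - cfg$dropout),
                         length(idx), f_tot) / (1 - cfg$dropout)
        }
        bw <- cnn_backward_batch(Ab, labels[idx], params, cfg, dropmask = mask)
        st <- adam_step(params, bw$grads, opt, cfg$learning_rate)
        params <- st$params
        opt <- st$state
        opt$t <- st$state$t
        tot <- tot + bw$loss; nb <- nb + 1
      }
      curve[[epoch]] <- tibble(epoch = epoch, loss = tot / nb)
    }
  })
  structure(list(params = params, config = cfg, dim = d,
                 loss_curve = bind_rows(curve)),
            class = "tr_textcnn")
}

#' @export
print.tr_textcnn <- function(x, ...) {
  cat(sprintf("<TextCNN classifier: kernels %s x %d filters, d = %d>\n",
              paste(x$config$kernel_sizes, collapse = "/"),
              x$config$filters_per_size, x$dim))
  invisible(x)
}

#' Predict risk-factor probabilities for comments
#'
#' @param object A `tr_textcnn` fit.
#' @param comments Tibble with a `tokens` list-column.
#' @param model The trained `tr_embedding` used at training time.
#' @param ... Unused.
#' @return The input tibble with a `.prob` column (`P(label = 1)`).
#' @export
predict.tr_textcnn <- function(object, comments, model, ...) {
  cfg <- object$config
  probs <- numeric(nrow(comments))
  bs <- 256L
  for (start in seq(1L, nrow(comments), by = bs)) {
    idx <- start:min(start + bs - 1L, nrow(comments))
    A <- vectorize_batch(comments$tokens[idx], model, cfg)
    probs[idx] <- cnn_forward_batch(A, object$params, cfg)$p1
  }
  comments$.prob <- probs
  comments
}

#' Build a metrics report from confusion counts
#'
#' @param tp,fp,fn,tn Confusion counts.
#' @return A one-row tibble of class `tr_metrics` with the counts and
#'   accuracy, precision, recall and F1 (harmonic mean); degenerate
#'   denominators yield `NaN`.
#' @export
metrics_report <- function(tp, fp, fn, tn) {
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  out <- tibble(
    TP = tp, FP = fp, FN = fn, TN = tn,
    accuracy = (tp + tn) / (tp + fp + fn + tn),
    precision = precision,
    recall = recall,
    f1 = 2 * precision * recall / (precision + recall)
  )
  class(out) <- c("tr_metrics", class(out))
  out
}

#' Evaluate a classifier on a labelled test set
#'
#' Thresholds predicted probabilities at the configured decision
#' threshold and derives accuracy, precision, recall and F1 from the
#' confusion counts.
#'
#' @param fit A `tr_textcnn`.
#' @param test Tibble with `tokens` and `label` columns (non-empty).
#' @param model The trained embedding model.
#' @return A `tr_metrics` one-row tibble.
#' @export
evaluate_classifier <- function(fit, test, model) {
  if (nrow(test) == 0L) abort("test set is empty")
  pred <- predict(fit, test, model)
  flag <- pred$.prob >= fit$config$decision_threshold
  y <- test$label == 1L
  metrics_report(tp = sum(flag & y), fp = sum(flag & !y),
                 fn = sum(!flag & y), tn = sum(!flag & !y))
}

#' Stratified k-fold cross-validation of the classifier
#'
#' Partitions the data into `folds` stratified subsets (class ratio
#' preserved within one item per fold), trains on k-1 folds and
#' evaluates on the held-out fold, once per fold. Shuffling is seeded
#' by `cfg$seed`.
#'
#' @param data Labelled tibble (`tokens`, `label`).
#' @param model Trained embedding model.
#' @param cfg A [classifier_config()].
#' @param folds Number of folds (>= 2; every class needs at least
#'   `folds` items).
#' @return A list with `folds` (per-fold `tr_metrics` rows, with a
#'   `fold` column) and `mean` (column means of the metric fractions).
#' @export
cross_validate <- function(data, model, cfg = classifier_config(), folds = 10L) {
  if (folds < 2L) abort("folds must be >= 2")
  labels <- as.integer(data$label)
  if (min(table(labels)) < folds) abort("each class needs at least `folds` items")
  n <- nrow(data)
  fold_id <- integer(n)
  withr::with_seed(derive_seed(cfg$seed, 101L), {
    for (lab in unique(labels)) {
      idx <- sample(which(labels == lab))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  reports <- vector("list", folds)
  for (f in seq_len(folds)) {
    fit <- train_classifier(data[fold_id != f, , drop = FALSE], model, cfg)
    rep_f <- evaluate_classifier(fit, data[fold_id == f, , drop = FALSE], model)
    rep_f$fold <- f
    reports[[f]] <- rep_f
  }
  per_fold <- bind_rows(reports)
  mean_report <- per_fold |>
    summarise(across(c("accuracy", "precision", "recall", "f1"), mean))
  list(folds = per_fold, mean = mean_report)
}

#' Flag risk-factor comments across a corpus
#'
#' Applies the trained classifier to every comment and returns those
#' whose probability reaches the decision threshold, annotated with the
#' probability.
#'
#' @param fit A `tr_textcnn`.
#' @param comments Preprocessed comment tibble (`tokens` list-column).
#' @param model Trained embedding model.
#' @param threshold Overrides the configured decision threshold.
#' @return The flagged subset of `comments` with a `.prob` column.
#' @export
predict_corpus <- function(fit, comments, model, threshold = NULL) {
  threshold <- threshold %||% fit$config$decision_threshold
  pred <- predict(fit, comments, model)
  pred[pred$.prob >= threshold, , drop = FALSE]
}
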