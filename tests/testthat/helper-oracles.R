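# Independent reference implementations used as oracles. These are written
# as explicit loops with no shared code with the package internals.

# plain Skip-gram trainer: full softmax, one batch-mean SGD step per
# comment, identical protocol and initialization to the package trainer
oracle_skipgram_train <- function(sequences, V, d, window, lr, n_steps, seed) {
  set.seed(seed)
  W_in <- matrix(stats::runif(V * d, -0.5 / d, 0.5 / d), V, d)
  W_out <- matrix(0, V, d)
  steps <- 0L
  for (s in sequences) {
    if (steps >= n_steps) break
    L <- length(s)
    pr_i <- integer(); pr_j <- integer()
    for (i in seq_len(L)) {
      for (j in seq_len(L)) {
        if (j != i && abs(j - i) <= window) {
          pr_i <- c(pr_i, i); pr_j <- c(pr_j, j)
        }
      }
    }
    if (length(pr_i) == 0L) next
    gin <- matrix(0, V, d)
    gout <- matrix(0, V, d)
    for (p in seq_along(pr_i)) {
      center <- s[pr_i[p]]
      target <- s[pr_j[p]]
      h <- W_in[center, ]
      scores <- numeric(V)
      for (v in seq_len(V)) scores[v] <- sum(W_out[v, ] * h)
      pvec <- exp(scores - max(scores))
      pvec <- pvec / sum(pvec)
      for (v in seq_len(V)) {
        coef <- pvec[v] - as.numeric(v == target)
        gout[v, ] <- gout[v, ] + coef * h
        gin[center, ] <- gin[center, ] + coef * W_out[v, ]
      }
    }
    W_in <- W_in - lr * gin / length(pr_i)
    W_out <- W_out - lr * gout / length(pr_i)
    steps <- steps + 1L
  }
  list(W_in = W_in, W_out = W_out, steps = steps)
}

# damped weighted-voting scores by long-run iteration to 1e-12
oracle_textrank_power <- function(nodes, edges, damping) {
  n <- length(nodes)
  S <- stats::setNames(rep(1, n), nodes)
  nbrs <- stats::setNames(vector("list", n), nodes)
  for (e in seq_len(nrow(edges))) {
    a <- edges$from[e]; b <- edges$to[e]; w <- edges$weight[e]
    nbrs[[a]] <- rbind(nbrs[[a]], data.frame(v = b, w = w))
    nbrs[[b]] <- rbind(nbrs[[b]], data.frame(v = a, w = w))
  }
  strength <- vapply(nbrs, function(x) if (is.null(x)) 0 else sum(x$w), numeric(1))
  for (iter in 1:10000) {
    S_new <- S
    for (u in nodes) {
      acc <- 0
      if (!is.null(nbrs[[u]])) {
        for (r in seq_len(nrow(nbrs[[u]]))) {
          v <- nbrs[[u]]$v[r]
          acc <- acc + nbrs[[u]]$w[r] / strength[[v]] * S[[v]]
        }
      }
      S_new[[u]] <- (1 - damping) + damping * acc
    }
    if (max(abs(S_new - S)) < 1e-12) return(S_new)
    S <- S_new
  }
  S
}

# brute-force co-occurrence counts over all position pairs
oracle_cooccurrence <- function(tokens, window_size) {
  keys <- character()
  L <- length(tokens)
  if (L >= 2L) {
    for (i in seq_len(L - 1L)) {
      for (j in (i + 1L):L) {
        if (j - i < window_size && tokens[i] != tokens[j]) {
          a <- min(tokens[i], tokens[j]); b <- max(tokens[i], tokens[j])
          keys <- c(keys, paste(a, b, sep = "\r"))
        }
      }
    }
  }
  table(keys)
}

# brute-force window enumeration: per center position, all context
# positions within distance c
oracle_windows <- function(idx, window) {
  lapply(seq_along(idx), function(i) {
    j <- setdiff(which(abs(seq_along(idx) - i) <= window), i)
    idx[j]
  })
}

# pair-counting adjusted Rand index
oracle_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sa <- a[i] == a[j]; sb <- b[i] == b[j]
      if (sa && sb) s11 <- s11 + 1
      else if (sa && !sb) s10 <- s10 + 1
      else if (!sa && sb) s01 <- s01 + 1
      else s00 <- s00 + 1
    }
  }
  num <- 2 * (s11 * s00 - s10 * s01)
  den <- (s11 + s10) * (s10 + s00) + (s11 + s01) * (s01 + s00)
  if (den == 0) 1 else num / den
}

# reference single-pass clustering: centroids recomputed from scratch at
# every step
oracle_single_pass <- function(M, theta) {
  cats <- list()
  assign <- integer(nrow(M))
  for (i in seq_len(nrow(M))) {
    best <- 0L; best_sim <- -Inf
    for (k in seq_along(cats)) {
      cen <- colMeans(M[cats[[k]], , drop = FALSE])
      sim <- sum(cen * M[i, ]) / (sqrt(sum(cen^2)) * sqrt(sum(M[i, ]^2)))
      if (sim > best_sim) { best_sim <- sim; best <- k }
    }
    if (best > 0L && best_sim >= theta) {
      cats[[best]] <- c(cats[[best]], i)
      assign[i] <- best
    } else {
      cats[[length(cats) + 1L]] <- i
      assign[i] <- length(cats)
    }
  }
  assign
}
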