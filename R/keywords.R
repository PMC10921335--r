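#' Build a word co-occurrence graph
#'
#' Nodes are the distinct words of a (stopword-filtered) token
#' sequence; an undirected edge connects two different words once per
#' pair of token positions lying strictly closer than `window_size`
#' apart, weighted by the number of such pairs. Self-loops are
#' excluded. Treat a whole clustering category as one document by
#' concatenating its comments' tokens.
#'
#' @param tokens Character vector of tokens.
#' @param window_size Co-occurrence window (positions `i < j` co-occur
#'   when `j - i < window_size`).
#' @return An object of class `tr_wordgraph`: `nodes` (character) and
#'   `edges` (tibble `from`, `to`, `weight` with `from < to`
#'   lexicographically).
#' @export
build_word_graph <- function(tokens, window_size = 5L) {
  if (window_size < 1L) abort("window_size must be >= 1")
  nodes <- sort(unique(tokens))
  L <- length(tokens)
  if (L < 2L || window_size < 2L) {
    return(structure(list(nodes = nodes,
                          edges = tibble(from = character(), to = character(),
                                         weight = numeric()),
                          window_size = window_size),
                     class = "tr_wordgraph"))
  }
  from <- character(); to <- character()
  for (off in seq_len(min(window_size - 1L, L - 1L))) {
    a <- tokens[seq_len(L - off)]
    b <- tokens[seq_len(L - off) + off]
    keep <- a != b
    from <- c(from, pmin(a[keep], b[keep]))
    to <- c(to, pmax(a[keep], b[keep]))
  }
  edges <- tibble(from = from, to = to) |>
    count(.data$from, .data$to, name = "weight") |>
    arrange(.data$from, .data$to)
  edges$weight <- as.numeric(edges$weight)
  structure(list(nodes = nodes, edges = edges, window_size = window_size),
            class = "tr_wordgraph")
}

#' TextRank scores over a word graph
#'
#' Iterates the damped weighted voting update
#' \deqn{S(u) = (1 - d) + d \sum_{v \in N(u)} \frac{w_{uv}}{\sum_{x \in N(v)} w_{vx}} S(v)}
#' from a uniform start until the maximum absolute change drops below
#' `tol` or `max_iter` is reached. Isolated nodes have an empty
#' neighbour sum and score exactly `1 - damping`. Frequent words of a
#' single document accumulate votes from their many co-occurrence
#' neighbours and rise to the top — the behaviour that makes TextRank
#' suitable for per-category keyword extraction.
#'
#' @param graph A `tr_wordgraph`.
#' @param damping Damping factor `d` in (0, 1); default 0.85.
#' @param tol Convergence tolerance on the max score change.
#' @param max_iter Iteration cap.
#' @return An object of class `tr_keyword_scores`: tibble (`word`,
#'   `score`) with attributes `iterations` and `converged`.
#' @export
textrank <- function(graph, damping = 0.85, tol = 1e-6, max_iter = 200L) {
  if (damping <= 0 || damping >= 1) abort("damping must be in (0, 1)")
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0L) abort("graph has no nodes")
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(graph$edges)) {
    i <- match(graph$edges$from, nodes)
    j <- match(graph$edges$to, nodes)
    W[cbind(i, j)] <- graph$edges$weight
    W[cbind(j, i)] <- graph$edges$weight
  }
  strength <- rowSums(W)
  inv_strength <- ifelse(strength > 0, 1 / strength, 0)
  S <- rep(1, n)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    S_new <- (1 - damping) + damping * as.vector(W %*% (S * inv_strength))
    if (max(abs(S_new - S)) < tol) {
      S <- S_new
      converged <- TRUE
      break
    }
    S <- S_new
  }
  out <- tibble(word = nodes, score = S)
  attr(out, "iterations") <- iter
  attr(out, "converged") <- converged
  attr(out, "damping") <- damping
  class(out) <- c("tr_keyword_scores", class(out))
  out
}

#' Top keywords of a category
#'
#' Runs TextRank over the co-occurrence graph of a category's
#' concatenated tokens and reports the top `n` words. Reported weights
#' are each word's share of the category's total score mass (so a
#' category's full weight vector sums to 1 and any top-n list sums to
#' less), the scale on which per-category keyword weights are usually
#' printed. Ties are broken lexicographically.
#'
#' @param category_tokens Character vector: all tokens of the category.
#' @param n Number of keywords (> 0).
#' @param window_size,damping,tol,max_iter Passed to
#'   [build_word_graph()] and [textrank()].
#' @return A tibble of class `tr_keywords`: `rank`, `word`, `weight`
#'   (normalized share), `score` (raw TextRank score).
#' @export
top_keywords <- function(category_tokens, n = 10L, window_size = 5L,
                         damping = 0.85, tol = 1e-6, max_iter = 200L) {
  if (n <= 0) abort("n must be positive")
  if (length(category_tokens) == 0L) abort("category has no tokens")
  graph <- build_word_graph(category_tokens, window_size)
  scores <- textrank(graph, damping = damping, tol = tol, max_iter = max_iter)
  scores$weight <- scores$score / sum(scores$score)
  out <- scores |>
    arrange(desc(.data$weight), .data$word) |>
    utils::head(n) |>
    mutate(rank = seq_len(dplyr::n())) |>
    select("rank", "word", "weight", "score")
  class(out) <- c("tr_keywords", setdiff(class(out), "tr_keyword_scores"))
  out
}

#' Export keyword weights for word-cloud rendering
#'
#' Writes a two-column UTF-8 TSV (`word`, `weight`, 6 decimal places)
#' that any word-cloud renderer can consume.
#'
#' @param scores A tibble with `word` and `weight` (or `score`)
#'   columns, e.g. from [top_keywords()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
wordcloud_export <- function(scores, path) {
  w <- if ("weight" %in% names(scores)) scores$weight else scores$score
  lines <- c("word\tweight",
             sprintf("%s\t%.6f", scores$word, w))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
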