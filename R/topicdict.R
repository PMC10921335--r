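#' Create an empty weighted topic dictionary
#'
#' A topic dictionary maps words to topics with positive weights. Words
#' belonging to the risk-factor topic carry a large weight
#' (`risk_weight`) so that the topic-prediction task of the embedding
#' model pays more attention to them; other topics get
#' `default_weight`. A word belongs to at most one topic.
#'
#' @param default_weight Weight for non-risk topic words (> 0).
#' @param risk_weight Weight for risk-factor topic words (> 0, and in
#'   any sensible configuration >= `default_weight`).
#' @return An object of class `tr_topicdict` with an `entries` tibble
#'   (`word`, `topic`, `weight`, `risk`).
#' @export
topic_dictionary <- function(default_weight = 1, risk_weight = 2) {
  if (default_weight <= 0 || risk_weight <= 0) abort("dictionary weights must be positive")
  structure(
    list(
      entries = tibble(word = character(), topic = character(),
                       weight = numeric(), risk = logical()),
      default_weight = default_weight,
      risk_weight = risk_weight
    ),
    class = "tr_topicdict"
  )
}

#' @export
print.tr_topicdict <- function(x, ...) {
  cat(sprintf("<topic dictionary: %d words, %d topics>\n",
              nrow(x$entries), dplyr::n_distinct(x$entries$topic)))
  if (nrow(x$entries)) {
    print(count(x$entries, .data$topic, wt = NULL, name = "words"))
  }
  invisible(x)
}

#' Collapse tokenized phrases into a seed word set
#'
#' The deduplicated union of all tokens across a collection of
#' risk-factor phrases (typically extracted manually from annotated
#' comments, or supplied by the synthetic generator).
#'
#' @param phrases A list of character vectors (tokenized phrases);
#'   nested lists are flattened.
#' @return A character vector of unique seed words (warns when empty).
#' @export
seeds_from_phrases <- function(phrases) {
  words <- unique(unlist(phrases, use.names = FALSE))
  words <- words[!is.na(words) & nzchar(words)]
  if (length(words) == 0L) warn("no seed words extracted from phrases")
  words
}

#' Assign words to a topic with weights
#'
#' Maps every word in `words` to `topic_id` at the dictionary's risk or
#' default weight. A word already mapped (to any topic) is reassigned
#' only if the new weight is strictly larger, so risk-topic membership
#' is never silently downgraded and no word ever belongs to two topics.
#'
#' @param dict A [topic_dictionary()].
#' @param words Non-empty character vector.
#' @param topic_id Topic identifier (string).
#' @param risk Whether these are risk-factor topic words (large weight).
#' @return The updated dictionary.
#' @export
assign_weights <- function(dict, words, topic_id, risk = TRUE) {
  stopifnot(inherits(dict, "tr_topicdict"))
  words <- unique(words)
  if (length(words) == 0L) abort("words must be non-empty")
  weight <- if (risk) dict$risk_weight else dict$default_weight
  existing <- match(words, dict$entries$word)
  new <- is.na(existing)
  upgrade <- !new & dict$entries$weight[existing] < weight
  if (any(upgrade)) {
    rows <- existing[upgrade]
    dict$entries$topic[rows] <- topic_id
    dict$entries$weight[rows] <- weight
    dict$entries$risk[rows] <- risk
  }
  if (any(new)) {
    dict$entries <- bind_rows(
      dict$entries,
      tibble(word = words[new], topic = topic_id, weight = weight, risk = risk)
    )
  }
  dict
}

#' Look up a word's topic membership
#'
#' @param dict A [topic_dictionary()].
#' @param word A single word.
#' @return A list `(topic, weight)` or `NULL` when the word is absent.
#' @export
lookup_topic <- function(dict, word) {
  i <- match(word, dict$entries$word)
  if (is.na(i)) return(NULL)
  list(topic = dict$entries$topic[[i]], weight = dict$entries$weight[[i]])
}

# vectorized internals used by the embedding trainer
dict_topics <- function(dict) sort(unique(dict$entries$topic))

dict_topic_index <- function(dict, words) {
  topics <- dict_topics(dict)
  i <- match(words, dict$entries$word)
  match(dict$entries$topic[i], topics)
}

dict_weight <- function(dict, words) {
  i <- match(words, dict$entries$word)
  dict$entries$weight[i]
}

#' Expand a topic word set through embedding neighbours
#'
#' The semi-automated dictionary-building loop: starting from seed
#' words, each iteration adds, for every current member, its `topn`
#' nearest vocabulary neighbours by cosine similarity over the trained
#' word vectors (optionally cut below `similarity_floor`). Iteration
#' stops after `iterations` rounds or at a fixed point, whichever comes
#' first; the result is deterministic given the model and
#' configuration and always a superset of the (in-vocabulary) seeds.
#'
#' @param seeds Character vector of seed words; out-of-vocabulary seeds
#'   are skipped with a warning.
#' @param model A trained embedding model (see [train_embeddings()]).
#' @param topn Neighbours added per member per iteration (>= 0).
#' @param iterations Maximum expansion rounds (>= 0).
#' @param similarity_floor Minimum cosine for a neighbour to be added;
#'   default -1 (pure top-n rule, no cut).
#' @return Character vector: the expanded topic word set, in insertion
#'   order (seeds first).
#' @export
expand_topic <- function(seeds, model, topn = 5L, iterations = 3L,
                         similarity_floor = -1) {
  stopifnot(inherits(model, "tr_embedding"))
  if (!isTRUE(model$trained)) abort("model must be trained before expansion")
  if (topn < 0 || iterations < 0) abort("topn and iterations must be >= 0")
  in_vocab <- seeds %in% model$vocab$word
  if (any(!in_vocab)) {
    warn(sprintf("skipping %d out-of-vocabulary seed(s): %s",
                 sum(!in_vocab), paste(utils::head(seeds[!in_vocab], 5), collapse = ", ")))
  }
  current <- unique(seeds[in_vocab])
  if (topn == 0L || iterations == 0L || length(current) == 0L) return(current)
  for (iter in seq_len(iterations)) {
    added <- character()
    frontier <- current
    for (w in frontier) {
      nb <- most_similar(model, w, topn = topn)
      nb <- nb[nb$similarity >= similarity_floor, , drop = FALSE]
      new <- setdiff(nb$word, c(current, added))
      added <- c(added, new)
    }
    if (length(added) == 0L) break
    current <- c(current, added)
  }
  current
}
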