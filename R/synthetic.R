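#' Configuration for the planted-topic corpus generator
#'
#' Describes a synthetic short-comment corpus with the statistical
#' structure the mining pipeline assumes: a small number of planted
#' risk-factor topics with dedicated vocabularies, a Zipfian background
#' vocabulary, a controllable fraction of risk-labelled comments whose
#' tokens come from their topic with probability `topic_purity`, and a
#' fraction of ultrashort (< 3 token) noise comments.
#'
#' Defaults state the testing world used throughout the package: two
#' planted topics of 50 words over a 200-word background, 2000 comments
#' of 5–15 tokens, balanced labels, purity 0.9, 5% ultrashort noise and
#' a Zipf exponent of 1.1 (top-ranked background words dominate corpus
#' coverage, as in real short-comment corpora).
#'
#' @param n_topics Number of planted risk-factor topics.
#' @param words_per_topic Vocabulary size of each planted topic.
#' @param background_vocab_size Background vocabulary size.
#' @param n_comments Number of comments to generate.
#' @param length_min,length_max Token-count range (uniform) for normal
#'   comments.
#' @param risk_fraction Fraction of comments labelled 1 (risk factor
#'   present); allocated exactly.
#' @param topic_purity Probability that a token of a risk comment is
#'   drawn from its topic's vocabulary rather than the background.
#' @param ultrashort_fraction Fraction of comments truncated to 1–2
#'   tokens, emulating "Thank you!"-class noise.
#' @param zipf_exponent Exponent of the background Zipf distribution.
#' @param seed Mandatory RNG seed; every draw is reproducible per seed.
#' @return An object of class `tr_generator_config`.
#' @export
generator_config <- function(n_topics = 2L,
                             words_per_topic = 50L,
                             background_vocab_size = 200L,
                             n_comments = 2000L,
                             length_min = 5L,
                             length_max = 15L,
                             risk_fraction = 0.5,
                             topic_purity = 0.9,
                             ultrashort_fraction = 0.05,
                             zipf_exponent = 1.1,
                             seed = 1L) {
  if (is.null(seed) || is.na(seed)) abort("seed is mandatory")
  if (risk_fraction < 0 || risk_fraction > 1) abort("risk_fraction must be in [0,1]")
  if (topic_purity < 0 || topic_purity > 1) abort("topic_purity must be in [0,1]")
  if (ultrashort_fraction < 0 || ultrashort_fraction > 1) abort("ultrashort_fraction must be in [0,1]")
  if (length_min < 1 || length_max < length_min) abort("invalid comment length range")
  if (n_topics < 1 || words_per_topic < 1 || background_vocab_size < 1) {
    abort("topic and vocabulary sizes must be positive")
  }
  structure(
    list(
      n_topics = as.integer(n_topics),
      words_per_topic = as.integer(words_per_topic),
      background_vocab_size = as.integer(background_vocab_size),
      n_comments = as.integer(n_comments),
      length_min = as.integer(length_min),
      length_max = as.integer(length_max),
      risk_fraction = risk_fraction,
      topic_purity = topic_purity,
      ultrashort_fraction = ultrashort_fraction,
      zipf_exponent = zipf_exponent,
      seed = as.integer(seed)
    ),
    class = "tr_generator_config"
  )
}

topic_word_names <- function(cfg) {
  lapply(seq_len(cfg$n_topics), function(t) {
    sprintf("topic%d_w%02d", t, seq_len(cfg$words_per_topic))
  })
}

background_word_names <- function(cfg) {
  sprintf("bg_w%03d", seq_len(cfg$background_vocab_size))
}

#' Generate a planted-topic synthetic corpus
#'
#' Risk comments (label 1) are assigned one of the planted topics and
#' draw each token from that topic's vocabulary with probability
#' `topic_purity`, otherwise from the Zipfian background; background
#' comments (label 0) draw from the background only. Exactly
#' `round(n_comments * risk_fraction)` comments are labelled 1, and
#' `floor(n_comments * ultrashort_fraction)` comments are truncated to
#' 1–2 tokens. Identical seeds yield identical corpora.
#'
#' @param cfg A [generator_config()].
#' @return A list with
#'   * `comments`: tibble (`comment_id`, `post_id`, `text`, `tokens`,
#'     `label`) ready for the pipeline (tokens are also joined into
#'     `text` so the preprocessing module can be exercised on them),
#'   * `truth`: tibble (`comment_id`, `label`, `topic`) with the
#'     planted topic (`NA` for background comments),
#'   * `dictionary`: the ground-truth [topic_dictionary()] mapping every
#'     planted topic word to its topic at the risk weight.
#' @export
generate_corpus <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "tr_generator_config"))
  topics <- topic_word_names(cfg)
  bg <- background_word_names(cfg)
  bg_prob <- seq_len(cfg$background_vocab_size)^(-cfg$zipf_exponent)
  bg_prob <- bg_prob / sum(bg_prob)

  n <- cfg$n_comments
  n_risk <- as.integer(round(n * cfg$risk_fraction))
  n_ultra <- as.integer(floor(n * cfg$ultrashort_fraction))

  withr::with_seed(cfg$seed, {
    label <- integer(n)
    label[sample.int(n, n_risk)] <- 1L
    topic <- rep(NA_integer_, n)
    topic[label == 1L] <- sample(rep_len(seq_len(cfg$n_topics), n_risk))
    len <- sample(cfg$length_min:cfg$length_max, n, replace = TRUE)
    ultra <- sample.int(n, n_ultra)
    len[ultra] <- sample(1:2, n_ultra, replace = TRUE)
    tokens <- vector("list", n)
    for (i in seq_len(n)) {
      if (label[i] == 1L) {
        from_topic <- stats::runif(len[i]) < cfg$topic_purity
        tok <- character(len[i])
        n_t <- sum(from_topic)
        if (n_t > 0) tok[from_topic] <- sample(topics[[topic[i]]], n_t, replace = TRUE)
        if (n_t < len[i]) tok[!from_topic] <- sample(bg, len[i] - n_t, replace = TRUE, prob = bg_prob)
      } else {
        tok <- sample(bg, len[i], replace = TRUE, prob = bg_prob)
      }
      tokens[[i]] <- tok
    }
  })

  dict <- topic_dictionary()
  for (t in seq_len(cfg$n_topics)) {
    dict <- assign_weights(dict, topics[[t]], topic_id = sprintf("topic%d", t), risk = TRUE)
  }

  comments <- tibble(
    comment_id = sprintf("c%05d", seq_len(n)),
    post_id = sprintf("p%04d", ((seq_len(n) - 1L) %/% 4L) + 1L),
    text = map_chr(tokens, paste, collapse = " "),
    tokens = tokens,
    label = label
  )
  truth <- tibble(
    comment_id = comments$comment_id,
    label = label,
    topic = ifelse(is.na(topic), NA_character_, sprintf("topic%d", topic))
  )
  list(comments = comments, truth = truth, dictionary = dict)
}

#' Generate a labelled training/test set
#'
#' Stands in for the manually annotated subset of a real corpus: a
#' planted-topic corpus with an exactly configured class split and a
#' stratified 90/10 train/test division (disjoint by construction).
#'
#' @param cfg A [generator_config()]; `n_comments` and `risk_fraction`
#'   control the class counts (e.g. `n_comments = 2000`,
#'   `risk_fraction = 996/2000` emulates a 996:1004 annotation).
#' @param test_fraction Held-out fraction (default 0.1).
#' @return The [generate_corpus()] list whose `comments` tibble gains a
#'   `split` column (`"train"`/`"test"`, stratified by label).
#' @export
generate_labeled_set <- function(cfg = generator_config(n_comments = 400L,
                                                        ultrashort_fraction = 0),
                                 test_fraction = 0.1) {
  out <- generate_corpus(cfg)
  comments <- out$comments
  split <- rep("train", nrow(comments))
  withr::with_seed(derive_seed(cfg$seed, 17L), {
    for (lab in unique(comments$label)) {
      idx <- which(comments$label == lab)
      n_test <- round(length(idx) * test_fraction)
      if (n_test > 0) split[sample(idx, n_test)] <- "test"
    }
  })
  out$comments$split <- split
  out
}

#' Draw seed phrases from the planted topic vocabulary
#'
#' Stands in for manual extraction of risk-factor phrases from
#' annotated comments: samples `k_per_topic` true topic words per
#' planted topic, without replacement.
#'
#' @param cfg The [generator_config()] the corpus was generated with.
#' @param k_per_topic Number of seed words per topic (0 allowed).
#' @return A named list, one element per topic, each a list of
#'   single-token phrases (character vectors) suitable for
#'   [seeds_from_phrases()].
#' @export
generate_seed_phrases <- function(cfg, k_per_topic = 5L) {
  if (k_per_topic > cfg$words_per_topic) {
    abort("k_per_topic exceeds the planted topic vocabulary size")
  }
  topics <- topic_word_names(cfg)
  withr::with_seed(derive_seed(cfg$seed, 29L), {
    out <- lapply(topics, function(w) {
      picked <- if (k_per_topic > 0) sample(w, k_per_topic) else character()
      lapply(picked, identity)
    })
  })
  names(out) <- sprintf("topic%d", seq_len(cfg$n_topics))
  out
}
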