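#' Cleaning and segmentation configuration
#'
#' Bundles every rule applied between a raw comment and its token
#' sequence: regex-based scrubbing (URLs, e-mail addresses, symbol
#' noise such as emoticons), a user dictionary of specialised terms
#' that must survive segmentation as single tokens, a stopword list,
#' and the ultrashort-comment threshold.
#'
#' The symbol rule is a conservative whitelist: any character that is
#' not a letter, digit, CJK character, whitespace or basic punctuation
#' is replaced by a space. The ultrashort threshold defaults to 3
#' tokens, which drops "Thank you!"-class noise while keeping short
#' symptom reports; both it and the lists are fully configurable.
#'
#' @param stopwords Character vector of stopwords removed after
#'   segmentation.
#' @param user_dictionary Character vector of multi-word or domain
#'   terms emitted as single tokens (e.g. drug names, allergen
#'   phrases). Entries must be non-empty.
#' @param min_tokens Minimum token count for a comment to be kept by
#'   [filter_ultrashort()]. Must be >= 1.
#' @param url_pattern,email_pattern,symbol_pattern Regexes (ICU) for the
#'   three scrubbing passes; the defaults implement the rules above.
#' @return An object of class `tr_cleaning_config`.
#' @seealso [clean_text()], [segment_text()], [tokenize_comments()]
#' @export
cleaning_config <- function(stopwords = character(),
                            user_dictionary = character(),
                            min_tokens = 3L,
                            url_pattern = "(?i)\\b(?:https?://|www\\.)[^\\s]+",
                            email_pattern = "[[:alnum:]._%+-]+@[[:alnum:]-]+(?:\\.[[:alnum:]-]+)+",
                            symbol_pattern = "[^\\p{L}\\p{N}_\\s.,!?;:'\"()\\-]") {
  if (any(!nzchar(user_dictionary))) abort("user_dictionary entries must be non-empty strings")
  if (min_tokens < 1) abort("min_tokens must be >= 1")
  structure(
    list(
      stopwords = unique(stopwords),
      user_dictionary = unique(user_dictionary),
      min_tokens = as.integer(min_tokens),
      url_pattern = url_pattern,
      email_pattern = email_pattern,
      symbol_pattern = symbol_pattern
    ),
    class = "tr_cleaning_config"
  )
}

#' Scrub raw comment text
#'
#' Removes URLs, e-mail addresses and symbol noise (emoticons and any
#' other character outside the whitelist), then collapses runs of
#' whitespace. The operation is idempotent and never mutates its input;
#' the cleaned string is a new value.
#'
#' @param text Character vector of raw comment text.
#' @param cfg A [cleaning_config()].
#' @return Character vector of cleaned text, same length as `text`.
#' @examples
#' cfg <- cleaning_config()
#' clean_text("pollen bad, see https://a.b/c today", cfg)
#' @export
clean_text <- function(text, cfg = cleaning_config()) {
  out <- stringr::str_replace_all(text, cfg$url_pattern, " ")
  out <- stringr::str_replace_all(out, cfg$email_pattern, " ")
  out <- stringr::str_replace_all(out, cfg$symbol_pattern, " ")
  out <- stringr::str_squish(out)
  out
}

#' Segment cleaned text into tokens
#'
#' Whitespace/punctuation segmentation with user-dictionary
#' protection: every dictionary term occurring verbatim in the text is
#' emitted as a single token, even when it spans whitespace ("dust
#' mites") — the stand-in for a dictionary-aware Chinese segmenter on
#' Latin-script corpora. Longer dictionary entries take precedence over
#' shorter ones. Punctuation and whitespace act as separators.
#'
#' @param text A single cleaned string.
#' @param cfg A [cleaning_config()] supplying the user dictionary.
#' @return Character vector of tokens (empty for empty input).
#' @examples
#' cfg <- cleaning_config(user_dictionary = "dust mites")
#' segment_text("dust mites in spring", cfg)
#' @export
segment_text <- function(text, cfg = cleaning_config()) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character())
  dict <- cfg$user_dictionary
  protected <- text
  if (length(dict)) {
    dict <- dict[order(-nchar(dict))]
    for (i in seq_along(dict)) {
      protected <- gsub(dict[[i]], sprintf("▁%d▁", i), protected, fixed = TRUE)
    }
  }
  toks <- stringr::str_split_1(protected, "[^\\p{L}\\p{N}_▁]+")
  toks <- toks[nzchar(toks)]
  if (length(dict)) {
    ph <- sprintf("▁%d▁", seq_along(dict))
    hit <- match(toks, ph)
    toks[!is.na(hit)] <- dict[hit[!is.na(hit)]]
  }
  toks
}

#' Remove stopwords from a token sequence
#'
#' @param tokens Character vector of tokens.
#' @param cfg A [cleaning_config()] supplying the stopword list.
#' @return `tokens` minus every stopword occurrence, order preserved.
#' @export
remove_stopwords <- function(tokens, cfg) {
  tokens[!tokens %in% cfg$stopwords]
}

#' Clean, segment and de-stopword a comment table
#'
#' Runs the whole preprocessing pipeline over a tibble of comments:
#' [clean_text()], [segment_text()], [remove_stopwords()]. The raw
#' `text` column is preserved unchanged; results land in new `clean`
#' and `tokens` columns.
#'
#' @param comments Tibble with at least a `text` column; a `comment_id`
#'   column is added (row number) when absent.
#' @param cfg A [cleaning_config()].
#' @return The input tibble with `clean` (character) and `tokens`
#'   (list of character vectors) columns.
#' @export
tokenize_comments <- function(comments, cfg = cleaning_config()) {
  comments <- as_tibble(comments)
  if (!"comment_id" %in% names(comments)) {
    comments$comment_id <- sprintf("c%05d", seq_len(nrow(comments)))
  }
  comments$clean <- clean_text(comments$text, cfg)
  comments$tokens <- map(comments$clean, function(x) {
    remove_stopwords(segment_text(x, cfg), cfg)
  })
  comments
}

#' Split off ultrashort comments
#'
#' Token-poor comments ("Thank you!") carry no analysable content and
#' are filtered before any downstream modelling. A comment is kept when
#' it has at least `cfg$min_tokens` tokens.
#'
#' @param comments Tibble with a `tokens` list-column (see
#'   [tokenize_comments()]).
#' @param cfg A [cleaning_config()].
#' @return A list with tibbles `kept` and `dropped`; together they
#'   partition the input.
#' @export
filter_ultrashort <- function(comments, cfg = cleaning_config()) {
  stopifnot("tokens" %in% names(comments))
  n_tok <- lengths(comments$tokens)
  keep <- n_tok >= cfg$min_tokens
  list(kept = comments[keep, , drop = FALSE], dropped = comments[!keep, , drop = FALSE])
}

#' Build a ranked vocabulary from tokenized comments
#'
#' Counts every token across the corpus and ranks words by frequency
#' (ties broken lexicographically, making the ranking — and coverage
#' statistics computed from it — deterministic). Indices are contiguous
#' from 0 in rank order, matching the word2vec text-format convention.
#'
#' @param comments Tibble with a `tokens` list-column, or a list of
#'   character token vectors.
#' @param min_count Minimum corpus frequency for a word to enter the
#'   vocabulary (default 1: no pruning).
#' @return A tibble of class `tr_vocab` with columns `word`, `index`
#'   (0-based), `count`, carrying attribute `total_token_count`.
#' @export
build_vocab <- function(comments, min_count = 1L) {
  tokens <- if (is.data.frame(comments)) comments$tokens else comments
  all_tok <- unlist(tokens, use.names = FALSE)
  if (length(all_tok) == 0L) abort("empty corpus: no tokens to build a vocabulary from")
  tab <- table(all_tok)
  vocab <- tibble(word = names(tab), count = as.integer(tab)) |>
    filter(.data$count >= min_count) |>
    arrange(desc(.data$count), .data$word) |>
    mutate(index = seq_len(dplyr::n()) - 1L) |>
    select("word", "index", "count")
  if (nrow(vocab) == 0L) abort("min_count pruned every word: no trainable vocabulary")
  attr(vocab, "total_token_count") <- sum(vocab$count)
  class(vocab) <- c("tr_vocab", class(vocab))
  vocab
}

#' Fraction of corpus tokens covered by the top-ranked words
#'
#' The cumulative frequency share of the `top_k` highest-ranked
#' vocabulary words — the statistic used to judge whether a compact
#' embedding vocabulary suffices for a corpus (e.g. a heavily skewed
#' corpus where the top 10,000 words cover ~95% of tokens).
#'
#' @param vocab A `tr_vocab` from [build_vocab()].
#' @param top_k Number of top-ranked words (>= 0).
#' @return A fraction in \[0, 1\]; exactly 1 when `top_k >= nrow(vocab)`.
#' @export
coverage_fraction <- function(vocab, top_k) {
  if (top_k < 0) abort("top_k must be non-negative")
  total <- attr(vocab, "total_token_count")
  k <- min(top_k, nrow(vocab))
  if (k == 0L) return(0)
  sum(vocab$count[seq_len(k)]) / total
}
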