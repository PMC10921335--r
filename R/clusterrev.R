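#' Document vectors for clustering
#'
#' Represents each comment as the unweighted mean of its in-vocabulary
#' token embeddings. Comments whose tokens are all out of vocabulary
#' (or whose vectors cancel to zero norm) cannot be placed on the
#' cosine sphere; they are quarantined and never clustered, and are
#' reported separately.
#'
#' @param comments Tibble with `comment_id` and `tokens` columns.
#' @param model A trained `tr_embedding`.
#' @return A list with `vectors` (matrix, one row per usable comment,
#'   rownames = comment ids) and `quarantined` (character ids).
#' @export
doc_vectors <- function(comments, model) {
  d <- ncol(model$W_in)
  n <- nrow(comments)
  M <- matrix(0, n, d)
  for (i in seq_len(n)) {
    idx <- match(comments$tokens[[i]], rownames(model$W_in))
    idx <- idx[!is.na(idx)]
    if (length(idx)) M[i, ] <- colMeans(model$W_in[idx, , drop = FALSE])
  }
  rownames(M) <- comments$comment_id
  norms <- sqrt(rowSums(M^2))
  keep <- norms > 0
  list(vectors = M[keep, , drop = FALSE],
       quarantined = comments$comment_id[!keep])
}

new_cluster_set <- function(vectors, threshold, assignments, review_log = NULL,
                            quarantined = character()) {
  structure(
    list(vectors = vectors, threshold = threshold, assignments = assignments,
         review_log = review_log %||%
           tibble(step = character(), comment_id = character(),
                  from = integer(), to = integer(), similarity = numeric()),
         quarantined = quarantined),
    class = "tr_clusters"
  )
}

cluster_centroids <- function(clusters) {
  asg <- clusters$assignments
  cats <- sort(unique(asg$category))
  C <- t(vapply(cats, function(cid) {
    colMeans(clusters$vectors[asg$comment_id[asg$category == cid], , drop = FALSE])
  }, numeric(ncol(clusters$vectors))))
  rownames(C) <- cats
  C
}

#' @export
print.tr_clusters <- function(x, ...) {
  sizes <- table(x$assignments$category)
  cat(sprintf("<cluster set: %d documents in %d categories (theta = %g, %d singletons, %d quarantined)>\n",
              nrow(x$assignments), length(sizes), x$threshold,
              sum(sizes == 1L), length(x$quarantined)))
  invisible(x)
}

#' Single-pass incremental clustering
#'
#' Processes documents in input order. Each document joins the existing
#' category whose centroid it is most cosine-similar to, provided that
#' similarity reaches the threshold `theta`; otherwise it founds a new
#' category. Centroids are updated incrementally (mean of members).
#' The number of clusters is never fixed in advance; the result is
#' deterministic for a fixed input order — and genuinely
#' order-sensitive, which is what the review pass mitigates.
#'
#' @param docs A [doc_vectors()] result (or a plain matrix with rownames
#'   as document ids).
#' @param theta Similarity threshold in (0, 1).
#' @return An object of class `tr_clusters`.
#' @export
single_pass <- function(docs, theta = 0.5) {
  if (theta <= 0 || theta >= 1) abort("theta must be in (0, 1)")
  if (is.list(docs) && !is.matrix(docs)) {
    M <- docs$vectors; quarantined <- docs$quarantined
  } else {
    M <- docs; quarantined <- character()
  }
  n <- nrow(M)
  if (n == 0L) {
    return(new_cluster_set(M, theta,
                           tibble(comment_id = character(), category = integer()),
                           quarantined = quarantined))
  }
  d <- ncol(M)
  cent_sum <- matrix(0, 0, d)   # running sums; centroid = sum / size
  sizes <- integer()
  category <- integer(n)
  for (i in seq_len(n)) {
    v <- M[i, ]
    if (nrow(cent_sum) > 0L) {
      cents <- cent_sum / sizes
      sims <- cosine_to(cents, v)
      best <- which.max(sims)
      if (sims[best] >= theta) {
        category[i] <- best
        cent_sum[best, ] <- cent_sum[best, ] + v
        sizes[best] <- sizes[best] + 1L
        next
      }
    }
    cent_sum <- rbind(cent_sum, v)
    sizes <- c(sizes, 1L)
    category[i] <- nrow(cent_sum)
  }
  new_cluster_set(M, theta,
                  tibble(comment_id = rownames(M), category = category),
                  quarantined = quarantined)
}

#' Automatic review of singleton categories
#'
#' After the single pass, documents that arrived early can end up alone
#' in a category because the centroid they should have joined had not
#' yet drifted toward them. The review pass re-traverses every
#' singleton category once: its document is re-scored against all
#' non-singleton centroids and merged into the best one when the cosine
#' reaches the threshold. Merges are logged; merged singletons are not
#' revisited, so the sweep terminates after one traversal and never
#' increases the category or singleton count.
#'
#' @param clusters A `tr_clusters` from [single_pass()].
#' @return The reviewed `tr_clusters`; category ids keep their founding
#'   numbers (absorbed singleton ids simply disappear) and
#'   `review_log` records each merge.
#' @export
review_pass <- function(clusters) {
  asg <- clusters$assignments
  sizes <- table(asg$category)
  singletons <- as.integer(names(sizes)[sizes == 1L])
  non_single <- as.integer(names(sizes)[sizes > 1L])
  if (length(singletons) == 0L || length(non_single) == 0L) return(clusters)
  M <- clusters$vectors
  cent <- cluster_centroids(clusters)
  log <- clusters$review_log
  for (cid in singletons) {
    doc_id <- asg$comment_id[asg$category == cid]
    v <- M[doc_id, ]
    cand <- as.character(non_single)
    sims <- cosine_to(cent[cand, , drop = FALSE], v)
    best <- which.max(sims)
    if (sims[best] >= clusters$threshold) {
      target <- non_single[best]
      asg$category[asg$comment_id == doc_id] <- target
      members <- asg$comment_id[asg$category == target]
      cent[as.character(target), ] <- colMeans(M[members, , drop = FALSE])
      log <- bind_rows(log, tibble(step = "auto_review", comment_id = doc_id,
                                   from = cid, to = target,
                                   similarity = sims[best]))
    }
  }
  new_cluster_set(M, clusters$threshold, asg, review_log = log,
                  quarantined = clusters$quarantined)
}

#' Manual-review report for a cluster set
#'
#' Summarises every category for a human reviewer: size, the most
#' central member texts (highest cosine to the centroid), and — when an
#' embedding model is supplied — the vocabulary words nearest the
#' centroid as quick keywords. The human decision itself is consumed by
#' [apply_review_decisions()].
#'
#' @param clusters A `tr_clusters`.
#' @param comments Comment tibble with `comment_id` and `text` (or
#'   `tokens`).
#' @param top_examples Number of example texts per category.
#' @param model Optional `tr_embedding` for centroid-nearest keywords.
#' @return A tibble of class `tr_review_report`: `category`, `size`,
#'   `examples` (list of texts, most central first), `keywords` (list).
#' @export
review_report <- function(clusters, comments, top_examples = 3L, model = NULL) {
  asg <- clusters$assignments
  if (nrow(asg) == 0L) {
    out <- tibble(category = integer(), size = integer(),
                  examples = list(), keywords = list())
    class(out) <- c("tr_review_report", class(out))
    return(out)
  }
  M <- clusters$vectors
  text_of <- if ("text" %in% names(comments)) {
    stats::setNames(comments$text, comments$comment_id)
  } else {
    stats::setNames(map_chr(comments$tokens, paste, collapse = " "),
                    comments$comment_id)
  }
  cent <- cluster_centroids(clusters)
  cats <- sort(unique(asg$category))
  rows <- map(cats, function(cid) {
    ids <- asg$comment_id[asg$category == cid]
    sims <- cosine_to(M[ids, , drop = FALSE], cent[as.character(cid), ])
    ord <- order(-sims)
    ex <- unname(text_of[ids[utils::head(ord, top_examples)]])
    kw <- character()
    if (!is.null(model)) {
      s <- cosine_to(model$W_in, cent[as.character(cid), ])
      kw <- rownames(model$W_in)[utils::head(order(-s, seq_along(s)), 5L)]
    }
    tibble(category = cid, size = length(ids),
           examples = list(ex), keywords = list(kw))
  })
  out <- bind_rows(rows)
  class(out) <- c("tr_review_report", class(out))
  out
}

#' Apply human review decisions to a cluster set
#'
#' Ingests the outcome of the manual review: a list of decisions, each
#' either `list(action = "merge", source = <id>, target = <id>)`
#' (source category absorbed into target) or
#' `list(action = "relabel", source = <id>, label = <string>)`. Merges
#' are applied in order; referencing an unknown or already-absorbed
#' category is an error, which also rules out cyclic merges.
#'
#' @param clusters A `tr_clusters`.
#' @param decisions A list of decision lists (possibly empty).
#' @return The updated `tr_clusters`, with an audit trail appended to
#'   `review_log` and labels stored in a `labels` named vector.
#' @export
apply_review_decisions <- function(clusters, decisions) {
  asg <- clusters$assignments
  labels <- attr(clusters, "labels") %||% character()
  log <- clusters$review_log
  alive <- unique(asg$category)
  for (dec in decisions) {
    if (!dec$action %in% c("merge", "relabel")) {
      abort(sprintf("unknown review action '%s'", dec$action))
    }
    if (!dec$source %in% alive) {
      abort(sprintf("decision references unknown category %s", dec$source))
    }
    if (dec$action == "merge") {
      if (!dec$target %in% alive) {
        abort(sprintf("decision references unknown category %s", dec$target))
      }
      if (dec$source == dec$target) abort("cannot merge a category into itself")
      asg$category[asg$category == dec$source] <- dec$target
      alive <- setdiff(alive, dec$source)
      log <- bind_rows(log, tibble(step = "manual_merge", comment_id = NA_character_,
                                   from = as.integer(dec$source),
                                   to = as.integer(dec$target),
                                   similarity = NA_real_))
    } else {
      labels[as.character(dec$source)] <- dec$label
    }
  }
  out <- new_cluster_set(clusters$vectors, clusters$threshold, asg,
                         review_log = log, quarantined = clusters$quarantined)
  attr(out, "labels") <- labels
  out
}
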