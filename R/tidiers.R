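#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_point
#'   facet_wrap labs coord_flip
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a trained embedding model into a long tibble of loss values
#'
#' One row per epoch and loss component (`L_cont`, `L_topic`, `L_s`).
#'
#' @param x A `tr_embedding`.
#' @param ... Unused.
#' @export
tidy.tr_embedding <- function(x, ...) {
  x$loss_curve |>
    tidyr::pivot_longer(c("L_cont", "L_topic", "L_s"),
                        names_to = "component", values_to = "loss")
}

#' @describeIn tidy.tr_embedding One-row model summary.
#' @export
glance.tr_embedding <- function(x, ...) {
  lc <- x$loss_curve
  tibble(
    vocab_size = nrow(x$W_in),
    dim = ncol(x$W_in),
    lambda = x$config$lambda %||% NA_real_,
    epochs = nrow(lc),
    n_topics = length(x$topics),
    final_loss = if (nrow(lc)) lc$L_s[[nrow(lc)]] else NA_real_
  )
}

#' @export
autoplot.tr_embedding <- function(object, ...) {
  tidy(object) |>
    ggplot(aes(x = .data$epoch, y = .data$loss, colour = .data$component)) +
    geom_line() +
    geom_point(size = 1) +
    labs(x = "epoch", y = "mean loss", colour = NULL,
         title = "Embedding training loss")
}

#' Tidy a classifier fit into its training-loss curve
#'
#' @param x A `tr_textcnn`.
#' @param ... Unused.
#' @export
tidy.tr_textcnn <- function(x, ...) x$loss_curve

#' @describeIn tidy.tr_textcnn One-row fit summary.
#' @export
glance.tr_textcnn <- function(x, ...) {
  n_par <- sum(vapply(x$params$kernels, length, numeric(1))) +
    sum(vapply(x$params$biases, length, numeric(1))) +
    length(x$params$W) + length(x$params$b)
  tibble(
    kernel_sizes = paste(x$config$kernel_sizes, collapse = ","),
    filters_per_size = x$config$filters_per_size,
    dim = x$dim,
    n_parameters = n_par,
    epochs = nrow(x$loss_curve),
    final_loss = x$loss_curve$loss[[nrow(x$loss_curve)]]
  )
}

#' @export
autoplot.tr_textcnn <- function(object, ...) {
  ggplot(object$loss_curve, aes(x = .data$epoch, y = .data$loss)) +
    geom_line() +
    geom_point(size = 1) +
    labs(x = "epoch", y = "training cross-entropy",
         title = "Classifier training loss")
}

#' Tidy a cluster set into its assignment table
#'
#' @param x A `tr_clusters`.
#' @param ... Unused.
#' @export
tidy.tr_clusters <- function(x, ...) as_tibble(x$assignments)

#' @describeIn tidy.tr_clusters One-row clustering summary.
#' @export
glance.tr_clusters <- function(x, ...) {
  sizes <- table(x$assignments$category)
  tibble(
    n_documents = nrow(x$assignments),
    n_categories = length(sizes),
    n_singletons = sum(sizes == 1L),
    n_quarantined = length(x$quarantined),
    n_reviewed = nrow(x$review_log),
    theta = x$threshold,
    largest = if (length(sizes)) max(sizes) else 0L
  )
}

#' @export
autoplot.tr_clusters <- function(object, ...) {
  tidy(object) |>
    count(.data$category, name = "size") |>
    arrange(desc(.data$size)) |>
    mutate(category = factor(.data$category, levels = .data$category)) |>
    ggplot(aes(x = .data$category, y = .data$size)) +
    geom_col() +
    labs(x = "category (founding order)", y = "members",
         title = sprintf("Cluster sizes (theta = %g)", object$threshold))
}

#' @export
autoplot.tr_keywords <- function(object, ...) {
  object |>
    mutate(word = factor(.data$word, levels = rev(.data$word))) |>
    ggplot(aes(x = .data$word, y = .data$weight)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "normalized TextRank weight",
         title = "Top category keywords")
}

#' Tidy a topic dictionary into its entry table
#'
#' @param x A `tr_topicdict`.
#' @param ... Unused.
#' @export
tidy.tr_topicdict <- function(x, ...) as_tibble(x$entries)

#' @describeIn tidy.tr_topicdict One-row dictionary summary.
#' @export
glance.tr_topicdict <- function(x, ...) {
  tibble(
    n_words = nrow(x$entries),
    n_topics = dplyr::n_distinct(x$entries$topic),
    default_weight = x$default_weight,
    risk_weight = x$risk_weight
  )
}

#' @importFrom rlang .data
NULL
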