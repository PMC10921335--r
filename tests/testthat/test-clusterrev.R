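# deterministic 2-D cone fixture: two directions with small angular spread
cone_vectors <- function() {
  ang <- c(0.00, 0.05, 0.10, 0.15, 1.45, 1.50, 1.55, 1.60)
  M <- cbind(cos(ang), sin(ang))
  rownames(M) <- sprintf("d%d", seq_len(nrow(M)))
  M
}

test_that("doc_vectors averages token embeddings and quarantines zero norms", {
  m <- toy_six_words()
  comments <- tibble::tibble(
    comment_id = c("one", "five"),
    tokens = list("sun",
                  c("sun", "warm", "heat", "rain", "damp"))
  )
  dv <- doc_vectors(comments, m)
  expect_identical(unname(dv$vectors["one", ]), unname(m$W_in["sun", ]))
  expect_equal(unname(dv$vectors["five", ]),
               unname(colMeans(m$W_in[c("sun", "warm", "heat", "rain", "damp"), ])))
  # cancellation -> zero vector -> quarantined
  m2 <- toy_embedding(rbind(up = c(0, 1), down = c(0, -1)))
  dv2 <- doc_vectors(tibble::tibble(comment_id = "x", tokens = list(c("up", "down"))), m2)
  expect_identical(dv2$quarantined, "x")
  expect_identical(nrow(dv2$vectors), 0L)
  # all-OOV comment is quarantined too
  dv3 <- doc_vectors(tibble::tibble(comment_id = "y", tokens = list("zzz")), m)
  expect_identical(dv3$quarantined, "y")
})

test_that("single_pass matches the spec'd trivial geometries", {
  M <- matrix(rep(c(1, 2), each = 6), 6, 2)
  rownames(M) <- sprintf("d%d", 1:6)
  cl <- single_pass(M, theta = 0.9)
  expect_identical(length(unique(cl$assignments$category)), 1L)

  O <- diag(4)
  rownames(O) <- sprintf("d%d", 1:4)
  cl2 <- single_pass(O, theta = 0.5)
  expect_identical(cl2$assignments$category, 1:4)

  expect_error(single_pass(M, theta = 1.5), "theta")
  empty <- single_pass(list(vectors = M[0, , drop = FALSE], quarantined = "q"), 0.5)
  expect_identical(nrow(empty$assignments), 0L)
  expect_identical(empty$quarantined, "q")
})

test_that("single_pass follows the traced assignment on the two-cone fixture", {
  M <- cone_vectors()
  cl <- single_pass(M, theta = 0.8)
  # independent reference implementation (centroids from scratch)
  expect_identical(cl$assignments$category, oracle_single_pass(M, 0.8))
  # two cones -> two categories, split 4/4, hand-checked:
  # cos(0.15) = 0.989 >= 0.8 keeps the first cone together; cos(1.45) = 0.12
  # forces a new category; drifted centroids still accept the rest
  expect_identical(unname(cl$assignments$category), c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L))
})

test_that("centroids always equal recomputed member means", {
  withr::with_seed(83, {
    for (rep in 1:5) {
      M <- matrix(rnorm(40 * 3), 40, 3)
      rownames(M) <- sprintf("d%02d", 1:40)
      cl <- review_pass(single_pass(M, theta = 0.6))
      cents <- topicrisk:::cluster_centroids(cl)
      for (cid in rownames(cents)) {
        ids <- cl$assignments$comment_id[cl$assignments$category == as.integer(cid)]
        expect_equal(unname(cents[cid, ]),
                     unname(colMeans(M[ids, , drop = FALSE])),
                     tolerance = 1e-9)
      }
    }
  })
})

test_that("review_pass merges rescuable singletons and only those", {
  # no singletons: identity
  M <- matrix(rep(c(1, 0), each = 4), 4, 2)
  rownames(M) <- sprintf("d%d", 1:4)
  cl <- single_pass(M, theta = 0.5)
  expect_identical(review_pass(cl)$assignments, cl$assignments)

  # singleton orthogonal to every centroid: unchanged
  M2 <- rbind(a = c(1, 0), b = c(1, 0.01), x = c(0, 1))
  cl2 <- review_pass(single_pass(M2, theta = 0.7))
  expect_identical(sort(unique(cl2$assignments$category)), c(1L, 2L))

  # constructed drift case: d1 founds category 1; d2 (0.62 rad away) founds
  # a singleton; d3..d8 each sit closer to category 1's evolving centroid
  # than to d2 and drag that centroid from angle 0 up to ~0.34, so on
  # review the singleton's cosine to the final centroid clears the
  # threshold cos(0.3) and it is merged
  ang <- c(0, 0.62, 0.28, 0.37, 0.40, 0.42, 0.44, 0.46)
  M3 <- cbind(cos(ang), sin(ang))
  rownames(M3) <- sprintf("d%d", 1:8)
  theta <- cos(0.3)  # 0.955
  cl3 <- single_pass(M3, theta = theta)
  expect_identical(unname(cl3$assignments$category),
                   c(1L, 2L, 1L, 1L, 1L, 1L, 1L, 1L))
  sizes <- table(cl3$assignments$category)
  expect_identical(length(sizes), 2L)
  expect_identical(sum(sizes == 1L), 1L)
  cl3r <- review_pass(cl3)
  expect_identical(length(unique(cl3r$assignments$category)), 1L)
  expect_identical(nrow(cl3r$review_log), 1L)
  expect_identical(cl3r$review_log$step, "auto_review")
})

test_that("review_pass never increases category or singleton counts", {
  withr::with_seed(89, {
    for (rep in 1:100) {
      n <- sample(5:25, 1)
      M <- matrix(rnorm(n * 2), n, 2)
      rownames(M) <- sprintf("d%02d", seq_len(n))
      cl <- single_pass(M, theta = runif(1, 0.3, 0.9))
      clr <- review_pass(cl)
      before <- table(cl$assignments$category)
      after <- table(clr$assignments$category)
      expect_lte(length(after), length(before))
      expect_lte(sum(after == 1L), sum(before == 1L))
      # partition preserved
      expect_setequal(clr$assignments$comment_id, cl$assignments$comment_id)
      expect_identical(anyDuplicated(clr$assignments$comment_id), 0L)
    }
  })
})

test_that("order sensitivity exists and review_pass reduces it", {
  # two noisy planted groups and a threshold tight enough to fragment
  # them differently depending on arrival order
  withr::with_seed(6, {
    g1 <- matrix(rnorm(30 * 2, mean = c(3, 0), sd = 0.45), 30, 2, byrow = TRUE)
    g2 <- matrix(rnorm(30 * 2, mean = c(0, 3), sd = 0.45), 30, 2, byrow = TRUE)
    M <- rbind(g1, g2)
    rownames(M) <- sprintf("d%02d", 1:60)
    ord2 <- sample(60)
  })
  theta <- 0.995
  cl_a <- single_pass(M, theta)
  cl_b <- single_pass(M[ord2, ], theta)
  pair <- function(a, b) {
    bb <- b$assignments$category[match(a$assignments$comment_id,
                                       b$assignments$comment_id)]
    adjusted_rand_index(a$assignments$category, bb)
  }
  agree_before <- pair(cl_a, cl_b)
  expect_lt(agree_before, 1)  # the two orders genuinely disagree
  agree_after <- pair(review_pass(cl_a), review_pass(cl_b))
  expect_gt(agree_after, agree_before)
})

test_that("review_report summarises sizes, central members and keywords", {
  empty <- single_pass(list(vectors = matrix(0, 0, 2), quarantined = character()), 0.5)
  expect_identical(nrow(review_report(empty, tibble::tibble())), 0L)

  m <- toy_six_words()
  comments <- tibble::tibble(
    comment_id = sprintf("c%d", 1:6),
    text = sprintf("comment %d", 1:6),
    tokens = lapply(rownames(m$W_in), identity)
  )
  dv <- doc_vectors(comments, m)
  cl <- single_pass(dv, theta = 0.8)
  rep <- review_report(cl, comments, top_examples = 2, model = m)
  expect_identical(sum(rep$size), nrow(cl$assignments))
  # most-central member checked exhaustively per category
  cents <- topicrisk:::cluster_centroids(cl)
  for (i in seq_len(nrow(rep))) {
    ids <- cl$assignments$comment_id[cl$assignments$category == rep$category[i]]
    sims <- apply(dv$vectors[ids, , drop = FALSE], 1, function(v) {
      sum(v * cents[as.character(rep$category[i]), ]) /
        sqrt(sum(v^2) * sum(cents[as.character(rep$category[i]), ]^2))
    })
    best_text <- comments$text[comments$comment_id == ids[which.max(sims)]]
    expect_identical(rep$examples[[i]][1], best_text)
  }
})

test_that("apply_review_decisions merges and relabels with validation", {
  O <- diag(6)
  rownames(O) <- sprintf("d%d", 1:6)
  cl <- single_pass(O, theta = 0.5)  # 6 singleton categories
  expect_identical(apply_review_decisions(cl, list())$assignments, cl$assignments)

  merged <- apply_review_decisions(cl, list(
    list(action = "merge", source = 2L, target = 1L)
  ))
  expect_identical(length(unique(merged$assignments$category)), 5L)

  # three chained merges, hand-applied result
  m3 <- apply_review_decisions(cl, list(
    list(action = "merge", source = 2L, target = 1L),
    list(action = "merge", source = 3L, target = 1L),
    list(action = "merge", source = 5L, target = 4L)
  ))
  expect_identical(unname(m3$assignments$category), c(1L, 1L, 1L, 4L, 4L, 6L))

  expect_error(apply_review_decisions(cl, list(
    list(action = "merge", source = 99L, target = 1L)
  )), "unknown category")
  # cyclic: after 2 -> 1, category 2 no longer exists
  expect_error(apply_review_decisions(cl, list(
    list(action = "merge", source = 2L, target = 1L),
    list(action = "merge", source = 1L, target = 2L)
  )), "unknown category")
  relabeled <- apply_review_decisions(cl, list(
    list(action = "relabel", source = 1L, label = "pollen season")
  ))
  expect_identical(unname(attr(relabeled, "labels")["1"]), "pollen season")
})

test_that("adjusted_rand_index matches the pair-counting oracle", {
  withr::with_seed(101, {
    for (rep in 1:10) {
      n <- sample(8:20, 1)
      a <- sample(1:4, n, replace = TRUE)
      b <- sample(1:3, n, replace = TRUE)
      expect_equal(adjusted_rand_index(a, b), oracle_ari(a, b), tolerance = 1e-12)
    }
  })
  expect_equal(adjusted_rand_index(c(1, 1, 2), c("x", "x", "y")), 1)
})
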