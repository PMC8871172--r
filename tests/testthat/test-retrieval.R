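test_that("aggregation is fG + alpha * fL, elementwise", {
  fg <- c(1, 0); fl <- c(0, 2)
  expect_equal(as.numeric(aggregate_features(fg, fl, 0.5)), c(1, 1))
  expect_equal(as.numeric(aggregate_features(fg, fl, 0)), fg)
  v <- runif(6)
  expect_equal(as.numeric(aggregate_features(v, v, 1)), 2 * v)
  expect_error(aggregate_features(c(1, 2), c(1, 2, 3)), "lengths differ")
  expect_error(aggregate_features(fg, fl, -1), "non-negative")
})

test_that("cosine similarity is normalized, symmetric, and guards zero norms", {
  v <- c(0.3, 1.2, 0.5)
  expect_equal(cosine_similarity(v, v), 1)
  expect_equal(cosine_similarity(v, 3 * v), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  a <- runif(5); b <- runif(5)
  expect_equal(cosine_similarity(a, b), cosine_similarity(b, a))
  expect_warning(s <- cosine_similarity(c(0, 0), c(1, 2)), "zero-norm")
  expect_equal(s, 0)
})

toy_index <- function() {
  feats <- rbind(a = c(1, 0, 0), b = c(0, 1, 0), c = c(0.9, 0.1, 0))
  idx <- list(ids = rownames(feats),
              labels = c(a = "x", b = "y", c = "x"),
              features = feats,
              settings = list(mode = "original", minsupp = 2L, alpha = 1,
                              connectivity = 8L))
  class(idx) <- "retrieval_index"
  idx
}

test_that("ranking sorts by score with ascending-id tie-breaks and self-exclusion", {
  idx <- toy_index()
  r <- rank_index(idx, c(1, 0, 0))
  expect_equal(r$id[1], "a")
  expect_equal(r$score[1], 1)
  expect_true(all(diff(r$score) <= 0))
  # K larger than the index returns everything
  expect_equal(nrow(rank_index(idx, c(1, 0, 0), k = 100)), 3L)
  expect_equal(nrow(rank_index(idx, c(1, 0, 0), k = 1)), 1L)
  # exact ties resolve by ascending id
  tie <- toy_index()
  tie$features <- rbind(a = c(1, 0, 0), b = c(2, 0, 0), c = c(3, 0, 0))
  tie$ids <- rownames(tie$features)
  expect_equal(rank_index(tie, c(1, 0, 0))$id, c("a", "b", "c"))
  # self-exclusion
  expect_false("a" %in% rank_index(idx, c(1, 0, 0), query_id = "a")$id)
  empty <- toy_index(); empty$ids <- character(0)
  expect_error(rank_index(empty, c(1, 0, 0)), "empty index")
  expect_error(rank_index(idx, c(1, 0)), "dimensions")
})

test_that("average precision matches hand evaluation and edge cases", {
  # relevant at ranks 1 and 3 of 4, R = 2: (1/2)(1/1 + 2/3) = 5/6
  expect_equal(average_precision(c("r1", "x", "r2", "y"), c("r1", "r2")),
               5 / 6)
  # all relevant first -> 1
  expect_equal(average_precision(c("r1", "r2", "x", "y"), c("r1", "r2")), 1)
  # none present, explicit R -> 0
  expect_equal(average_precision(c("x", "y"), c("r1", "r2"),
                                 n_relevant = 2), 0)
  expect_warning(ap <- average_precision(c("x", "y"), character(0)),
                 "undefined")
  expect_true(is.na(ap))
})

test_that("mAP is the arithmetic mean of per-query APs", {
  expect_equal(mean_average_precision(c(1, 0.5)), 0.75)
  expect_equal(mean_average_precision(0.4), 0.4)
  expect_equal(mean_average_precision(rep(0.3, 7)), 0.3)
  expect_warning(m <- mean_average_precision(c(0.5, NA)), "undefined")
  expect_equal(m, 0.5)
  expect_error(suppressWarnings(mean_average_precision(NA_real_)), "no valid")
})

test_that("AP agrees with an independent cumulative-hit formulation", {
  set.seed(123)
  for (rep in 1:100) {
    n <- sample(2:40, 1)
    rel <- rbinom(n, 1, runif(1, 0.1, 0.9))
    ids <- sprintf("i%02d", seq_len(n))
    ap1 <- suppressWarnings(average_precision(ids, ids[rel == 1]))
    ap2 <- ap_cumulative_hits(rel)
    if (is.na(ap2)) expect_true(is.na(ap1))
    else {
      expect_equal(ap1, ap2, tolerance = 1e-12)
      expect_gte(ap1, 0); expect_lte(ap1, 1)
    }
  }
})

test_that("AP is 1 exactly when all relevant precede all irrelevant", {
  ids <- sprintf("i%d", 1:6)
  expect_equal(average_precision(ids, ids[1:3]), 1)
  expect_lt(average_precision(ids, ids[c(1, 2, 4)]), 1)
})

test_that("positive rescaling of database features never changes rankings", {
  set.seed(9)
  idx <- toy_index()
  idx$features <- matrix(runif(15), 5, 3,
                         dimnames = list(sprintf("i%d", 1:5), NULL))
  idx$ids <- rownames(idx$features)
  q <- runif(3)
  base <- rank_index(idx, q)
  for (scale in c(0.01, 7, 1e4)) {
    scaled <- idx
    scaled$features <- idx$features * scale
    expect_equal(rank_index(scaled, q)$id, base$id)
  }
})

test_that("leave-one-out evaluation scores a separable corpus perfectly", {
  set.seed(4)
  base1 <- array(runif(3 * 3 * 6), c(3, 3, 6))
  base2 <- array(runif(3 * 3 * 6), c(3, 3, 6))
  tensors <- list(a1 = activation_tensor(base1),
                  a2 = activation_tensor(base1),
                  b1 = activation_tensor(base2),
                  b2 = activation_tensor(base2))
  labels <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  idx <- build_index(tensors, labels, mode = "original")
  rep <- evaluate_index(idx)
  expect_equal(rep$map, 1)
  expect_equal(rep$Q, 4L)
  expect_equal(sort(names(rep$per_query_ap)), sort(names(tensors)))
})

test_that("random features score near the label-permutation chance level", {
  set.seed(2024)
  n <- 20; dims <- 16
  feats <- matrix(runif(n * dims), n, dims,
                  dimnames = list(sprintf("i%02d", 1:n), NULL))
  labels <- stats::setNames(rep(sprintf("c%d", 1:4), each = 5), rownames(feats))
  obs <- mean_average_precision(
    fgir:::eval_features(feats, rownames(feats), labels))
  # empirical chance baseline: the same features under permuted labels
  perm_maps <- replicate(100, {
    pl <- stats::setNames(sample(labels), names(labels))
    mean_average_precision(fgir:::eval_features(feats, rownames(feats), pl))
  })
  expect_lt(abs(obs - mean(perm_maps)), 3 * stats::sd(perm_maps) + 0.02)
})

test_that("the ablation respects its analytic limits", {
  corp <- generate_corpus(2, 3, c(5, 5, 16), seed = 3, s = 4, part_size = 3)
  tab0 <- run_ablation(corp$tensors, corp$labels, minsupp = 4, alpha = 0)
  expect_equal(tab0$map[tab0$mode == "global_local"],
               tab0$map[tab0$mode == "global"])
  expect_equal(tab0$mode, c("original", "global", "local", "global_local"))
  expect_true(all(tab0$map >= 0 & tab0$map <= 1))
  # a single class makes every candidate relevant: every mAP is 1
  one_cls <- stats::setNames(rep("only", length(corp$labels)),
                             names(corp$labels))
  tab1 <- run_ablation(corp$tensors, one_cls, minsupp = 4, alpha = 1)
  expect_equal(tab1$map, rep(1, 4))
})

test_that("aggregating the streams helps when classes differ by co-activation", {
  corp <- generate_corpus(4, 5, c(7, 7, 64), seed = 2)
  tab <- run_ablation(corp$tensors, corp$labels, minsupp = 4, alpha = 1)
  maps <- stats::setNames(tab$map, tab$mode)
  expect_gte(maps[["global_local"]], maps[["global"]])
  expect_gte(maps[["global_local"]], maps[["original"]])
})
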