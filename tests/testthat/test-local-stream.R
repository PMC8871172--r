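# the hand-worked database used throughout: items a=1, b=2, c=3
worked_db <- function() transaction_db(list(c(1, 2, 3), c(1, 2), c(1, 3), 2))

test_that("feature maps binarize at their own mean, strictly", {
  x <- array(0, c(2, 2, 3))
  x[, , 1] <- matrix(c(0, 2, 4, 2), 2, 2, byrow = TRUE)  # mean 2
  x[, , 2] <- 5                                           # constant
  x[1, 2, 3] <- 1                                         # lone spike
  tensor <- activation_tensor(x)
  expect_equal(binarize_feature_map(tensor, 1), 2L)  # only (1,0), value 4
  expect_equal(binarize_feature_map(tensor, 2), integer(0))
  expect_equal(binarize_feature_map(tensor, 3), 1L)
  expect_error(binarize_feature_map(tensor, 4), "out of range")
})

test_that("transactions mirror feature maps one-to-one", {
  set.seed(5)
  x <- array(runif(7 * 7 * 12, 0, 0.1), c(7, 7, 12))
  # channels 1..10 spike identically at flats 9 and 30
  rc <- flat_to_rowcol(c(9L, 30L), 7L) + 1L
  for (ch in 1:10) x[cbind(rc, ch)] <- 50
  db <- build_transactions(activation_tensor(x))
  expect_s3_class(db, "transaction_db")
  expect_equal(db$m, 12L)
  for (ch in 1:10) expect_equal(db$transactions[[ch]], c(9L, 30L))

  zero <- build_transactions(activation_tensor(array(0, c(7, 7, 6))))
  expect_equal(zero$m, 6L)
  expect_true(all(lengths(zero$transactions) == 0L))
  expect_length(zero$items, 0L)
})

test_that("support counts containment, with the empty set vacuously universal", {
  db <- worked_db()
  expect_equal(support(c(1, 2), db), 2L)
  expect_equal(support(1, db), 3L)
  expect_equal(support(3, db), 2L)
  expect_equal(support(integer(0), db), 4L)
  expect_equal(support(99, db), 0L)
  expect_equal(support(c(1, 2, 3), db), 1L)
})

test_that("FP-tree construction sorts, merges prefixes, and keeps header sums", {
  db <- worked_db()
  tree <- build_fp_tree(db, 2)
  # decreasing support with ascending-id tie-break: a(3), b(3), c(2)
  expect_equal(tree$items, c(1L, 2L, 3L))
  expect_equal(unname(tree$supports), c(3, 3, 2))
  # transaction {b} opens its own branch: root children are a:3 and b:1
  kids <- sort(ls(tree$root$children))
  expect_equal(kids, c("1", "2"))
  expect_equal(get("1", tree$root$children)$count, 3)
  expect_equal(get("2", tree$root$children)$count, 1)
  # header-chain conservation: per-item chain counts sum to the support
  for (it in tree$items)
    expect_equal(sum(fgir:::header_chain_counts(tree, it)),
                 unname(tree$supports[as.character(it)]))
})

test_that("degenerate FP-trees: nothing frequent, or a single path", {
  db <- worked_db()
  expect_length(build_fp_tree(db, db$m + 1L)$items, 0L)
  single <- transaction_db(list(c(1, 2)))
  tree <- build_fp_tree(single, 1)
  a <- get("1", tree$root$children)
  b <- get("2", a$children)
  expect_equal(a$count, 1); expect_equal(b$count, 1)
  expect_length(ls(b$children), 0L)
})

test_that("FP-growth reproduces the hand-enumerated worked instance", {
  db <- worked_db()
  all_ps <- mine_patterns(db, 2, mode = "all")
  expect_equal(pattern_df(all_ps),
               data.frame(items = c("1", "2", "1 2", "1 3", "3"),
                          support = c(3L, 3L, 2L, 2L, 2L)))
  max_ps <- mine_patterns(db, 2, mode = "maximal")
  expect_equal(pattern_df(max_ps),
               data.frame(items = c("1 2", "1 3"), support = c(2L, 2L)))
  expect_equal(max_ps$support_mask, c(1L, 2L, 3L))
  # one transaction, minsupp 1
  expect_equal(pattern_df(mine_patterns(transaction_db(list(1)), 1,
                                        mode = "all")),
               data.frame(items = "1", support = 1L))
})

test_that("FP-growth equals brute-force enumeration on random databases", {
  set.seed(13)
  for (rep in 1:40) {
    db <- random_db(sample(1:12, 1), sample(1:8, 1))
    for (ms in seq_len(db$m)) {
      mined <- mine_patterns(db, ms, mode = "all")
      oracle <- brute_force_patterns(db, ms, mode = "all")
      expect_equal(pattern_df(mined), pattern_df(oracle),
                   info = sprintf("rep %d minsupp %d", rep, ms))
    }
  }
})

test_that("apriori monotonicity holds in mode = all", {
  set.seed(31)
  for (rep in 1:10) {
    db <- random_db(10, 6)
    ps <- mine_patterns(db, 2, mode = "all")
    keys <- vapply(ps$patterns, function(p) paste(p$items, collapse = ","),
                   character(1))
    supp <- stats::setNames(vapply(ps$patterns, `[[`, integer(1), "support"),
                            keys)
    for (p in ps$patterns) {
      if (length(p$items) < 2) next
      for (drop in seq_along(p$items)) {
        sub <- p$items[-drop]
        key <- paste(sub, collapse = ",")
        expect_true(key %in% keys)
        expect_gte(supp[[key]], p$support)
      }
    }
  }
})

test_that("maximal patterns are subset-maximal and share the support mask", {
  set.seed(77)
  for (rep in 1:15) {
    db <- random_db(8, 7)
    all_ps <- mine_patterns(db, 2, mode = "all")
    max_ps <- mine_patterns(db, 2, mode = "maximal")
    sets <- lapply(max_ps$patterns, `[[`, "items")
    for (i in seq_along(sets)) for (j in seq_along(sets)) {
      if (i != j) expect_false(all(sets[[i]] %in% sets[[j]]))
    }
    # pooling bridge: union over maximal equals union over all patterns
    expect_equal(max_ps$support_mask, all_ps$support_mask)
  }
})

test_that("mined supports agree with direct containment counts", {
  set.seed(19)
  for (rep in 1:10) {
    db <- random_db(9, 6)
    for (p in mine_patterns(db, 2, mode = "all")$patterns)
      expect_equal(support(p$items, db), p$support)
  }
})

test_that("planted co-activation sets are recovered with exact support", {
  for (sd in 1:8) {
    set.seed(sd * 100)
    size <- sample(3:6, 1)
    s <- sample(5:12, 1)
    S <- sort(sample(0:48, size))
    spec <- scene_spec(7, 7, 32,
                       part_sets = list(list(positions = S, s = s)),
                       noise = list(level = 0.3, positions_per_channel = 3,
                                    max_support = 1),
                       seed = sd)
    tensor <- generate_tensor(spec)
    ps <- mine_patterns(build_transactions(tensor), 2, mode = "maximal")
    keys <- vapply(ps$patterns, function(p) paste(p$items, collapse = ","),
                   character(1))
    hit <- which(keys == paste(S, collapse = ","))
    expect_length(hit, 1)
    expect_equal(ps$patterns[[hit]]$support, s)
    expect_equal(ps$support_mask, S)
  }
})

test_that("local feature pools exactly the pattern support positions", {
  S <- c(3L, 10L, 17L, 24L)
  spec <- scene_spec(7, 7, 32,
                     part_sets = list(list(positions = S, s = 10)),
                     noise = list(level = 0.3, positions_per_channel = 3,
                                  max_support = 1),
                     seed = 42)
  tensor <- generate_tensor(spec)
  fl <- local_feature(tensor, minsupp = 2)
  expect_equal(attr(fl, "region"), S)
  expect_equal(as.numeric(fl), as.numeric(pool_region(tensor, S)))
})

test_that("channel permutation leaves patterns invariant and fL equivariant", {
  set.seed(55)
  x <- array(rexp(5 * 5 * 10), c(5, 5, 10))
  tensor <- activation_tensor(x)
  perm <- sample(10)
  permuted <- activation_tensor(x[, , perm])
  ps1 <- mine_patterns(build_transactions(tensor), 2, mode = "all")
  ps2 <- mine_patterns(build_transactions(permuted), 2, mode = "all")
  expect_equal(pattern_df(ps1), pattern_df(ps2))
  expect_equal(ps1$support_mask, ps2$support_mask)
  fl <- suppressWarnings(local_feature(tensor, 2))
  flp <- suppressWarnings(local_feature(permuted, 2))
  d <- 10
  expect_equal(as.numeric(flp), as.numeric(fl)[c(perm, perm + d)],
               tolerance = 1e-14)
})

test_that("degenerate mining falls back to full-grid pooling with a warning", {
  zero <- activation_tensor(array(0, c(3, 3, 4)))
  expect_warning(fl <- local_feature(zero, 2), "fall")
  expect_equal(as.numeric(fl), rep(0, 8))
  expect_equal(attr(fl, "region"), 0:8)
  # minsupp too large for anything to be frequent
  set.seed(2)
  tensor <- activation_tensor(array(runif(3 * 3 * 4), c(3, 3, 4)))
  expect_warning(fl2 <- local_feature(tensor, 100), "fall")
  expect_equal(as.numeric(fl2), as.numeric(original_feature(tensor)))
})

test_that("minsupp is an absolute count; zero clamps, negatives fail", {
  db <- worked_db()
  expect_warning(ps <- mine_patterns(db, 0, mode = "all"), "minsupp")
  expect_equal(pattern_df(ps),
               pattern_df(mine_patterns(db, 1, mode = "all")))
  expect_error(mine_patterns(db, -1), "non-negative")
})

test_that("a pattern explosion aborts with an explicit error", {
  # 10 items present in every one of 3 transactions: 1023 frequent itemsets
  db <- transaction_db(rep(list(0:9), 3))
  expect_error(mine_patterns(db, 3, max_patterns = 100),
               "explosion.*minsupp = 3")
  ps <- mine_patterns(db, 3, mode = "all", max_patterns = 2000)
  expect_length(ps$patterns, 1023L)
})

test_that("empty transactions count toward m but never support a pattern", {
  db <- transaction_db(list(c(1, 2), integer(0), c(1, 2), integer(0)))
  expect_equal(db$m, 4L)
  ps <- mine_patterns(db, 2, mode = "all")
  expect_equal(pattern_df(ps),
               data.frame(items = c("1", "1 2", "2"),
                          support = c(2L, 2L, 2L)))
})

test_that("FIMI transaction files round-trip", {
  db <- transaction_db(list(c(3, 7, 11), integer(0), c(0, 7)))
  path <- withr::local_tempfile(fileext = ".dat")
  write_transactions(db, path)
  back <- read_transactions(path)
  expect_equal(back$transactions, db$transactions)
  expect_equal(back$m, db$m)
  expect_error(read_transactions(file.path(tempdir(), "none.dat")),
               "not found")
})
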