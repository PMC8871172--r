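#' Transaction databases over activated positions
#'
#' The local stream casts the activation tensor as a market-basket problem:
#' each of the `d` feature maps is one transaction, and each spatial
#' position whose response strictly exceeds that map's own mean is an item
#' of the transaction. Items are 0-based row-major flat ids.
#' `transaction_db()` builds a database from explicit item sets (used for
#' generic mining and for the FIMI text format); [build_transactions()]
#' derives one from a tensor.
#'
#' @param transactions list of integer vectors (item sets); duplicates
#'   within a transaction are not allowed. Empty transactions are legal and
#'   retained — they count toward `m` but can never support a pattern.
#' @return a `transaction_db`: list with `transactions`, `m` (transaction
#'   count), `items` (sorted item universe).
#' @export
transaction_db <- function(transactions) {
  if (!is.list(transactions)) stop("transactions must be a list")
  transactions <- lapply(transactions, function(t) {
    t <- as.integer(t)
    if (anyNA(t) || any(t < 0L)) stop("items must be non-negative integers")
    if (anyDuplicated(t)) stop("a transaction cannot repeat an item")
    sort(t)
  })
  db <- list(transactions = transactions,
             m = length(transactions),
             items = sort(unique(unlist(transactions))))
  class(db) <- "transaction_db"
  db
}

#' @export
print.transaction_db <- function(x, ...) {
  cat(sprintf("<transaction_db: m = %d transactions, %d distinct items>\n",
              x$m, length(x$items)))
  invisible(x)
}

#' Activated positions of one feature map
#'
#' Binarizes channel `channel` of the tensor at that channel's own mean:
#' a position is activated iff its response strictly exceeds the mean.
#' A constant feature map therefore activates nothing.
#'
#' @param tensor an activation tensor.
#' @param channel 1-based channel index.
#' @return sorted integer vector of 0-based row-major flat ids.
#' @export
binarize_feature_map <- function(tensor, channel) {
  assert_tensor(tensor)
  dm <- dim(tensor)
  if (channel < 1L || channel > dm[3L])
    stop(sprintf("channel %s out of range [1, %d]", toString(channel), dm[3L]))
  fm <- unclass(tensor)[, , channel]
  hits <- which(fm > mean(fm))                  # column-major cell indices
  h <- dm[1L]; w <- dm[2L]
  i <- (hits - 1L) %% h
  j <- (hits - 1L) %/% h
  sort(as.integer(i * w + j))
}

#' Convert a tensor into a transaction database
#'
#' One transaction per feature map (`m = d`), holding that map's activated
#' positions per [binarize_feature_map()].
#'
#' @param tensor an activation tensor.
#' @return a `transaction_db` with extra fields `h`, `w`, `d`.
#' @export
build_transactions <- function(tensor) {
  assert_tensor(tensor)
  dm <- dim(tensor)
  db <- transaction_db(lapply(seq_len(dm[3L]),
                              function(ch) binarize_feature_map(tensor, ch)))
  db$h <- dm[1L]; db$w <- dm[2L]; db$d <- dm[3L]
  db
}

#' Support of an itemset
#'
#' The number of transactions containing every item of the set (an absolute
#' count in `[0, m]`; the transaction count `m` is fixed by the backbone, so
#' supports are used as raw counts rather than fractions). The empty set is
#' vacuously contained in every transaction.
#'
#' @param items integer vector of item ids (may be empty).
#' @param db a `transaction_db`.
#' @return integer count.
#' @export
support <- function(items, db) {
  items <- as.integer(items)
  if (length(items) == 0L) return(db$m)
  sum(vapply(db$transactions, function(t) all(items %in% t), logical(1L)))
}

# minsupp is an absolute transaction count; 0 is vacuous and clamped to 1
normalize_minsupp <- function(minsupp) {
  minsupp <- as.integer(minsupp)
  if (length(minsupp) != 1L || is.na(minsupp) || minsupp < 0L)
    stop("minsupp must be a single non-negative integer")
  if (minsupp == 0L) {
    warning("minsupp = 0 is vacuous (every support is >= 0); using minsupp = 1")
    minsupp <- 1L
  }
  minsupp
}

## ---- FP-tree ---------------------------------------------------------------

new_fp_node <- function(label, parent) {
  node <- new.env(parent = emptyenv())
  node$label <- label
  node$count <- 0
  node$parent <- parent
  node$children <- new.env(parent = emptyenv())
  node
}

fp_insert <- function(root, header, items, count) {
  node <- root
  for (it in items) {
    key <- as.character(it)
    child <- get0(key, envir = node$children, inherits = FALSE)
    if (is.null(child)) {
      child <- new_fp_node(it, node)
      assign(key, child, envir = node$children)
      chain <- get0(key, envir = header, inherits = FALSE)
      assign(key, c(chain, list(child)), envir = header)
    }
    child$count <- child$count + count
    node <- child
  }
}

# shared builder over weighted transactions: list of list(items, count)
build_tree_weighted <- function(wtrans, minsupp, m) {
  counts <- numeric(0)
  for (wt in wtrans) {
    for (it in wt$items) {
      key <- as.character(it)
      counts[key] <- (if (is.na(counts[key])) 0 else counts[key]) + wt$count
    }
  }
  counts <- counts[counts >= minsupp]
  items_int <- as.integer(names(counts))
  # decreasing support, ties broken by ascending item id, for a
  # deterministic tree shape
  ord <- order(-counts, items_int)
  item_order <- items_int[ord]
  supports <- stats::setNames(as.numeric(counts[ord]), item_order)
  rank_of <- stats::setNames(seq_along(item_order), item_order)
  root <- new_fp_node(NA_integer_, NULL)
  header <- new.env(parent = emptyenv())
  for (wt in wtrans) {
    keep <- wt$items[wt$items %in% item_order]
    if (length(keep) == 0L) next
    keep <- keep[order(rank_of[as.character(keep)])]
    fp_insert(root, header, keep, wt$count)
  }
  tree <- list(root = root, header = header, items = item_order,
               supports = supports, minsupp = minsupp, m = m)
  class(tree) <- "fp_tree"
  tree
}

#' Build an FP-tree
#'
#' Compresses the transaction database into a frequent-pattern tree: items
#' with support below `minsupp` are dropped from every transaction, the
#' remaining items of each transaction are sorted by decreasing support
#' (ties by ascending item id), and transactions are inserted along shared
#' prefixes whose node counts accumulate. Header chains link all tree nodes
#' of one item; for every retained item the counts along its chain sum to
#' its support.
#'
#' @param db a `transaction_db`.
#' @param minsupp minimum support as an absolute transaction count
#'   (`>= 1`; 0 is clamped to 1 with a warning).
#' @return an `fp_tree`: list with `root`, `header` (environment keyed by
#'   item), `items` (retained items in insertion order), `supports`,
#'   `minsupp`, `m`.
#' @export
build_fp_tree <- function(db, minsupp) {
  minsupp <- normalize_minsupp(minsupp)
  wtrans <- lapply(db$transactions, function(t) list(items = t, count = 1))
  build_tree_weighted(wtrans, minsupp, db$m)
}

#' @export
print.fp_tree <- function(x, ...) {
  cat(sprintf("<fp_tree: %d retained items, minsupp = %d, m = %d>\n",
              length(x$items), x$minsupp, x$m))
  invisible(x)
}

# header-chain counts of `item` (used by mining and the conservation tests)
header_chain_counts <- function(tree, item) {
  chain <- get0(as.character(item), envir = tree$header, inherits = FALSE)
  if (is.null(chain)) return(numeric(0))
  vapply(chain, function(nd) nd$count, numeric(1L))
}

## ---- FP-growth -------------------------------------------------------------

#' Mine frequent patterns from an FP-tree
#'
#' Recursive FP-growth: for each retained item (least-frequent first) the
#' item's header chain gives its support and its conditional pattern base
#' (the prefix paths above each of its nodes, weighted by that node's
#' count); a conditional FP-tree is built from the base and mined
#' recursively with the item appended to the suffix. With `mode = "all"`
#' every itemset of support `>= minsupp` is returned with its exact
#' support; with `mode = "maximal"` only subset-maximal itemsets survive.
#' Output is canonically ordered (descending support, then lexicographic
#' item sequence) for determinism.
#'
#' With tiny `minsupp` the number of frequent itemsets can grow
#' exponentially; mining aborts with an explicit error once more than
#' `max_patterns` itemsets have been generated.
#'
#' @param tree an [build_fp_tree()] result.
#' @param minsupp minimum support count; defaults to the tree's.
#' @param mode `"maximal"` (default) or `"all"`.
#' @param max_patterns guard on the number of generated itemsets.
#' @return a `pattern_set`: list with `patterns` (each a list of sorted
#'   `items` and `support`), `mode`, `support_mask` (sorted union of all
#'   retained patterns' items), `m`.
#' @export
fp_growth <- function(tree, minsupp = tree$minsupp,
                      mode = c("maximal", "all"), max_patterns = 1e6) {
  mode <- match.arg(mode)
  minsupp <- normalize_minsupp(minsupp)
  if (minsupp != tree$minsupp)
    stop(sprintf("tree was built at minsupp = %d but mining requested %d",
                 tree$minsupp, minsupp))
  acc <- new.env(parent = emptyenv())
  acc$patterns <- vector("list", 64L)
  acc$n <- 0L
  add_pattern <- function(items, supp) {
    if (acc$n >= max_patterns)
      stop(sprintf(
        "frequent-pattern explosion: more than %d itemsets at minsupp = %d; raise minsupp or max_patterns",
        as.integer(max_patterns), minsupp))
    acc$n <- acc$n + 1L
    if (acc$n > length(acc$patterns))
      length(acc$patterns) <- 2L * length(acc$patterns)
    acc$patterns[[acc$n]] <- list(items = sort(items), support = supp)
  }
  mine <- function(tr, suffix) {
    for (item in rev(tr$items)) {
      chain <- get0(as.character(item), envir = tr$header, inherits = FALSE)
      supp <- sum(vapply(chain, function(nd) nd$count, numeric(1L)))
      pattern <- c(suffix, item)
      add_pattern(pattern, supp)
      # conditional pattern base: prefix path above each node, weighted by
      # that node's count
      cpb <- list()
      for (nd in chain) {
        path <- integer(0)
        p <- nd$parent
        while (!is.null(p) && !is.na(p$label)) {
          path <- c(p$label, path)
          p <- p$parent
        }
        if (length(path) > 0L)
          cpb[[length(cpb) + 1L]] <- list(items = path, count = nd$count)
      }
      if (length(cpb) > 0L) {
        cond <- build_tree_weighted(cpb, tr$minsupp, tr$m)
        if (length(cond$items) > 0L) mine(cond, pattern)
      }
    }
  }
  mine(tree, integer(0))
  patterns <- acc$patterns[seq_len(acc$n)]
  # supports are integral transaction counts
  patterns <- lapply(patterns, function(p) {
    p$support <- as.integer(round(p$support)); p
  })
  if (mode == "maximal") patterns <- keep_maximal(patterns)
  pattern_set(patterns, mode = mode, m = tree$m)
}

keep_maximal <- function(patterns) {
  if (length(patterns) <= 1L) return(patterns)
  sets <- lapply(patterns, `[[`, "items")
  ord <- order(-lengths(sets))
  keep <- logical(length(patterns))
  kept_sets <- list()
  for (i in ord) {
    s <- sets[[i]]
    contained <- any(vapply(kept_sets, function(k) all(s %in% k), logical(1L)))
    if (!contained) {
      keep[i] <- TRUE
      kept_sets[[length(kept_sets) + 1L]] <- s
    }
  }
  patterns[keep]
}

pattern_key <- function(items) paste(sprintf("%08d", items), collapse = " ")

#' Assemble a pattern set
#'
#' Canonically orders mined patterns (descending support, then
#' lexicographic item sequence) and records the support mask — the union of
#' positions appearing in any retained pattern, which is the set of
#' positions the local stream pools over.
#'
#' @param patterns list of `list(items, support)`.
#' @param mode `"all"` or `"maximal"`.
#' @param m transaction count of the mined database.
#' @return a `pattern_set`.
#' @export
pattern_set <- function(patterns, mode = c("maximal", "all"), m = NA_integer_) {
  mode <- match.arg(mode)
  supp <- vapply(patterns, `[[`, numeric(1L), "support")
  keys <- vapply(patterns, function(p) pattern_key(p$items), character(1L))
  patterns <- patterns[order(-supp, keys, method = "radix")]
  out <- list(patterns = patterns, mode = mode,
              support_mask = sort(unique(unlist(lapply(patterns, `[[`, "items")))),
              m = as.integer(m))
  class(out) <- "pattern_set"
  out
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("<pattern_set: %d %s frequent pattern(s), support mask of %d position(s)>\n",
              length(x$patterns), x$mode, length(x$support_mask)))
  for (p in utils::head(x$patterns, 10L))
    cat(sprintf("  {%s}: %d\n", paste(p$items, collapse = ","), p$support))
  if (length(x$patterns) > 10L) cat("  ...\n")
  invisible(x)
}

#' @export
as.data.frame.pattern_set <- function(x, ...) {
  data.frame(items = vapply(x$patterns,
                            function(p) paste(p$items, collapse = " "),
                            character(1L)),
             support = vapply(x$patterns, `[[`, integer(1L), "support"))
}

#' Mine a transaction database in one call
#'
#' Convenience wrapper: [build_fp_tree()] followed by [fp_growth()].
#'
#' @inheritParams build_fp_tree
#' @inheritParams fp_growth
#' @param db a `transaction_db`.
#' @return a `pattern_set`.
#' @export
mine_patterns <- function(db, minsupp, mode = c("maximal", "all"),
                          max_patterns = 1e6) {
  mode <- match.arg(mode)
  minsupp <- normalize_minsupp(minsupp)
  fp_growth(build_fp_tree(db, minsupp), minsupp, mode = mode,
            max_patterns = max_patterns)
}

#' Local stream feature
#'
#' Composes the local stream: binarize each feature map at its own mean,
#' mine the maximal frequent co-activation patterns with FP-growth, and
#' max+avg pool the descriptors at the pattern support positions into the
#' `2d`-dimensional local feature `fL`. (Pooling over the union of maximal
#' patterns equals pooling over the union of all frequent patterns, since
#' every frequent itemset is contained in a maximal one.) When nothing is
#' frequent the stream falls back to full-grid pooling with a warning,
#' mirroring the global stream's degenerate case.
#'
#' @param tensor an activation tensor.
#' @param minsupp minimum support count for a co-activation pattern.
#' @param max_patterns guard passed to [fp_growth()].
#' @return numeric vector of length `2d`, stream tag `"local"`, with the
#'   pooled positions in attribute `"region"` and the mined `pattern_set`
#'   in attribute `"patterns"`.
#' @export
local_feature <- function(tensor, minsupp = 2L, max_patterns = 1e6) {
  assert_tensor(tensor)
  db <- build_transactions(tensor)
  ps <- mine_patterns(db, minsupp, mode = "maximal",
                      max_patterns = max_patterns)
  region <- ps$support_mask
  if (length(region) == 0L) {
    warning("no frequent co-activation pattern; falling back to full-grid pooling")
    region <- all_positions(tensor)
  }
  feat <- pool_region(tensor, region, stream = "local")
  attr(feat, "region") <- region
  attr(feat, "patterns") <- ps
  feat
}

## ---- text interchange ------------------------------------------------------

#' Transaction file I/O (FIMI format)
#'
#' One transaction per line, whitespace-separated integer item ids — the
#' de-facto interchange format of frequent-itemset miners, so mined results
#' can be cross-checked against standalone tools. Empty lines are empty
#' transactions.
#'
#' @param db a `transaction_db`.
#' @param path file path.
#' @return `read_transactions()` returns a `transaction_db`.
#' @export
write_transactions <- function(db, path) {
  lines <- vapply(db$transactions,
                  function(t) paste(t, collapse = " "), character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_transactions
#' @export
read_transactions <- function(path) {
  if (!file.exists(path))
    stop(sprintf("transaction file not found: '%s'", path))
  lines <- readLines(path)
  transaction_db(lapply(lines, function(l) {
    toks <- strsplit(trimws(l), "\\s+")[[1L]]
    as.integer(toks[nzchar(toks)])
  }))
}

#' Write a pattern report
#'
#' Tab-separated (`items`, `support`) in canonical order.
#'
#' @param ps a `pattern_set`.
#' @param path file path.
#' @export
write_patterns_tsv <- function(ps, path) {
  utils::write.table(as.data.frame(ps), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
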