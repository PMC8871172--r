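#' Aggregate the two stream features
#'
#' The retrieval representation is the elementwise sum `F = fG + alpha * fL`,
#' where `alpha >= 0` balances the local stream against the global one
#' (`alpha = 0` reduces to the global feature alone).
#'
#' @param fg,fl numeric vectors of equal length `2d`.
#' @param alpha non-negative weight.
#' @return numeric vector `F` with attribute `alpha`.
#' @export
aggregate_features <- function(fg, fl, alpha = 1) {
  if (length(fg) != length(fl))
    stop(sprintf("stream feature lengths differ (%d vs %d)",
                 length(fg), length(fl)))
  if (length(alpha) != 1L || is.na(alpha) || alpha < 0)
    stop("alpha must be a single non-negative number")
  v <- as.numeric(fg) + alpha * as.numeric(fl)
  attr(v, "alpha") <- alpha
  v
}

#' Cosine similarity of two features
#'
#' `S(a, b) = <a, b> / (|a| |b|)`, symmetric and invariant to positive
#' rescaling of either argument. A zero-norm feature (a degenerate image)
#' yields score 0 with a warning rather than a division by zero.
#'
#' @param a,b numeric vectors of equal length.
#' @return a number in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b))
    stop(sprintf("feature lengths differ (%d vs %d)", length(a), length(b)))
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) {
    warning("zero-norm feature; similarity defined as 0")
    return(0)
  }
  sum(a * b) / (na * nb)
}

# rows scaled to unit norm; zero rows stay zero (their similarities are 0)
normalize_rows <- function(mat) {
  norms <- sqrt(rowSums(mat * mat))
  zero <- norms == 0
  if (any(zero)) {
    warning(sprintf("%d zero-norm feature(s); their similarities are 0",
                    sum(zero)))
    norms[zero] <- 1
  }
  mat / norms
}

#' Build a retrieval index
#'
#' Computes the configured representation for every tensor in a corpus.
#' Modes mirror the four-way ablation: `"original"` is plain full-grid
#' max+avg pooling with no selection, `"global"` is the salient-region
#' feature `fG`, `"local"` the frequent-pattern feature `fL`, and
#' `"global_local"` the aggregate `fG + alpha * fL`.
#'
#' @param tensors named list of activation tensors.
#' @param labels optional named character vector of class labels (needed
#'   for evaluation).
#' @param mode representation, see above.
#' @param minsupp,alpha,connectivity,max_patterns pipeline hyperparameters.
#' @return a `retrieval_index`: list with `ids`, `labels`, `features`
#'   (`n x 2d` matrix, one row per id) and `settings`.
#' @export
build_index <- function(tensors, labels = NULL,
                        mode = c("global_local", "original", "global", "local"),
                        minsupp = 2L, alpha = 1, connectivity = 8L,
                        max_patterns = 1e6) {
  mode <- match.arg(mode)
  ids <- names(tensors)
  if (length(tensors) == 0L || is.null(ids) || anyDuplicated(ids))
    stop("tensors must be a non-empty list with unique ids")
  if (!is.null(labels)) {
    missing <- setdiff(ids, names(labels))
    if (length(missing) > 0L)
      stop(sprintf("missing label(s) for: %s", toString(missing)))
    labels <- labels[ids]
  }
  feature_of <- function(tensor) {
    switch(mode,
      original = original_feature(tensor),
      global = global_feature(tensor, connectivity),
      local = local_feature(tensor, minsupp, max_patterns),
      global_local = aggregate_features(
        global_feature(tensor, connectivity),
        local_feature(tensor, minsupp, max_patterns),
        alpha))
  }
  feats <- t(vapply(tensors, function(x) as.numeric(feature_of(x)),
                    numeric(2L * dim(tensors[[1L]])[3L])))
  rownames(feats) <- ids
  idx <- list(ids = ids, labels = labels, features = feats,
              settings = list(mode = mode, minsupp = as.integer(minsupp),
                              alpha = alpha,
                              connectivity = as.integer(connectivity)))
  class(idx) <- "retrieval_index"
  idx
}

#' @export
print.retrieval_index <- function(x, ...) {
  cat(sprintf("<retrieval_index: %d image(s), %d-dim '%s' features>\n",
              length(x$ids), ncol(x$features), x$settings$mode))
  invisible(x)
}

#' Rank an index against a query feature
#'
#' Scores every index entry by cosine similarity to the query, sorts by
#' descending score with ties broken by ascending id, and excludes the
#' query's own entry when `query_id` names one. `k` truncates the returned
#' list for display; evaluation always uses the full ranking.
#'
#' @param index a `retrieval_index`.
#' @param query numeric feature vector of the index's dimension.
#' @param query_id optional id to exclude (leave-one-out queries).
#' @param k cutoff for the returned list (default all).
#' @return data frame with columns `id`, `score`, best first.
#' @export
rank_index <- function(index, query, query_id = NULL, k = Inf) {
  if (!inherits(index, "retrieval_index")) stop("expected a retrieval_index")
  if (length(index$ids) == 0L) stop("cannot rank against an empty index")
  if (length(query) != ncol(index$features))
    stop(sprintf("query feature has %d dimensions, index has %d",
                 length(query), ncol(index$features)))
  if (k < 1) stop("k must be >= 1")
  qn <- sqrt(sum(query^2))
  if (qn == 0) {
    warning("zero-norm query feature; all similarities are 0")
    qn <- 1
  }
  scores <- as.numeric(normalize_rows(index$features) %*% (query / qn))
  keep <- if (is.null(query_id)) rep(TRUE, length(index$ids))
          else index$ids != query_id
  ids <- index$ids[keep]; scores <- scores[keep]
  ord <- order(-scores, ids, method = "radix")
  out <- data.frame(id = ids[ord], score = scores[ord])
  utils::head(out, n = min(k, nrow(out)))
}

#' Average precision of one ranked list
#'
#' `AP = (1/R) * sum_k p(k) * rel(k)` over the full ranked list, where
#' `p(k)` is the precision of the first `k` results, `rel(k)` indicates a
#' relevant item at rank `k`, and `R` is the total number of relevant
#' items. With the ranking covering the whole candidate set (the protocol
#' used here), `R` defaults to the number of relevant ids present in the
#' list. A query with no relevant item in the candidate set has undefined
#' AP and returns `NA` with a warning.
#'
#' @param ranked_ids character vector, best first.
#' @param relevant_ids character vector (or set) of relevant ids.
#' @param n_relevant optional explicit `R`.
#' @return AP in `[0, 1]`, or `NA` if `R = 0`.
#' @export
average_precision <- function(ranked_ids, relevant_ids, n_relevant = NULL) {
  rel <- as.integer(ranked_ids %in% relevant_ids)
  R <- if (is.null(n_relevant)) sum(rel) else as.integer(n_relevant)
  if (R == 0L) {
    warning("no relevant item for this query; AP undefined")
    return(NA_real_)
  }
  sum(cumsum(rel) / seq_along(rel) * rel) / R
}

#' Mean average precision
#'
#' Arithmetic mean of per-query APs; `NA` APs (queries with no relevant
#' item) are dropped with a warning.
#'
#' @param aps numeric vector of per-query APs.
#' @return mAP in `[0, 1]`.
#' @export
mean_average_precision <- function(aps) {
  bad <- is.na(aps)
  if (any(bad)) {
    warning(sprintf("dropping %d query(ies) with undefined AP", sum(bad)))
    aps <- aps[!bad]
  }
  if (length(aps) == 0L) stop("no valid query to average")
  mean(aps)
}

# leave-one-out mAP over a feature matrix (shared by evaluate_index and the
# ablation, so all modes see the identical query/database split)
eval_features <- function(features, ids, labels) {
  nmat <- normalize_rows(features)
  sim <- nmat %*% t(nmat)
  aps <- stats::setNames(numeric(length(ids)), ids)
  for (q in seq_along(ids)) {
    cand <- setdiff(seq_along(ids), q)
    scores <- sim[q, cand]
    cand_ids <- ids[cand]
    ord <- order(-scores, cand_ids, method = "radix")
    relevant <- cand_ids[labels[cand] == labels[q]]
    aps[[q]] <- average_precision(cand_ids[ord], relevant)
  }
  aps
}

#' Leave-one-out retrieval evaluation
#'
#' Uses every indexed image in turn as a query against all the others and
#' reports per-query AP plus the corpus mAP. Requires labels on the index.
#'
#' @param index a labeled `retrieval_index`.
#' @return an `eval_report`: list with `per_query_ap`, `map`, `Q`,
#'   `settings`.
#' @export
evaluate_index <- function(index) {
  if (!inherits(index, "retrieval_index")) stop("expected a retrieval_index")
  if (is.null(index$labels))
    stop("evaluation needs class labels; build the index with labels")
  if (length(unique(index$labels)) < 2L)
    warning("a single class makes every candidate relevant; mAP is trivially 1")
  aps <- eval_features(index$features, index$ids, index$labels)
  report <- list(per_query_ap = as.list(aps),
                 map = mean_average_precision(unlist(aps)),
                 Q = sum(!is.na(unlist(aps))),
                 settings = index$settings)
  class(report) <- "eval_report"
  report
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: mAP = %.4f over Q = %d queries (mode '%s')>\n",
              x$map, x$Q, x$settings$mode))
  invisible(x)
}

#' Four-way ablation
#'
#' Evaluates leave-one-out mAP for the four representations — original
#' (full-grid pooling), global stream, local stream, and the global-local
#' aggregate — on the same corpus and the same query/database split, so the
#' columns are directly comparable.
#'
#' @param tensors named list of activation tensors.
#' @param labels named character vector of class labels.
#' @inheritParams build_index
#' @return data frame with columns `mode` and `map` (four rows).
#' @export
run_ablation <- function(tensors, labels, minsupp = 2L, alpha = 1,
                         connectivity = 8L, max_patterns = 1e6) {
  ids <- names(tensors)
  d <- dim(tensors[[1L]])[3L]
  gmat <- t(vapply(tensors, function(x)
    as.numeric(global_feature(x, connectivity)), numeric(2L * d)))
  lmat <- t(vapply(tensors, function(x)
    as.numeric(local_feature(x, minsupp, max_patterns)), numeric(2L * d)))
  omat <- t(vapply(tensors, function(x)
    as.numeric(original_feature(x)), numeric(2L * d)))
  labels <- labels[ids]
  maps <- vapply(list(original = omat, global = gmat, local = lmat,
                      global_local = gmat + alpha * lmat),
                 function(mat) mean_average_precision(
                   eval_features(mat, ids, labels)),
                 numeric(1L))
  data.frame(mode = names(maps), map = unname(maps))
}
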