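#' Describe a synthetic activation scene
#'
#' A scene spec plants controlled structure into an otherwise quiet
#' activation tensor, emulating what a rectified convolutional layer
#' produces for a fine-grained image: a spatially coherent high-response
#' blob (the salient object), position sets that co-activate across a known
#' number of channels (shared parts), and sparse low-support background
#' clutter. The recorded ground truth makes mask-recovery and
#' pattern-recovery tests exact instead of probabilistic.
#'
#' @param h,w,d tensor shape.
#' @param blob `NULL` or `list(positions, level)`: flat ids of the salient
#'   footprint and the per-channel activation added there on every channel.
#'   The blob must end up strictly above the aggregation-map mean
#'   (validated after generation).
#' @param part_sets list of plants, each
#'   `list(positions, s, level, channels)`: the position set `S`
#'   co-activates at `level` in exactly `s` channels (explicit `channels`,
#'   1-based, or sampled from the unused pool). Plants must be mutually
#'   disjoint and disjoint from the blob, otherwise their supports would
#'   not be the recorded ones.
#' @param noise `NULL` or
#'   `list(level, positions_per_channel, max_support)`: background clutter
#'   placed on channels not used by any plant, drawn only from unplanted
#'   positions, with at most `max_support` placements per position — an
#'   upper bound on any noise item's support, kept below the planted
#'   supports by construction.
#' @param seed integer seed; generation is a pure function of the spec.
#' @return a `scene_spec`.
#' @export
scene_spec <- function(h, w, d, blob = NULL, part_sets = list(),
                       noise = NULL, seed = 1L) {
  h <- as.integer(h); w <- as.integer(w); d <- as.integer(d)
  if (h < 1L || w < 1L || d < 1L) stop("h, w, d must be positive")
  n_pos <- h * w
  check_positions <- function(p, what) {
    p <- as.integer(p)
    if (length(p) == 0L || anyNA(p) || any(p < 0L) || any(p >= n_pos))
      stop(sprintf("%s positions must be flat ids in [0, %d)", what, n_pos))
    if (anyDuplicated(p)) stop(sprintf("%s positions must be distinct", what))
    sort(p)
  }
  if (!is.null(blob)) {
    blob$positions <- check_positions(blob$positions, "blob")
    if (is.null(blob$level)) blob$level <- 6
    if (blob$level <= 0) stop("blob level must be positive")
  }
  used <- if (is.null(blob)) integer(0) else blob$positions
  taken_channels <- integer(0)
  part_sets <- lapply(seq_along(part_sets), function(i) {
    ps <- part_sets[[i]]
    ps$positions <- check_positions(ps$positions, sprintf("part set %d", i))
    if (any(ps$positions %in% used))
      stop(sprintf("part set %d overlaps another plant", i))
    used <<- c(used, ps$positions)
    ps$s <- as.integer(ps$s)
    if (is.na(ps$s) || ps$s < 1L) stop("a part set needs s >= 1 channels")
    if (is.null(ps$level)) ps$level <- 10
    if (!is.null(ps$channels)) {
      ps$channels <- as.integer(ps$channels)
      if (length(ps$channels) != ps$s || any(ps$channels < 1L) ||
          any(ps$channels > d))
        stop(sprintf("part set %d: channels must be %d indices in [1, %d]",
                     i, ps$s, d))
      if (any(ps$channels %in% taken_channels))
        stop(sprintf("part set %d reuses a planted channel", i))
      taken_channels <<- c(taken_channels, ps$channels)
    }
    ps
  })
  total_s <- sum(vapply(part_sets, `[[`, integer(1L), "s"))
  if (total_s > d)
    stop(sprintf("part sets need %d channels but the tensor has d = %d",
                 total_s, d))
  if (!is.null(noise)) {
    if (is.null(noise$level)) noise$level <- 0.3
    if (is.null(noise$positions_per_channel)) noise$positions_per_channel <- 3L
    if (is.null(noise$max_support)) noise$max_support <- 1L
    if (noise$level < 0) stop("noise level must be non-negative")
  }
  spec <- list(h = h, w = w, d = d, blob = blob, part_sets = part_sets,
               noise = noise, seed = as.integer(seed))
  class(spec) <- "scene_spec"
  spec
}

#' Generate an activation tensor from a scene spec
#'
#' Deterministic given the spec (including its seed). The returned tensor
#' carries a `ground_truth` attribute recording the blob footprint, each
#' plant's positions, channels and support, and the noise placements, so
#' tests can assert recovery exactly.
#'
#' @param spec a [scene_spec()].
#' @return an `activation_tensor` with attribute `ground_truth`.
#' @export
generate_tensor <- function(spec) {
  if (!inherits(spec, "scene_spec")) stop("expected a scene_spec")
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)
  h <- spec$h; w <- spec$w; d <- spec$d
  x <- array(0, c(h, w, d))
  cell <- function(flat) flat_to_rowcol(flat, w) + 1L   # 1-based (row, col)
  # channel assignment: explicit channels first, then sampled from the pool
  pool <- setdiff(seq_len(d),
                  unlist(lapply(spec$part_sets, `[[`, "channels")))
  parts_gt <- list()
  for (i in seq_along(spec$part_sets)) {
    ps <- spec$part_sets[[i]]
    chans <- ps$channels
    if (is.null(chans)) {
      chans <- if (length(pool) == 1L) pool else sort(sample(pool, ps$s))
      pool <- setdiff(pool, chans)
    }
    rc <- cell(ps$positions)
    for (ch in chans)
      x[cbind(rc, ch)] <- ps$level
    parts_gt[[i]] <- list(positions = ps$positions, s = ps$s,
                          channels = sort(chans), level = ps$level)
  }
  if (!is.null(spec$blob)) {
    rc <- cell(spec$blob$positions)
    for (ch in seq_len(d))
      x[cbind(rc, ch)] <- x[cbind(rc, ch)] + spec$blob$level
  }
  # background clutter may fall on any channel: a clutter cell only adds an
  # item whose support is capped at max_support placements, so it can never
  # reach a mining threshold above that cap; it is kept off planted
  # positions so recorded plant supports stay exact
  noise_gt <- NULL
  if (!is.null(spec$noise) && spec$noise$level > 0) {
    planted <- c(if (is.null(spec$blob)) integer(0) else spec$blob$positions,
                 unlist(lapply(spec$part_sets, `[[`, "positions")))
    eligible <- setdiff(seq_len(h * w) - 1L, planted)
    counts <- stats::setNames(integer(length(eligible)), eligible)
    placements <- list()
    for (ch in sample(d)) {
      open <- as.integer(names(counts)[counts < spec$noise$max_support])
      if (length(open) == 0L) break
      k <- min(spec$noise$positions_per_channel, length(open))
      pick <- if (length(open) == 1L) open else sample(open, k)
      rc <- cell(pick)
      x[cbind(rc, ch)] <- x[cbind(rc, ch)] +
        stats::runif(length(pick), spec$noise$level / 2, spec$noise$level)
      counts[as.character(pick)] <- counts[as.character(pick)] + 1L
      placements[[length(placements) + 1L]] <-
        list(channel = ch, positions = sort(pick))
    }
    noise_gt <- list(placements = placements, counts = counts)
  }
  if (!is.null(spec$blob)) {
    A <- rowSums(matrix(x, nrow = h * w))           # column-major flat sums
    rc <- cell(spec$blob$positions)
    blob_cm <- (rc[, 2L] - 1L) * h + rc[, 1L]
    if (min(A[blob_cm]) <= mean(A))
      stop("blob level too low: footprint does not exceed the aggregation-map mean")
  }
  out <- activation_tensor(x)
  attr(out, "ground_truth") <- list(blob = spec$blob, parts = parts_gt,
                                    noise = noise_gt)
  out
}

#' Generate a labeled synthetic retrieval corpus
#'
#' Classes share the salient-blob statistics and the background-noise
#' distribution and differ only in their planted part co-activation sets
#' (disjoint position sets on class-specific channel blocks), realizing in
#' controllable form the fine-grained regime of small interclass
#' distinction and large intraclass variance. Per-image variation comes
#' from blob translation, plant-level jitter, and resampled noise.
#'
#' Background clutter dominates the raw pooled representation (as real
#' backgrounds do — the object occupies a minority of spatial cells), so
#' mining at a `minsupp` above the clutter support cap is what separates
#' the streams from plain pooling; with the defaults any
#' `minsupp > noise_max_support = 3` does.
#'
#' @param n_classes,n_per_class corpus layout (both `>= 2`).
#' @param shape tensor shape `c(h, w, d)`.
#' @param seed corpus seed; per-image seeds are derived from it.
#' @param part_size positions per class part set.
#' @param s channels co-activated by each class's part set.
#' @param part_level,blob_level,noise_level activation levels.
#' @param noise_positions_per_channel,noise_max_support clutter density and
#'   the per-position placement cap (an upper bound on any clutter item's
#'   support).
#' @return a `synthetic_corpus`: list with `tensors` (named list), `labels`
#'   (named character vector), `class_specs`.
#' @export
generate_corpus <- function(n_classes = 4L, n_per_class = 5L,
                            shape = c(7L, 7L, 64L), seed = 1L,
                            part_size = 4L, s = 8L,
                            part_level = 10, blob_level = 3,
                            noise_level = 15,
                            noise_positions_per_channel = 3L,
                            noise_max_support = 3L) {
  n_classes <- as.integer(n_classes); n_per_class <- as.integer(n_per_class)
  if (n_classes < 2L || n_per_class < 2L)
    stop("need at least 2 classes and 2 images per class")
  h <- as.integer(shape[1L]); w <- as.integer(shape[2L])
  d <- as.integer(shape[3L])
  if (n_classes * s > d)
    stop(sprintf("%d classes x %d channels exceed d = %d", n_classes, s, d))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  # shared blob: a centered rectangle, jittered per image by +-1 cell
  blob_rows <- floor(h / 2) + (-1L:0L)
  blob_cols <- floor(w / 2) + (-1L:1L)
  blob_base <- as.integer(outer(blob_rows * w, blob_cols, `+`))
  open_pos <- setdiff(seq_len(h * w) - 1L, blob_base)
  if (length(open_pos) < n_classes * part_size)
    stop("cannot pack disjoint part sets outside the blob; enlarge the grid")
  part_pos <- sample(open_pos, n_classes * part_size)
  chan_perm <- sample(d)
  n_img <- n_classes * n_per_class
  img_seeds <- sample.int(.Machine$integer.max - 1L, n_img)
  offsets <- expand.grid(dr = -1L:1L, dc = -1L:1L)
  off_u <- stats::runif(n_img)
  lvl_jit <- stats::runif(n_img, 0.9, 1.1)
  blvl_jit <- stats::runif(n_img, 0.8, 1.2)
  class_specs <- list()
  tensors <- list()
  labels <- character(0)
  idx <- 0L
  for (k in seq_len(n_classes)) {
    cls <- sprintf("class%02d", k)
    S <- sort(part_pos[((k - 1L) * part_size + 1L):(k * part_size)])
    chans <- sort(chan_perm[((k - 1L) * s + 1L):(k * s)])
    class_specs[[cls]] <- list(positions = S, channels = chans)
    # translation jitter may not push the blob off-grid or onto this
    # class's part positions
    rc <- flat_to_rowcol(blob_base, w)
    valid_offs <- which(apply(offsets, 1L, function(o) {
      rr <- rc[, "row"] + o[["dr"]]; cc <- rc[, "col"] + o[["dc"]]
      all(rr >= 0L & rr < h & cc >= 0L & cc < w) &&
        !any((rr * w + cc) %in% S)
    }))
    for (j in seq_len(n_per_class)) {
      idx <- idx + 1L
      off <- offsets[valid_offs[max(1L, ceiling(off_u[idx] *
                                                  length(valid_offs)))], ]
      blob_j <- sort((rc[, "row"] + off$dr) * w + (rc[, "col"] + off$dc))
      lvl <- part_level * lvl_jit[idx]
      blvl <- blob_level * blvl_jit[idx]
      spec <- scene_spec(h, w, d,
                         blob = list(positions = blob_j, level = blvl),
                         part_sets = list(list(positions = S, s = s,
                                               level = lvl,
                                               channels = chans)),
                         noise = list(level = noise_level,
                                      positions_per_channel =
                                        noise_positions_per_channel,
                                      max_support = noise_max_support),
                         seed = img_seeds[idx])
      id <- sprintf("%s_img%02d", cls, j)
      tensors[[id]] <- generate_tensor(spec)
      labels[id] <- cls
    }
  }
  corpus <- list(tensors = tensors, labels = labels,
                 class_specs = class_specs,
                 shape = c(h, w, d), seed = as.integer(seed))
  class(corpus) <- "synthetic_corpus"
  corpus
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic_corpus: %d image(s), %d class(es), %d x %d x %d tensors>\n",
              length(x$tensors), length(unique(x$labels)),
              x$shape[1L], x$shape[2L], x$shape[3L]))
  invisible(x)
}

#' Brute-force frequent-itemset oracle
#'
#' Enumerates every non-empty subset of the item universe and counts its
#' containment support directly — exponential, so restricted to universes
#' of at most 20 items. This is the independent ground truth that the
#' FP-growth miner is checked against.
#'
#' @param db a `transaction_db` with at most 20 distinct items.
#' @param minsupp minimum support count.
#' @param mode `"all"` (default here) or `"maximal"`.
#' @return a `pattern_set` in canonical order.
#' @export
brute_force_patterns <- function(db, minsupp, mode = c("all", "maximal")) {
  mode <- match.arg(mode)
  minsupp <- normalize_minsupp(minsupp)
  universe <- db$items
  n <- length(universe)
  if (n > 20L)
    stop(sprintf("brute-force enumeration refuses %d items (max 20)", n))
  patterns <- list()
  if (n > 0L) {
    # membership matrix: m x n, TRUE where transaction contains item
    memb <- vapply(universe,
                   function(it) vapply(db$transactions,
                                       function(t) it %in% t, logical(1L)),
                   logical(db$m))
    memb <- matrix(memb, nrow = db$m, ncol = n)
    for (k in seq_len(n)) {
      combos <- utils::combn(n, k)
      for (ci in seq_len(ncol(combos))) {
        cols <- combos[, ci]
        supp <- sum(rowSums(memb[, cols, drop = FALSE]) == k)
        if (supp >= minsupp)
          patterns[[length(patterns) + 1L]] <-
            list(items = universe[cols], support = as.integer(supp))
      }
    }
  }
  if (mode == "maximal") patterns <- keep_maximal(patterns)
  pattern_set(patterns, mode = mode, m = db$m)
}
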