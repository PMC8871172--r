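#' Channel-summed aggregation map
#'
#' Sums the activation tensor across its `d` channels, producing the
#' `h x w` aggregation map. A spatial position where many channels fire is
#' likely to lie on the object, so the map's mean value serves as the
#' saliency threshold `delta`.
#'
#' @param tensor an activation tensor.
#' @return an `aggregation_map`: list with `values` (`h x w` matrix of
#'   per-position channel sums) and `mean` (scalar threshold `delta`).
#' @export
compute_aggregation_map <- function(tensor) {
  assert_tensor(tensor)
  dm <- dim(tensor)
  values <- matrix(rowSums(matrix(unclass(tensor), nrow = dm[1L] * dm[2L])),
                   nrow = dm[1L], ncol = dm[2L])
  out <- list(values = values, mean = mean(values))
  class(out) <- "aggregation_map"
  out
}

#' Mean-threshold mask map
#'
#' Binarizes the aggregation map with a strict comparison against its mean:
#' position `(i, j)` is selected iff `A[i, j] > delta`. Strictness means a
#' constant map yields an all-zero mask (the degenerate case handled by the
#' full-grid fallback downstream).
#'
#' @param agg an [compute_aggregation_map()] result, or a plain `h x w`
#'   numeric matrix (then `delta` is its mean).
#' @return integer `h x w` matrix of 0/1.
#' @export
threshold_mask <- function(agg) {
  if (is.matrix(agg)) agg <- list(values = agg, mean = mean(agg))
  if (is.null(agg$values) || is.null(agg$mean))
    stop("expected an aggregation_map (values + mean)")
  mask <- (agg$values > agg$mean) * 1L
  mode(mask) <- "integer"
  mask
}

neighbor_offsets <- function(connectivity) {
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8")
  if (connectivity == 4L)
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  else
    cbind(dr = c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
          dc = c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))
}

#' Largest connected component of a binary mask
#'
#' Flood-fills the mask and returns the maximum-cardinality connected
#' component of 1-cells, taken as the salient object's footprint. Seeds are
#' visited in ascending flat-id order, so when two components tie in size
#' the one containing the smallest flat id wins (deterministic tie-break).
#'
#' @param mask integer/logical `h x w` matrix.
#' @param connectivity neighborhood: 8 (default, includes diagonals) or 4.
#' @return sorted integer vector of 0-based row-major flat ids; `integer(0)`
#'   when the mask has no 1-cells (callers apply the full-grid fallback).
#' @export
largest_component <- function(mask, connectivity = 8L) {
  if (!is.matrix(mask)) stop("mask must be an h x w matrix")
  offs <- neighbor_offsets(as.integer(connectivity))
  h <- nrow(mask); w <- ncol(mask)
  on <- mask > 0
  visited <- matrix(FALSE, h, w)
  # cells in ascending flat-id (row-major) order
  ord <- order(((which(on) - 1L) %% h) * w + (which(on) - 1L) %/% h)
  seeds <- which(on)[ord]
  best <- integer(0)
  for (seed in seeds) {
    si <- (seed - 1L) %% h + 1L; sj <- (seed - 1L) %/% h + 1L
    if (visited[si, sj]) next
    queue <- matrix(c(si, sj), ncol = 2L)
    visited[si, sj] <- TRUE
    comp <- integer(0)
    while (nrow(queue) > 0L) {
      i <- queue[1L, 1L]; j <- queue[1L, 2L]
      queue <- queue[-1L, , drop = FALSE]
      comp <- c(comp, (i - 1L) * w + (j - 1L))
      for (k in seq_len(nrow(offs))) {
        ni <- i + offs[k, 1L]; nj <- j + offs[k, 2L]
        if (ni >= 1L && ni <= h && nj >= 1L && nj <= w &&
            on[ni, nj] && !visited[ni, nj]) {
          visited[ni, nj] <- TRUE
          queue <- rbind(queue, c(ni, nj))
        }
      }
    }
    if (length(comp) > length(best)) best <- comp
  }
  sort(as.integer(best))
}

#' Global stream feature
#'
#' Composes the global stream: aggregation map, strict mean-threshold mask,
#' largest connected component, and max+avg pooling of the selected
#' descriptors into the `2d`-dimensional global feature `fG`. When the mask
#' is empty (e.g. a constant tensor) the stream degrades gracefully to
#' pooling over the whole grid, with a warning — i.e. to the unselected
#' "original" representation.
#'
#' @param tensor an activation tensor.
#' @param connectivity passed to [largest_component()].
#' @return numeric vector of length `2d` (max half then avg half), stream
#'   tag `"global"`, with the selected region (flat ids) in attribute
#'   `"region"`.
#' @export
global_feature <- function(tensor, connectivity = 8L) {
  assert_tensor(tensor)
  agg <- compute_aggregation_map(tensor)
  region <- largest_component(threshold_mask(agg), connectivity)
  if (length(region) == 0L) {
    warning("empty saliency mask; falling back to full-grid pooling")
    region <- all_positions(tensor)
  }
  feat <- pool_region(tensor, region, stream = "global")
  attr(feat, "region") <- region
  feat
}

#' Tabulate a salient region
#'
#' One-row summary (id, region size, bounding box) used by the index
#' command's region report.
#'
#' @param region integer vector of flat ids.
#' @param w grid width.
#' @param id image id.
#' @return a one-row data frame.
#' @export
region_report <- function(region, w, id = NA_character_) {
  if (length(region) == 0L)
    return(data.frame(id = id, size = 0L, row_min = NA_integer_,
                      row_max = NA_integer_, col_min = NA_integer_,
                      col_max = NA_integer_))
  rc <- flat_to_rowcol(region, w)
  data.frame(id = id, size = length(region),
             row_min = min(rc[, "row"]), row_max = max(rc[, "row"]),
             col_min = min(rc[, "col"]), col_max = max(rc[, "col"]))
}
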