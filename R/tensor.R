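#' Construct and validate an activation tensor
#'
#' An activation tensor is the `h x w x d` array of rectified (hence
#' non-negative) responses a convolutional layer produces for one image:
#' `d` feature maps of size `h x w`, or equivalently `h*w` deep descriptors
#' of dimension `d`. All downstream stages of the pipeline operate on this
#' container, so its invariants (3-d, finite, non-negative) are enforced
#' here, at the boundary, and assumed afterwards.
#'
#' @param values numeric 3-d array, `h x w x d`.
#' @return the validated array with class `"activation_tensor"`. Any
#'   attributes already on `values` (e.g. generator ground truth) are kept.
#' @examples
#' x <- activation_tensor(array(runif(2 * 3 * 4), c(2, 3, 4)))
#' dim(x)
#' @export
activation_tensor <- function(values) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("an activation tensor must be a 3-d array (h x w x d)")
  if (!is.numeric(values))
    stop("activation tensor entries must be numeric")
  if (anyNA(values) || any(!is.finite(values)))
    stop("activation tensor entries must be finite")
  if (any(values < 0))
    stop("activation tensor entries must be non-negative (post-rectification)")
  storage.mode(values) <- "double"
  class(values) <- c("activation_tensor", class(values))
  values
}

# cheap structural check for internal use; full validation happens in
# activation_tensor() at construction
assert_tensor <- function(tensor) {
  if (!is.array(tensor) || length(dim(tensor)) != 3L)
    stop("expected an h x w x d activation tensor")
  invisible(tensor)
}

#' @export
print.activation_tensor <- function(x, ...) {
  dm <- dim(x)
  cat(sprintf("<activation_tensor %d x %d x %d (h x w x d)>\n",
              dm[1L], dm[2L], dm[3L]))
  cat(sprintf("  range [%g, %g], mean %g\n", min(x), max(x), mean(x)))
  invisible(x)
}

#' Spatial position bookkeeping
#'
#' Spatial cells are addressed by 0-based `(row, col)` pairs or by a 0-based
#' row-major flat id, `flat = row * w + col`. The flat id is the item
#' identity used by the local (pattern-mining) stream, so the mapping is
#' bijective and fixed package-wide.
#'
#' @param row,col 0-based integer position indices.
#' @param flat 0-based row-major flat id(s).
#' @param w grid width (number of columns).
#' @return `flat_id()` returns the flat id(s); `flat_to_rowcol()` returns an
#'   integer matrix with columns `row` and `col`.
#' @examples
#' flat_id(1, 2, w = 7)        # 9
#' flat_to_rowcol(9, w = 7)    # row 1, col 2
#' @export
flat_id <- function(row, col, w) {
  as.integer(row) * as.integer(w) + as.integer(col)
}

#' @rdname flat_id
#' @export
flat_to_rowcol <- function(flat, w) {
  flat <- as.integer(flat)
  w <- as.integer(w)
  cbind(row = flat %/% w, col = flat %% w)
}

#' Read the deep descriptor at one spatial position
#'
#' Each spatial cell of an activation tensor holds a d-dimensional deep
#' descriptor (the channel values at that cell).
#'
#' @param tensor an activation tensor (`h x w x d` array).
#' @param row,col 0-based position indices.
#' @return numeric vector of length `d`.
#' @export
descriptor_at <- function(tensor, row, col) {
  assert_tensor(tensor)
  dm <- dim(tensor)
  if (length(row) != 1L || length(col) != 1L || is.na(row) || is.na(col) ||
      row < 0 || row >= dm[1L] || col < 0 || col >= dm[2L])
    stop(sprintf("position (%s, %s) out of bounds for a %d x %d grid",
                 toString(row), toString(col), dm[1L], dm[2L]))
  as.numeric(tensor[row + 1L, col + 1L, ])
}

# View the tensor as an (h*w) x d descriptor matrix whose row r holds the
# descriptor with flat id r - 1 (row-major order).
descriptors_matrix <- function(tensor) {
  dm <- dim(tensor)
  matrix(aperm(unclass(tensor), c(2L, 1L, 3L)),
         nrow = dm[1L] * dm[2L], ncol = dm[3L])
}

#' Max+avg pooling of descriptors over a spatial region
#'
#' Pools the deep descriptors at the given positions into a `2d`-dimensional
#' stream feature: the first `d` entries are the per-channel maximum over the
#' region, the last `d` the per-channel average. This is the pooling applied
#' to the salient region (global stream) and to the frequent-pattern support
#' positions (local stream).
#'
#' @param tensor an activation tensor.
#' @param region integer vector of 0-based row-major flat ids; must be
#'   non-empty (callers apply the full-grid fallback before pooling).
#' @param stream tag recorded on the result, one of `"global"`, `"local"`,
#'   `"original"`.
#' @return numeric vector of length `2d` with attribute `stream`.
#' @export
pool_region <- function(tensor, region, stream = "global") {
  assert_tensor(tensor)
  dm <- dim(tensor)
  n_pos <- dm[1L] * dm[2L]
  region <- as.integer(region)
  if (length(region) == 0L)
    stop("cannot pool an empty region; apply the full-grid fallback first")
  if (anyNA(region) || any(region < 0L) || any(region >= n_pos))
    stop("region contains flat ids outside [0, h*w)")
  mat <- descriptors_matrix(tensor)[region + 1L, , drop = FALSE]
  feat <- c(apply(mat, 2L, max), colMeans(mat))
  attr(feat, "stream") <- stream
  feat
}

all_positions <- function(tensor) {
  dm <- dim(tensor)
  seq_len(dm[1L] * dm[2L]) - 1L
}

#' Full-grid pooled feature (no descriptor selection)
#'
#' The `2d`-dimensional max+avg pooled feature over every spatial position,
#' i.e. plain pooling of the raw activation tensor with no saliency or
#' pattern selection. This is the "original" representation in the four-way
#' ablation.
#'
#' @inheritParams pool_region
#' @return numeric vector of length `2d`, stream tag `"original"`.
#' @export
original_feature <- function(tensor) {
  pool_region(tensor, all_positions(tensor), stream = "original")
}
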