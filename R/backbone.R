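#' Load and standardize a raster image
#'
#' Decodes a PNG/JPEG/TIFF file, resizes it to `input_side x input_side`
#' with bilinear interpolation (plain resize, no aspect-ratio preservation
#' or cropping), and replicates grayscale to three channels.
#'
#' Requires the `EBImage` package for decoding and resizing.
#'
#' @param path path to an image file.
#' @param input_side target side length in pixels (default 224, the input
#'   size of the convolutional backbones this pipeline assumes).
#' @param id image id; defaults to the file name without extension.
#' @return an `image_record`: list with `id`, `pixels`
#'   (`input_side x input_side x 3` array in `[0, 1]`), `label` (`NA`).
#' @export
load_image <- function(path, input_side = 224L, id = NULL) {
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("load_image() requires the EBImage package")
  if (!file.exists(path))
    stop(sprintf("cannot read image '%s': no such file", path))
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e)
                    stop(sprintf("failed to decode image '%s': %s",
                                 path, conditionMessage(e)), call. = FALSE))
  img <- EBImage::resize(img, w = input_side, h = input_side)
  px <- EBImage::imageData(img)
  if (length(dim(px)) == 2L) {                       # grayscale -> 3 channels
    px <- array(rep(px, 3L), c(dim(px), 3L))
  } else if (dim(px)[3L] > 3L) {                     # drop alpha
    px <- px[, , 1:3, drop = FALSE]
  } else if (dim(px)[3L] == 1L) {
    px <- array(rep(px, 3L), c(dim(px)[1:2], 3L))
  }
  # EBImage stores x (column) first; transpose to row x col
  px <- aperm(px, c(2L, 1L, 3L))
  px[px < 0] <- 0; px[px > 1] <- 1
  record <- list(id = if (is.null(id)) sub("\\.[^.]*$", "", basename(path)) else id,
                 pixels = px, label = NA_character_)
  class(record) <- "image_record"
  record
}

#' Describe a convolutional backbone
#'
#' The feature extractor is a pluggable adapter: any callable that maps a
#' standardized image to a fixed-shape non-negative activation tensor can
#' stand behind the pipeline (the reference configuration is the last
#' pooling layer of a VGG-16-class network, 7 x 7 x 512 for 224 x 224
#' input). Two adapters ship with the package:
#'
#' * `"synthetic"`: a weight-free deterministic extractor — per-block
#'   response statistics on a `grid x grid` partition of the image passed
#'   through a fixed random-seeded filter bank followed by rectification —
#'   so the whole pipeline runs without downloaded weights;
#' * `"store"`: a pass-through that looks each image id up in a list of
#'   precomputed activation tensors (the primary test path).
#'
#' @param name adapter name, `"synthetic"` or `"store"`.
#' @param layer tapped-layer label, recorded for provenance.
#' @param input_side expected image side in pixels.
#' @param grid,d spatial extent and channel count of the output tensor
#'   (synthetic adapter).
#' @param seed integer seed of the synthetic adapter's filter bank; the bank
#'   is a function of the seed only, never of the data.
#' @param tensors named list of precomputed tensors (store adapter).
#' @param deterministic flag recorded on the spec; both shipped adapters
#'   are deterministic.
#' @return a `backbone_spec` object.
#' @export
backbone_spec <- function(name = c("synthetic", "store"),
                          layer = "pool5",
                          input_side = 224L,
                          grid = 7L, d = 64L, seed = 1L,
                          tensors = NULL,
                          deterministic = TRUE) {
  name <- match.arg(name)
  if (name == "store" && (is.null(tensors) || is.null(names(tensors))))
    stop("a 'store' backbone spec needs a named list of tensors")
  spec <- list(name = name, layer = layer,
               input_side = as.integer(input_side),
               grid = as.integer(grid), d = as.integer(d),
               seed = as.integer(seed), tensors = tensors,
               deterministic = isTRUE(deterministic))
  class(spec) <- "backbone_spec"
  spec
}

# resolve a backbone_spec into image_record -> activation_tensor
resolve_backbone <- function(spec) {
  if (!inherits(spec, "backbone_spec"))
    stop("unresolvable backbone spec: expected a backbone_spec object")
  switch(spec$name,
    store = function(image) {
      x <- spec$tensors[[image$id]]
      if (is.null(x))
        stop(sprintf("store backbone has no tensor for id '%s'", image$id))
      activation_tensor(x)
    },
    synthetic = function(image) synthetic_backbone(image, spec),
    stop(sprintf("unresolvable backbone spec '%s'", spec$name))
  )
}

# Weight-free deterministic extractor: partition the image into grid x grid
# blocks, summarize each block with 12 response statistics (per-channel mean,
# spread, horizontal and vertical gradient energy), project through a fixed
# seeded Gaussian filter bank and rectify. Pooling over each block plus the
# final max(0, .) mimics the non-negative, spatially pooled statistics of a
# real rectified convolutional layer.
synthetic_backbone <- function(image, spec) {
  px <- image$pixels
  side <- dim(px)[1L]
  g <- spec$grid
  bounds <- round(seq(0L, side, length.out = g + 1L))
  stats_block <- function(block) {
    mu <- apply(block, 3L, mean)
    sd3 <- apply(block, 3L, stats::sd)
    gh <- apply(block, 3L, function(ch) mean(abs(diff(t(ch)))))
    gv <- apply(block, 3L, function(ch) mean(abs(diff(ch))))
    c(mu, sd3, gh, gv)
  }
  feats <- matrix(0, nrow = g * g, ncol = 12L)
  k <- 1L
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      block <- px[(bounds[i] + 1L):bounds[i + 1L],
                  (bounds[j] + 1L):bounds[j + 1L], , drop = FALSE]
      feats[k, ] <- stats_block(block)
      k <- k + 1L
    }
  }
  feats[is.na(feats)] <- 0
  bank <- filter_bank(spec$seed, 12L, spec$d)
  act <- pmax(feats %*% bank, 0)
  # rows of `feats` walk (i, j) in row-major order over the grid
  tensor <- array(0, c(g, g, spec$d))
  for (ch in seq_len(spec$d))
    tensor[, , ch] <- matrix(act[, ch], nrow = g, ncol = g, byrow = TRUE)
  activation_tensor(tensor)
}

filter_bank <- function(seed, n_in, n_out) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  matrix(stats::rnorm(n_in * n_out), nrow = n_in, ncol = n_out)
}

#' Extract the activation tensor of one image
#'
#' Resolves the backbone spec and applies it, enforcing the activation
#' tensor contract (fixed shape, finite, non-negative) on the adapter's
#' output.
#'
#' @param image an `image_record` (for the store adapter only `id` is used).
#' @param spec a [backbone_spec()].
#' @return an `activation_tensor`.
#' @export
extract_activations <- function(image, spec) {
  fn <- resolve_backbone(spec)
  out <- fn(image)
  tryCatch(activation_tensor(unclass(out)),
           error = function(e)
             stop(sprintf("backbone '%s' violated the activation contract: %s",
                          spec$name, conditionMessage(e)), call. = FALSE))
}
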