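#' Lossless plain-text tensor store
#'
#' Persists a named collection of activation tensors to a single text file
#' and reads it back bit-exactly. Values are written with 17 significant
#' digits, which round-trips IEEE doubles exactly, so
#' `read_tensor_store(write_tensor_store(x))` reproduces every id, shape and
#' value.
#'
#' File layout: a version line, then per tensor a header line
#' `@<TAB>id<TAB>h<TAB>w<TAB>d` followed by one line of `h*w*d`
#' space-separated values in R's native column-major order.
#'
#' @param tensors named list of activation tensors; names are the image ids
#'   and must be unique and non-empty.
#' @param path file path.
#' @return `write_tensor_store()` returns `path` invisibly;
#'   `read_tensor_store()` returns a named list of activation tensors.
#' @export
write_tensor_store <- function(tensors, path) {
  if (!is.list(tensors))
    stop("tensors must be a named list of activation tensors")
  ids <- names(tensors)
  if (length(tensors) > 0L &&
      (is.null(ids) || any(!nzchar(ids)) || anyNA(ids)))
    stop("every tensor must have a non-empty id (list name)")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate tensor id(s): %s",
                 toString(unique(ids[duplicated(ids)]))))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("fgir-tensor-store\t1", con)
  for (id in ids) {
    x <- tensors[[id]]
    assert_tensor(x)
    dm <- dim(x)
    writeLines(paste("@", id, dm[1L], dm[2L], dm[3L], sep = "\t"), con)
    writeLines(paste(sprintf("%.17g", as.vector(x)), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_tensor_store
#' @export
read_tensor_store <- function(path) {
  if (!file.exists(path))
    stop(sprintf("tensor store not found: '%s'", path))
  lines <- readLines(path)
  if (length(lines) < 1L || !startsWith(lines[[1L]], "fgir-tensor-store"))
    stop(sprintf("'%s' is not a tensor store (bad magic line)", path))
  out <- list()
  i <- 2L
  while (i <= length(lines)) {
    header <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(header) != 5L || header[[1L]] != "@")
      stop(sprintf("corrupt tensor store '%s' at line %d", path, i))
    id <- header[[2L]]
    dm <- as.integer(header[3:5])
    vals <- as.double(strsplit(lines[[i + 1L]], " ", fixed = TRUE)[[1L]])
    if (length(vals) != prod(dm))
      stop(sprintf("corrupt tensor store '%s': tensor '%s' has %d values, expected %d",
                   path, id, length(vals), prod(dm)))
    out[[id]] <- activation_tensor(array(vals, dm))
    i <- i + 2L
  }
  out
}

#' Read and write id/label tables
#'
#' Two-column tab-separated sidecar (`id`, `label`) used next to tensor and
#' index stores.
#'
#' @param labels named character vector (names are ids).
#' @param path file path.
#' @return `read_labels_tsv()` returns a named character vector.
#' @export
write_labels_tsv <- function(labels, path) {
  df <- data.frame(id = names(labels), label = as.character(labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels_tsv
#' @export
read_labels_tsv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("label table not found: '%s'", path))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  stats::setNames(df$label, df$id)
}
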