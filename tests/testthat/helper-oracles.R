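# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals they check.

# Connected components by iterative label propagation: every 1-cell starts
# with a unique label and repeatedly adopts the minimum label in its
# neighborhood until a fixpoint. Returns a list of components (sorted
# 0-based row-major flat ids), largest first, ties by smallest flat id.
label_prop_components <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(NA_integer_, h, w)
  lab[mask > 0] <- seq_len(sum(mask > 0))
  offs <- if (connectivity == 4L)
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
          c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  repeat {
    changed <- FALSE
    for (i in seq_len(h)) for (j in seq_len(w)) {
      if (is.na(lab[i, j])) next
      for (k in seq_len(nrow(offs))) {
        ni <- i + offs[k, 1]; nj <- j + offs[k, 2]
        if (ni >= 1 && ni <= h && nj >= 1 && nj <= w && !is.na(lab[ni, nj]) &&
            lab[ni, nj] < lab[i, j]) {
          lab[i, j] <- lab[ni, nj]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  comps <- list()
  for (lv in unique(lab[!is.na(lab)])) {
    cm <- which(lab == lv)
    flat <- sort(((cm - 1L) %% h) * w + (cm - 1L) %/% h)
    comps[[length(comps) + 1L]] <- flat
  }
  if (length(comps) == 0L) return(comps)
  sizes <- lengths(comps)
  mins <- vapply(comps, min, integer(1L))
  comps[order(-sizes, mins)]
}

# Average precision by explicit cumulative-hit accumulation: walk the
# ranking, and at every relevant rank add precision-so-far; divide by R.
ap_cumulative_hits <- function(rel, R = sum(rel)) {
  if (R == 0) return(NA_real_)
  hits <- 0
  acc <- 0
  for (k in seq_along(rel)) {
    if (rel[k] == 1) {
      hits <- hits + 1
      acc <- acc + hits / k
    }
  }
  acc / R
}

# Random transaction database over items 0..(n_items-1); transactions may
# be empty.
random_db <- function(m, n_items, p = 0.4) {
  transaction_db(lapply(seq_len(m), function(i) {
    keep <- stats::runif(n_items) < p
    (seq_len(n_items) - 1L)[keep]
  }))
}

# data.frame fingerprint of a pattern set (items + supports, canonical order)
pattern_df <- function(ps) {
  df <- as.data.frame(ps)
  rownames(df) <- NULL
  df
}

# small random mask
random_mask <- function(h, w, p = 0.45) {
  matrix(as.integer(stats::runif(h * w) < p), h, w)
}
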