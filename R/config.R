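#' Run configuration
#'
#' Bundles the pipeline hyperparameters with documented defaults and range
#' checks. Precedence when assembling a configuration is CLI flag > config
#' file > default. The full configuration is serialized into every command
#' output for provenance. `minsupp` and `alpha` have no universally good
#' value (they are tuned per dataset in practice); the defaults are
#' sensible starting points, not recommendations.
#'
#' @param minsupp minimum co-activation support count (`>= 0`; 0 clamps to
#'   1 at mining time).
#' @param alpha non-negative local-stream weight in `F = fG + alpha * fL`.
#' @param connectivity flood-fill neighborhood, 4 or 8.
#' @param k ranked-list display cutoff (`>= 1`).
#' @param mode representation: `"original"`, `"global"`, `"local"` or
#'   `"global_local"`.
#' @param seed integer seed for any stochastic input generation.
#' @param max_patterns mining-explosion guard.
#' @return a `run_config` list.
#' @export
run_config <- function(minsupp = 2L, alpha = 1, connectivity = 8L,
                       k = 10L, mode = "global_local", seed = 1L,
                       max_patterns = 1e6) {
  mode <- match.arg(mode, c("global_local", "original", "global", "local"))
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  if (alpha < 0) stop("alpha must be non-negative")
  if (minsupp < 0) stop("minsupp must be non-negative")
  if (k < 1) stop("k must be >= 1")
  cfg <- list(minsupp = as.integer(minsupp), alpha = as.numeric(alpha),
              connectivity = as.integer(connectivity), k = as.integer(k),
              mode = mode, seed = as.integer(seed),
              max_patterns = as.numeric(max_patterns))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Missing keys fall back to the package defaults; `overrides` (typically
#' CLI flags) take precedence over the file.
#'
#' @param path YAML file path, or `NULL` for defaults only.
#' @param overrides named list applied on top of the file values.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: '%s'", path))
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
  }
  overrides <- overrides[!vapply(overrides, is.null, logical(1L))]
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L)
    stop(sprintf("unknown config key(s): %s", toString(unknown)))
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}
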