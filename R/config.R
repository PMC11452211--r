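#' Default run configuration
#'
#' Returns the full default configuration for every pipeline stage: one
#' seed, per-stage thresholds, and permutation counts. Each value is
#' documented here once; [load_config()] merges user overrides onto these
#' defaults and rejects unknown keys.
#'
#' Stage parameters:
#' \describe{
#'   \item{seed}{integer >= 0, the single source of randomness for a run.}
#'   \item{methylome}{`sigma_cut` (sigma/sigma_max variance filter, 0.4),
#'     `q_cut_hyper` / `q_cut_hypo` (BH cutoffs for direction calls, both
#'     0.01; a stringent variant such as 1e-5 for hypermethylation is a
#'     supported override), `sigma_max` ("empirical" maximum sd across
#'     CpGs, or "theoretical" = 0.5 for a \[0,1\] variable),
#'     `top_k` (variable-CpG selection size, 10000),
#'     `ora_min_size` (gene sets retained only if larger than this, 10).}
#'   \item{sc}{`target_sum` (depth-normalisation target, 10000),
#'     `deg_q` (0.05), `deg_lfc` (0.25), `deg_min_pct` (0.10),
#'     `negligible_quantile` (0.10), `high_quantile` (0.60),
#'     `mki67_pct_factor` (proliferation gate: pct >= factor x median
#'     cluster pct, 2), `expressed_pct` (0.25), `absent_pct` (0.10),
#'     `state_floor` (minimum mean log-normalised expression for a marker
#'     to count as "high" in state calling, 0.25).}
#'   \item{cci}{`n_perm` (999), `min_pct` (expression gate, 0.10),
#'     `alpha` (significance for interaction counts, 0.05).}
#'   \item{screen}{`epsilon` (viability floor before logs, 1e-4),
#'     `active_cut` (relative log2FC at or below which a compound is
#'     "active", -1).}
#' }
#'
#' @return nested named list, serializable with [write_config()].
#' @export
default_config <- function() {
  list(
    seed = 0L,
    verbosity = 1L,
    methylome = list(
      sigma_cut = 0.4,
      q_cut_hyper = 0.01,
      q_cut_hypo = 0.01,
      sigma_max = "empirical",
      top_k = 10000L,
      ora_min_size = 10L
    ),
    sc = list(
      target_sum = 10000,
      deg_q = 0.05,
      deg_lfc = 0.25,
      deg_min_pct = 0.10,
      negligible_quantile = 0.10,
      high_quantile = 0.60,
      mki67_pct_factor = 2,
      expressed_pct = 0.25,
      absent_pct = 0.10,
      state_floor = 0.25
    ),
    cci = list(n_perm = 999L, min_pct = 0.10, alpha = 0.05),
    screen = list(epsilon = 1e-4, active_cut = -1)
  )
}

#' Load a run configuration
#'
#' Reads a YAML configuration file, validates every key against
#' [default_config()] (unknown keys are rejected with their full path),
#' and returns the defaults with the user's overrides merged in. With
#' `path = NULL` the defaults are returned unchanged.
#'
#' @param path YAML file or NULL.
#' @return resolved configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  merge_config(cfg, user, prefix = "")
}

merge_config <- function(base, user, prefix) {
  if (is.null(user)) return(base)
  if (!is.list(user)) stop("config section '", sub("\\.$", "", prefix),
                           "' must be a mapping")
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste0(prefix, unknown, collapse = ", "),
         " (see default_config() for the valid keys)")
  }
  for (k in names(user)) {
    if (is.list(base[[k]])) {
      base[[k]] <- merge_config(base[[k]], user[[k]], paste0(prefix, k, "."))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Write a resolved configuration back to disk
#'
#' @param cfg configuration list.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# One-line stage log, controlled by config verbosity.
stage_log <- function(verbosity, ...) {
  if (isTRUE(verbosity >= 1)) message("[ptclscape] ", ...)
  invisible(NULL)
}
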