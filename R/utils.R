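#' Derive a named random substream seed from a top-level seed
#'
#' All stochastic stages of the pipeline draw from substreams keyed by a
#' stage name, so that adding or reordering stages never perturbs another
#' stage's draws. The derived seed is a deterministic 31-bit integer.
#'
#' @param seed Integer top-level seed (>= 0).
#' @param stream Character scalar naming the stage (e.g. `"mating_assays"`).
#' @return A single integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @examples
#' substream_seed(1, "mating_assays")
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  stopifnot(is.character(stream), length(stream) == 1L, nzchar(stream))
  m <- 2147483647 # 2^31 - 1, Mersenne prime: keeps everything in 32-bit range
  h <- 0
  for (code in utf8ToInt(stream)) {
    h <- (h * 131 + code) %% m
  }
  as.integer((as.numeric(seed) %% m * 48271 + h) %% m)
}

#' Run configuration for a pipeline run
#'
#' Bundles the constants shared by all stages: the top-level seed, bootstrap
#' replicate count, CI level, the counts-per-million expression filter
#' threshold, the ortholog identity threshold, and the normalization mode.
#'
#' @param seed Integer >= 0; every stochastic stage derives its stream from it.
#' @param n_bootstrap Integer >= 1, bootstrap replicates (default 9999).
#' @param alpha CI tail mass in (0, 1), default 0.05 (95% intervals).
#' @param cpm_threshold Positive expressed-transcript threshold in cpm
#'   (default 2; retention requires strictly greater values in every sample).
#' @param identity_threshold Percent identity in (0, 100] required to keep a
#'   homology hit (default 90; `>=` retains).
#' @param normalization `"log_cpm"` (built-in log2(cpm + 0.5)) or
#'   `"precomputed"` (values already normalized upstream).
#' @return A list with class `"run_config"`.
#' @examples
#' run_config(seed = 1)
#' @export
run_config <- function(seed = 1L, n_bootstrap = 9999L, alpha = 0.05,
                       cpm_threshold = 2, identity_threshold = 90,
                       normalization = c("log_cpm", "precomputed")) {
  normalization <- match.arg(normalization)
  if (!is.numeric(seed) || length(seed) != 1L || seed < 0 || seed != floor(seed)) {
    abort("`seed` must be a single integer >= 0.")
  }
  if (!is.numeric(n_bootstrap) || n_bootstrap < 1 || n_bootstrap != floor(n_bootstrap)) {
    abort("`n_bootstrap` must be an integer >= 1.")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1).")
  }
  if (!is.numeric(cpm_threshold) || cpm_threshold <= 0) {
    abort("`cpm_threshold` must be > 0.")
  }
  if (!is.numeric(identity_threshold) || identity_threshold <= 0 ||
      identity_threshold > 100) {
    abort("`identity_threshold` must lie in (0, 100].")
  }
  structure(
    list(
      seed = as.integer(seed), n_bootstrap = as.integer(n_bootstrap),
      alpha = alpha, cpm_threshold = cpm_threshold,
      identity_threshold = identity_threshold, normalization = normalization
    ),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) cat(sprintf("  %s: %s\n", nm, format(x[[nm]])))
  invisible(x)
}

check_regime <- function(x, where = "regime") {
  bad <- setdiff(unique(as.character(x)), REGIMES)
  if (length(bad) > 0) {
    abort(sprintf(
      "Invalid %s value(s): %s (must be one of %s).",
      where, paste(sQuote(bad), collapse = ", "), paste(REGIMES, collapse = "/")
    ))
  }
  invisible(x)
}

check_sex <- function(x) {
  bad <- setdiff(unique(as.character(x)), SEXES)
  if (length(bad) > 0) {
    abort(sprintf(
      "Invalid sex value(s): %s (must be male/female).",
      paste(sQuote(bad), collapse = ", ")
    ))
  }
  invisible(x)
}

check_nonneg_int <- function(x, col) {
  bad <- which(is.na(x) | x < 0 | x != floor(x))
  if (length(bad) > 0) {
    abort(sprintf(
      "Column `%s` must hold non-negative integers; offending row(s): %s.",
      col, paste(head(bad, 5L), collapse = ", ")
    ))
  }
  invisible(x)
}

inv_logit <- function(x) plogis(x)
logit <- function(p) qlogis(p)
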