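#' Ground-truth parameters for the synthetic-data generators
#'
#' Collects every parameter the generators consume, so each simulated
#' dataset carries a machine-readable record of the effects it was built
#' with and downstream estimators can be tested by parameter recovery.
#'
#' Defaults encode the study conditions the generators emulate: female
#' lifetime mating rates of 1.0 (weak-sexual-selection, WSS) and 2.1
#' (strong-sexual-selection, SSS) matings; overall last-male paternity (P2)
#' of 0.44 (WSS) and 0.61 (SSS); logit-scale male-by-female interaction
#' variances of 0.222 (WSS) and 0.633 (SSS), stored as standard deviations;
#' Bateman slopes of 0.1 (WSS) and 0.4 (SSS) offspring per mating on the
#' absolute scale; an intra-clutch hatch correlation of 0.15 (chosen to
#' reproduce the residual overdispersion of roughly 7 seen in hatch-count
#' models at ~40 eggs per female); and designated reproductive gene sets
#' whose between-replicate expression SD is 1.5 times larger under SSS than
#' WSS against a background at ratio 1.
#'
#' @param bateman_slope_by_regime Named numeric, slope of reproductive
#'   success on absolute mating count per regime.
#' @param mating_rate_by_regime Named positive numeric, mean lifetime
#'   matings per regime (zero-truncated Poisson rate).
#' @param interaction_sd_by_regime Named non-negative numeric, logit-scale
#'   SD of the male-line-by-female-line random effect per regime.
#' @param line_effect_sd Non-negative; SD of additive line effects (on the
#'   offspring scale in the mating assays, on the logit scale in the
#'   double-mating design).
#' @param overdispersion_rho Intra-female hatch correlation in `[0, 1)`;
#'   beta-binomial intra-class correlation.
#' @param baseline_p2_by_regime Named numeric in (0, 1), regime-mean P2.
#' @param replicate_sd_by_regime_and_geneset Data frame with columns
#'   `gene_set`, `regime`, `sd`: between-replicate expression SD for each
#'   (gene set, regime); must include a `"background"` set.
#' @return A list with class `"synthetic_truth"`.
#' @examples
#' synthetic_truth()
#' @export
synthetic_truth <- function(
    bateman_slope_by_regime = c(WSS = 0.1, SSS = 0.4),
    mating_rate_by_regime = c(WSS = 1.0, SSS = 2.1),
    interaction_sd_by_regime = c(WSS = sqrt(0.222), SSS = sqrt(0.633)),
    line_effect_sd = 0.3,
    overdispersion_rho = 0.15,
    baseline_p2_by_regime = c(WSS = 0.44, SSS = 0.61),
    replicate_sd_by_regime_and_geneset = default_replicate_sds()) {
  named_by_regime <- function(x, what) {
    if (!all(REGIMES %in% names(x))) {
      abort(sprintf("`%s` must be named with both regimes (WSS, SSS).", what))
    }
    x[REGIMES]
  }
  bateman_slope_by_regime <- named_by_regime(bateman_slope_by_regime,
                                             "bateman_slope_by_regime")
  mating_rate_by_regime <- named_by_regime(mating_rate_by_regime,
                                           "mating_rate_by_regime")
  interaction_sd_by_regime <- named_by_regime(interaction_sd_by_regime,
                                              "interaction_sd_by_regime")
  baseline_p2_by_regime <- named_by_regime(baseline_p2_by_regime,
                                           "baseline_p2_by_regime")
  if (any(mating_rate_by_regime <= 0)) abort("Mating rates must be > 0.")
  if (any(interaction_sd_by_regime < 0)) abort("Interaction SDs must be >= 0.")
  if (line_effect_sd < 0) abort("`line_effect_sd` must be >= 0.")
  if (overdispersion_rho < 0 || overdispersion_rho >= 1) {
    abort("`overdispersion_rho` must lie in [0, 1).")
  }
  if (any(baseline_p2_by_regime <= 0 | baseline_p2_by_regime >= 1)) {
    abort("Baseline P2 values must lie strictly in (0, 1).")
  }
  sds <- as_tibble(replicate_sd_by_regime_and_geneset)
  need <- c("gene_set", "regime", "sd")
  if (!all(need %in% names(sds))) {
    abort("`replicate_sd_by_regime_and_geneset` needs columns gene_set, regime, sd.")
  }
  check_regime(sds$regime)
  if (any(sds$sd < 0)) abort("Replicate SDs must be >= 0.")
  if (!"background" %in% sds$gene_set) {
    abort("Replicate SD table must include a 'background' gene set.")
  }
  structure(
    list(
      bateman_slope_by_regime = bateman_slope_by_regime,
      mating_rate_by_regime = mating_rate_by_regime,
      interaction_sd_by_regime = interaction_sd_by_regime,
      line_effect_sd = line_effect_sd,
      overdispersion_rho = overdispersion_rho,
      baseline_p2_by_regime = baseline_p2_by_regime,
      replicate_sd_by_regime_and_geneset = sds
    ),
    class = "synthetic_truth"
  )
}

#' Default between-replicate expression SD table
#'
#' Background genes diverge equally under both regimes (SD 0.5); the two
#' designated reproductive sets ("SFP", seminal fluid proteins, and "FRP",
#' female reproductive-tract proteins) have an SSS:WSS SD ratio of 1.5.
#'
#' @return A tibble with columns `gene_set`, `regime`, `sd`.
#' @export
default_replicate_sds <- function() {
  tibble(
    gene_set = rep(c("background", "SFP", "FRP"), each = 2L),
    regime = rep(c("WSS", "SSS"), times = 3L),
    sd = c(0.5, 0.5, 0.5, 0.75, 0.5, 0.75)
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth>\n")
  cat("  bateman slope:   ", paste(sprintf("%s=%.3g", names(x$bateman_slope_by_regime),
                                           x$bateman_slope_by_regime), collapse = " "), "\n")
  cat("  mating rate:     ", paste(sprintf("%s=%.3g", names(x$mating_rate_by_regime),
                                           x$mating_rate_by_regime), collapse = " "), "\n")
  cat("  interaction SD:  ", paste(sprintf("%s=%.3g", names(x$interaction_sd_by_regime),
                                           x$interaction_sd_by_regime), collapse = " "), "\n")
  cat("  baseline P2:     ", paste(sprintf("%s=%.3g", names(x$baseline_p2_by_regime),
                                           x$baseline_p2_by_regime), collapse = " "), "\n")
  cat(sprintf("  line effect SD %.3g; overdispersion rho %.3g\n",
              x$line_effect_sd, x$overdispersion_rho))
  cat(sprintf("  replicate SD table: %d rows\n",
              nrow(x$replicate_sd_by_regime_and_geneset)))
  invisible(x)
}
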