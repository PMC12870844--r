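# Diagnostic figures for each result type.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_errorbar
#'   geom_hline geom_boxplot geom_violin facet_wrap labs position_dodge
#'   theme_minimal scale_y_log10
NULL

#' Plot sexual-selection metrics by sex and regime
#'
#' Bateman gradients (with parametric CIs) and the opportunity for sexual
#' selection (with bootstrap CIs), side by side per sex.
#'
#' @param object A `sexsel_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sexsel_fit <- function(object, ...) {
  est <- object$estimates
  zq <- qnorm(1 - object$config$alpha / 2)
  long <- bind_rows(
    est %>%
      mutate(metric = "Bateman gradient", value = .data$beta_B,
             lower = .data$beta_B - zq * .data$beta_B_se,
             upper = .data$beta_B + zq * .data$beta_B_se),
    est %>%
      mutate(metric = "Opportunity for selection", value = .data$I_s,
             lower = .data$I_s_ci_lower, upper = .data$I_s_ci_upper)
  )
  ggplot(long, aes(x = .data$regime, y = .data$value,
                   shape = .data$sex, colour = .data$sex)) +
    geom_point(position = position_dodge(width = 0.4), size = 2.5) +
    geom_errorbar(aes(ymin = .data$lower, ymax = .data$upper),
                  width = 0.15, position = position_dodge(width = 0.4)) +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "Selection regime", y = "Estimate") +
    theme_minimal()
}

#' Plot per-cell P2 by male and female line for one regime
#'
#' @param object A `crossed_p2_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crossed_p2_fit <- function(object, ...) {
  d <- object$glm_fit$data
  d$p2 <- d$hatched / d$eggs_total
  cell <- d %>%
    group_by(.data$male_line, .data$female_line) %>%
    summarise(mean_p2 = mean(.data$p2),
              se = sd(.data$p2) / sqrt(n()), .groups = "drop")
  ggplot(cell, aes(x = .data$male_line, y = .data$mean_p2,
                   colour = .data$female_line)) +
    geom_point(position = position_dodge(width = 0.5)) +
    geom_errorbar(aes(ymin = .data$mean_p2 - .data$se,
                      ymax = .data$mean_p2 + .data$se),
                  width = 0.2, position = position_dodge(width = 0.5)) +
    geom_hline(yintercept = object$predicted_mean_p2, linetype = "dashed") +
    labs(x = "Male line", y = "P2 (last-male paternity share)",
         colour = "Female line",
         title = sprintf("Regime %s", object$regime)) +
    theme_minimal()
}

#' Plot divergence-ratio distributions per gene set
#'
#' Violin-and-box display of per-gene SSS/WSS divergence ratios for the
#' transcriptome background of each sex and every designated set, with the
#' equal-divergence line at 1.
#'
#' @param object A `divergence_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.divergence_fit <- function(object, ...) {
  per_gene <- object$per_gene %>% filter(is.finite(.data$ratio))
  groups <- bind_rows(
    per_gene %>% mutate(set = sprintf("all_%s", .data$sex)),
    bind_rows(lapply(names(object$gene_sets), function(nm) {
      per_gene %>%
        filter(.data$gene_id %in% object$gene_sets[[nm]]) %>%
        mutate(set = nm)
    }))
  )
  ggplot(groups, aes(x = .data$set, y = .data$ratio)) +
    geom_violin(fill = "grey85", colour = NA) +
    geom_boxplot(width = 0.15, outlier.shape = NA) +
    geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    scale_y_log10() +
    labs(x = NULL, y = "Divergence ratio (SSS / WSS)") +
    theme_minimal()
}
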