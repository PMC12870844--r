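# Last-male sperm-competition success (P2) in the fully crossed
# female-line x male-line double-mating design, and the three complementary
# routes for comparing the male x female interaction between regimes:
#  (1) a binomial mixed model with fixed dispersion (PQL), extracting the
#      logit-scale interaction variance component;
#  (2) a weighted arcsine-square-root linear mixed model and a variance
#      ratio test on the interaction mean squares;
#  (3) an additive (no-interaction) model's residual cell means, their
#      variance, a BCa bootstrap, a variance-ratio F and Bartlett's test.

#' Keep only females where two ejaculates demonstrably competed
#'
#' Retains records where both matings succeeded, at least one egg was laid,
#' and at least one offspring hatched (a female with P2 = 0 gives no
#' evidence that the focal male transferred an ejaculate).
#'
#' @param records Double-mating records tibble.
#' @return The retained rows.
#' @export
filter_competing_females <- function(records) {
  records <- as_tibble(records)
  records %>%
    filter(.data$first_mating_ok, .data$second_mating_ok,
           .data$eggs_total >= 1L, .data$hatched >= 1L)
}

#' Last-male paternity share P2
#'
#' @param records Filtered double-mating records (positive egg totals).
#' @return Numeric vector `hatched / eggs_total`.
#' @export
compute_p2 <- function(records) {
  records <- as_tibble(records)
  if (any(records$eggs_total < 1L)) {
    abort("P2 is undefined for females with zero eggs; filter first.")
  }
  records$hatched / records$eggs_total
}

check_crossed_design <- function(records, regime = "this regime") {
  ml <- unique(records$male_line)
  fl <- unique(records$female_line)
  if (length(ml) < 2L || length(fl) < 2L) {
    abort("Need >= 2 male and >= 2 female lines for a crossed analysis.")
  }
  cells <- records %>% count(.data$male_line, .data$female_line)
  full <- tidyr::expand_grid(male_line = ml, female_line = fl)
  missing <- dplyr::anti_join(full, cells, by = c("male_line", "female_line"))
  if (nrow(missing) > 0L) {
    abort(sprintf("Empty design cell in %s: male %s x female %s.",
                  regime, missing$male_line[1L], missing$female_line[1L]))
  }
  invisible(records)
}

#' Quasi-binomial crossed GLM of sperm-competition success
#'
#' Fits hatched counts with the total eggs laid as the binomial denominator
#' and a logit link, with sequential fixed effects for male line, female
#' line and their interaction. The dispersion is estimated empirically as
#' the Pearson chi-square over the residual degrees of freedom; each term's
#' F statistic is (deviance change / df change) / dispersion with the p
#' value from F on (term df, residual df). The predicted regime-mean P2 is
#' the inverse logit of the average cell linear predictor with a
#' delta-method CI, and the interaction effect size is its share of the
#' total (model + residual) deviance.
#'
#' @param records Filtered double-mating records for one regime.
#' @param term_order Character vector giving the sequential order of the
#'   two main effects (default male line first, matching the canonical
#'   deviance-table layout).
#' @param alpha CI tail mass for the predicted-mean interval.
#' @return An object of class `"crossed_p2_fit"`; [tidy()] returns the
#'   deviance table, [glance()] the dispersion, predicted mean P2 and
#'   interaction effect size.
#' @export
fit_crossed_glm <- function(records,
                            term_order = c("male_line", "female_line"),
                            alpha = 0.05) {
  records <- as_tibble(records)
  stopifnot(setequal(term_order, c("male_line", "female_line")))
  regime <- unique(records$regime)
  if (length(regime) != 1L) abort("Fit one regime at a time.")
  check_crossed_design(records, regime)
  d <- records %>%
    mutate(male_line = factor(.data$male_line),
           female_line = factor(.data$female_line))
  # complete separation: a cell with every egg hatched (or none) pins the
  # fitted probability to the boundary; shrink counts slightly and continue
  sat <- d %>%
    group_by(.data$male_line, .data$female_line) %>%
    summarise(h = sum(.data$hatched), e = sum(.data$eggs_total),
              .groups = "drop") %>%
    filter(.data$h == .data$e | .data$h == 0L)
  succ <- d$hatched
  fail <- d$eggs_total - d$hatched
  if (nrow(sat) > 0L) {
    warn(sprintf(
      "%d saturated cell(s) (all or no eggs hatched); using shrunken counts.",
      nrow(sat)
    ))
    succ <- succ + 0.5
    fail <- fail + 0.5
  }
  fml <- as.formula(sprintf(
    "cbind(succ, fail) ~ %s + %s + %s:%s",
    term_order[1L], term_order[2L], term_order[1L], term_order[2L]
  ))
  d$succ <- succ
  d$fail <- fail
  fit <- suppressWarnings(glm(fml, family = quasibinomial(), data = d))
  an <- anova(fit)
  phi <- sum(residuals(fit, type = "pearson")^2) / fit$df.residual
  terms <- rownames(an)[-1L]
  dev <- an$Deviance[-1L]
  dfs <- an$Df[-1L]
  f_stat <- (dev / dfs) / phi
  p_val <- pf(f_stat, dfs, fit$df.residual, lower.tail = FALSE)
  dev_table <- tibble(
    term = c(terms, "residual"),
    df = c(dfs, fit$df.residual),
    deviance = c(dev, fit$deviance),
    f_statistic = c(f_stat, NA_real_),
    p_value = c(p_val, NA_real_)
  )
  int_term <- sprintf("%s:%s", term_order[1L], term_order[2L])
  eta2 <- dev[terms == int_term] / (sum(dev) + fit$deviance)
  # predicted regime mean: average cell linear predictor, delta-method CI
  grid <- tidyr::expand_grid(male_line = levels(d$male_line),
                             female_line = levels(d$female_line))
  X <- stats::model.matrix(stats::delete.response(stats::terms(fit)), grid)
  l <- colMeans(X)
  eta <- drop(l %*% coef(fit))
  se_eta <- sqrt(drop(t(l) %*% vcov(fit) %*% l))
  zq <- qnorm(1 - alpha / 2)
  structure(
    list(
      regime = regime, deviance_table = dev_table, dispersion = phi,
      predicted_mean_p2 = inv_logit(eta),
      predicted_mean_ci = inv_logit(c(eta - zq * se_eta, eta + zq * se_eta)),
      eta_squared_interaction = eta2, glm_fit = fit,
      n = nrow(d), term_order = term_order
    ),
    class = "crossed_p2_fit"
  )
}

#' @export
print.crossed_p2_fit <- function(x, ...) {
  cat(sprintf("Crossed quasi-binomial P2 model, regime %s (n = %d)\n",
              x$regime, x$n))
  print(as.data.frame(x$deviance_table), digits = 4)
  cat(sprintf("dispersion %.3f; predicted mean P2 %.3f (%.3f-%.3f); interaction eta^2 %.3f\n",
              x$dispersion, x$predicted_mean_p2, x$predicted_mean_ci[1L],
              x$predicted_mean_ci[2L], x$eta_squared_interaction))
  invisible(x)
}

#' @rdname fit_crossed_glm
#' @param x A `crossed_p2_fit` object.
#' @param ... Unused.
#' @export
tidy.crossed_p2_fit <- function(x, ...) {
  x$deviance_table %>% mutate(regime = x$regime, .before = 1L)
}

#' @rdname fit_crossed_glm
#' @export
glance.crossed_p2_fit <- function(x, ...) {
  tibble(
    regime = x$regime, n = x$n, dispersion = x$dispersion,
    predicted_mean_p2 = x$predicted_mean_p2,
    predicted_mean_ci_lower = x$predicted_mean_ci[1L],
    predicted_mean_ci_upper = x$predicted_mean_ci[2L],
    eta_squared_interaction = x$eta_squared_interaction
  )
}

#' Logit-scale male-by-female interaction variance component
#'
#' Estimates the variance of the male-line-by-female-line random effect in
#' a binomial mixed model with random main effects for both line factors, a
#' fixed intercept, and the dispersion fixed at the Pearson estimate from
#' the corresponding fixed-effects fit. Estimation is by penalized
#' quasi-likelihood: a working-response linear mixed model (REML) is
#' refitted until the linear predictor stabilizes. The standard error comes
#' from the curvature (numeric Hessian) of the profiled REML criterion at
#' convergence, transferred to the variance scale by the delta method.
#'
#' A deterministic method-of-moments style alternative
#' (`method = "moments"`) fits the same random-effect structure to
#' empirical logits, for robustness when the PQL loop fails to converge.
#'
#' @param records Filtered double-mating records for one regime.
#' @param dispersion Optional fixed dispersion; defaults to the Pearson
#'   chi-square / df from [fit_crossed_glm()] on the same records.
#' @param method `"pql"` (default) or `"moments"`.
#' @param max_iter,tol PQL loop controls.
#' @return One-row tibble: `regime`, `varcomp`, `se`, `method`,
#'   `dispersion`, `iterations`, `converged`.
#' @export
interaction_variance_component <- function(records, dispersion = NULL,
                                           method = c("pql", "moments"),
                                           max_iter = 200L, tol = 1e-5) {
  method <- match.arg(method)
  records <- as_tibble(records)
  regime <- unique(records$regime)
  if (length(regime) != 1L) abort("Fit one regime at a time.")
  check_crossed_design(records, regime)
  d <- records %>%
    mutate(male_line = factor(.data$male_line),
           female_line = factor(.data$female_line),
           cell = interaction(.data$male_line, .data$female_line, drop = TRUE))
  if (is.null(dispersion)) {
    dispersion <- fit_crossed_glm(records)$dispersion
  }
  if (method == "moments") {
    y <- qlogis((d$hatched + 0.5) / (d$eggs_total + 1))
    fit <- suppressMessages(suppressWarnings(lme4::lmer(
      y ~ 1 + (1 | male_line) + (1 | female_line) + (1 | cell),
      data = d, REML = TRUE
    )))
    vc <- as.data.frame(lme4::VarCorr(fit))
    v_int <- vc$vcov[vc$grp == "cell"]
    se <- varcomp_se(fit, "cell")
    return(tibble(regime = regime, varcomp = v_int, se = se,
                  method = "moments", dispersion = dispersion,
                  iterations = NA_integer_, converged = TRUE))
  }
  n <- d$eggs_total
  y <- d$hatched / n
  mu <- (d$hatched + 0.5) / (n + 1)
  eta <- qlogis(mu)
  fit <- NULL
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    w <- n * mu * (1 - mu) / dispersion
    z <- eta + (y - mu) / (mu * (1 - mu))
    d$z <- z
    d$w <- w
    fit <- suppressMessages(suppressWarnings(lme4::lmer(
      z ~ 1 + (1 | male_line) + (1 | female_line) + (1 | cell),
      data = d, weights = w, REML = TRUE
    )))
    eta_new <- fitted(fit)
    delta <- max(abs(eta_new - eta)) / (0.1 + max(abs(eta_new)))
    # half-step damping suppresses the two-cycle oscillation PQL is prone to
    eta <- (eta + eta_new) / 2
    mu <- plogis(eta)
    mu <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    abort(sprintf(
      "PQL loop did not converge in %d iterations (last delta %.2e); try method = 'moments'.",
      max_iter, delta
    ))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  v_int <- vc$vcov[vc$grp == "cell"]
  se <- varcomp_se(fit, "cell")
  tibble(regime = regime, varcomp = v_int, se = se, method = "pql",
         dispersion = dispersion, iterations = it, converged = TRUE)
}

# SE of one variance component from the curvature of the profiled REML
# criterion over the relative-covariance parameters (theta); delta method
# theta -> sigma^2 * theta^2, holding the profiled residual scale fixed.
varcomp_se <- function(fit, grp) {
  theta <- lme4::getME(fit, "theta")
  idx <- which(grepl(paste0("^", grp, "\\."), names(theta)) |
                 names(theta) == paste0(grp, ".(Intercept)"))
  if (length(idx) != 1L) return(NA_real_)
  devfun <- lme4::devfun2(fit, useSc = TRUE, signames = FALSE)
  # devfun2 parametrizes by standard deviations (and residual sd last)
  pars <- c(sqrt(unname(vapply(
    names(theta), function(nm) theta[[nm]], numeric(1)
  ))^2) * lme4::getME(fit, "sigma"), lme4::getME(fit, "sigma"))
  h <- tryCatch(optimHess(pars, devfun), error = function(e) NULL)
  if (is.null(h)) return(NA_real_)
  v <- tryCatch(2 * solve(h), error = function(e) NULL)
  if (is.null(v)) return(NA_real_)
  sd_hat <- pars[idx]
  se_sd <- sqrt(max(v[idx, idx], 0))
  2 * sd_hat * se_sd # delta method: var = sd^2
}

#' Weighted arcsine-square-root LMM share and variance-ratio test
#'
#' For each regime, transforms P2 to `asin(sqrt(P2))`, weights by the total
#' egg count, and (a) fits the fixed-effects two-way crossed ANOVA to
#' obtain the interaction mean square, and (b) fits the random-effects
#' model (intercept fixed; male line, female line and their interaction
#' random) to express the interaction variance component as a percentage
#' of the total variance. The between-regime variance-ratio test is
#' F = MS_interaction(SSS) / MS_interaction(WSS) on the two interaction
#' degrees of freedom, with a one-sided p for the directional prediction
#' that the interaction is stronger under strong sexual selection (a
#' two-sided p is also reported).
#'
#' @param records_wss,records_sss Filtered records per regime.
#' @return List of class `"interaction_ratio_test"` with `by_regime` (share
#'   and mean-square table) and `test` (F, df pair, one- and two-sided p).
#' @export
lmm_share_and_ratio_test <- function(records_wss, records_sss) {
  one_regime <- function(records) {
    records <- as_tibble(records)
    regime <- unique(records$regime)
    check_crossed_design(records, regime)
    d <- records %>%
      mutate(
        male_line = factor(.data$male_line),
        female_line = factor(.data$female_line),
        cell = interaction(.data$male_line, .data$female_line, drop = TRUE),
        y = asin(sqrt(compute_p2(records))),
        w = .data$eggs_total / mean(.data$eggs_total) # mean-1 weights
      )
    av <- anova(lm(y ~ male_line * female_line, data = d, weights = d$w))
    ms_int <- av["male_line:female_line", "Mean Sq"]
    df_int <- av["male_line:female_line", "Df"]
    lmm <- suppressMessages(suppressWarnings(lme4::lmer(
      y ~ 1 + (1 | male_line) + (1 | female_line) + (1 | cell),
      data = d, weights = d$w, REML = TRUE
    )))
    vc <- as.data.frame(lme4::VarCorr(lmm))
    v <- setNames(vc$vcov, vc$grp)
    total <- sum(v)
    tibble(
      regime = regime, ms_interaction = ms_int, df_interaction = df_int,
      varcomp_interaction = v[["cell"]],
      share_percent = 100 * v[["cell"]] / total
    )
  }
  by_regime <- bind_rows(one_regime(records_wss), one_regime(records_sss))
  wss <- by_regime %>% filter(.data$regime == "WSS")
  sss <- by_regime %>% filter(.data$regime == "SSS")
  f <- sss$ms_interaction / wss$ms_interaction
  p_one <- pf(f, sss$df_interaction, wss$df_interaction, lower.tail = FALSE)
  structure(
    list(
      by_regime = by_regime,
      test = tibble(
        f_statistic = f, df1 = sss$df_interaction, df2 = wss$df_interaction,
        p_one_sided = p_one, p_two_sided = 2 * min(p_one, 1 - p_one)
      )
    ),
    class = "interaction_ratio_test"
  )
}

#' @export
print.interaction_ratio_test <- function(x, ...) {
  cat("Weighted arcsine-sqrt P2 interaction comparison\n")
  print(as.data.frame(x$by_regime), digits = 3)
  print(as.data.frame(x$test), digits = 3)
  invisible(x)
}

#' Residual cell-mean bootstrap of the deviation from additivity
#'
#' Fits the additive (no-interaction) quasi-binomial model per regime and
#' extracts each female's residual hatched count (observed minus expected).
#' The mean residual per design cell measures that cell's deviation from
#' the additive expectation; the statistic is the sample variance of those
#' cell means. Females are resampled with replacement within cells (the
#' model is refitted on each resample) for a BCa interval; the regimes are
#' compared by a variance-ratio F on (cells - 1, cells - 1) df with a
#' one-sided p for the strong-selection prediction, and by Bartlett's
#' homogeneity test on the two groups of cell means.
#'
#' @param records_wss,records_sss Filtered records per regime.
#' @param n_boot Bootstrap replicates (warning below 100).
#' @param alpha CI tail mass.
#' @param seed Integer seed for the resampling stream.
#' @return List of class `"residual_cell_bootstrap"` with `by_regime`
#'   (variance, bootstrap average, BCa CI, cells) and `test` (F and
#'   Bartlett rows).
#' @export
residual_cell_bootstrap <- function(records_wss, records_sss,
                                    n_boot = 9999L, alpha = 0.05, seed = 1L) {
  if (n_boot < 100L) warn("Fewer than 100 bootstrap replicates is unreliable.")
  one_regime <- function(records, stream) {
    records <- as_tibble(records)
    regime <- unique(records$regime)
    check_crossed_design(records, regime)
    d <- records %>%
      mutate(male_line = factor(.data$male_line),
             female_line = factor(.data$female_line),
             cell = interaction(.data$male_line, .data$female_line,
                                drop = TRUE))
    cell_var <- function(dat) {
      fit <- suppressWarnings(glm(
        cbind(hatched, eggs_total - hatched) ~ male_line + female_line,
        family = quasibinomial(), data = dat
      ))
      res <- dat$hatched - dat$eggs_total * fitted(fit)
      cm <- tapply(res, dat$cell, mean)
      list(var = var(as.numeric(cm)), cell_means = as.numeric(cm))
    }
    obs <- cell_var(d)
    idx_by_cell <- split(seq_len(nrow(d)), d$cell)
    t_boot <- withr::with_seed(substream_seed(seed, stream), {
      vapply(seq_len(n_boot), function(b) {
        take <- unlist(lapply(idx_by_cell, function(ix) {
          ix[sample.int(length(ix), length(ix), replace = TRUE)]
        }), use.names = FALSE)
        cell_var(d[take, , drop = FALSE])$var
      }, numeric(1))
    })
    t_jack <- vapply(seq_len(nrow(d)), function(i) {
      cell_var(d[-i, , drop = FALSE])$var
    }, numeric(1))
    ci <- bca_interval(obs$var, t_boot, t_jack, alpha = alpha)
    list(
      row = tibble(
        regime = regime, n_cells = length(obs$cell_means),
        cell_variance = obs$var, boot_average_variance = mean(t_boot),
        ci_lower = ci[["lower"]], ci_upper = ci[["upper"]]
      ),
      cell_means = obs$cell_means,
      df_interaction = (length(unique(d$male_line)) - 1L) *
        (length(unique(d$female_line)) - 1L)
    )
  }
  wss <- one_regime(records_wss, "residual_boot_WSS")
  sss <- one_regime(records_sss, "residual_boot_SSS")
  f <- sss$row$cell_variance / wss$row$cell_variance
  df1 <- sss$row$n_cells - 1L
  df2 <- wss$row$n_cells - 1L
  p_one <- pf(f, df1, df2, lower.tail = FALSE)
  # cell means of additive-model residuals are confined to the interaction
  # subspace, so (I-1)(J-1) are the effective df; the (cells - 1) reference
  # is the conventional headline but is anticonservative (see vignette)
  p_eff <- pf(f, sss$df_interaction, wss$df_interaction, lower.tail = FALSE)
  groups <- factor(rep(c("WSS", "SSS"),
                       c(length(wss$cell_means), length(sss$cell_means))))
  bt <- bartlett.test(c(wss$cell_means, sss$cell_means), groups)
  structure(
    list(
      by_regime = bind_rows(wss$row, sss$row),
      test = tibble(
        statistic = c(f, f, unname(bt$statistic)),
        df1 = c(df1, sss$df_interaction, unname(bt$parameter)),
        df2 = c(df2, wss$df_interaction, NA_real_),
        p_value = c(p_one, p_eff, bt$p.value),
        type = c("variance_ratio_one_sided",
                 "variance_ratio_interaction_df", "bartlett")
      ),
      cell_means = list(WSS = wss$cell_means, SSS = sss$cell_means)
    ),
    class = "residual_cell_bootstrap"
  )
}

#' @export
print.residual_cell_bootstrap <- function(x, ...) {
  cat("Residual cell-mean variance (deviation from additivity)\n")
  print(as.data.frame(x$by_regime), digits = 3)
  print(as.data.frame(x$test), digits = 3)
  invisible(x)
}

#' Rank-sum comparison of within-line versus between-line crosses
#'
#' Tests whether within-line crosses (female and focal male from the same
#' replicate line) have higher P2 than between-line crosses, per regime and
#' pooled. Exact p values are used for small tie-free samples, otherwise
#' the tie-corrected normal approximation (the default behaviour of the
#' rank-sum test).
#'
#' @param records Filtered double-mating records (both regimes allowed).
#' @return Tibble with one row per scope (`WSS`, `SSS`, `combined`):
#'   `n_within`, `n_between`, `w_statistic`, `p_one_sided` (within
#'   greater), `p_two_sided`.
#' @export
within_vs_between_comparison <- function(records) {
  records <- as_tibble(records)
  one_scope <- function(d, scope) {
    p2 <- compute_p2(d)
    within <- d$female_line == d$male_line
    if (!any(within) || all(within)) {
      abort(sprintf("Scope %s needs both within- and between-line crosses.",
                    scope))
    }
    wt1 <- suppressWarnings(wilcox.test(p2[within], p2[!within],
                                        alternative = "greater"))
    wt2 <- suppressWarnings(wilcox.test(p2[within], p2[!within]))
    # completely tied samples leave the normal approximation with zero
    # variance; that is no evidence against the null
    fix_p <- function(p) if (is.finite(p)) p else 1
    tibble(
      scope = scope, n_within = sum(within), n_between = sum(!within),
      w_statistic = unname(wt1$statistic),
      p_one_sided = fix_p(wt1$p.value), p_two_sided = fix_p(wt2$p.value)
    )
  }
  bind_rows(
    lapply(REGIMES, function(rg) {
      one_scope(records %>% filter(.data$regime == rg), rg)
    }) %>% bind_rows(),
    one_scope(records, "combined")
  )
}

#' Full sperm-competition analysis of a double-mating table
#'
#' Runs the whole module: validates and filters the records, fits the
#' per-regime crossed quasi-binomial models, and compares the male x
#' female interaction between regimes by all three routes plus the
#' within- versus between-line rank-sum comparison.
#'
#' @param records Double-mating records (both regimes).
#' @param config A [run_config()] (bootstrap count, CI level, seed).
#' @return Object of class `"spermcomp_fit"`; [tidy()] returns the stacked
#'   deviance tables and [glance()] the per-regime summaries.
#' @examples
#' dm <- simulate_double_matings(synthetic_truth(), seed = 1)
#' fit <- spermcomp_analysis(dm, run_config(seed = 1, n_bootstrap = 199))
#' glance(fit)
#' @export
spermcomp_analysis <- function(records, config = run_config()) {
  records <- validate_double_matings(records)
  kept <- filter_competing_females(records)
  by_regime <- split(kept, kept$regime)
  if (!all(REGIMES %in% names(by_regime))) {
    abort("Both regimes (WSS, SSS) are required.")
  }
  glms <- lapply(by_regime[REGIMES], fit_crossed_glm, alpha = config$alpha)
  varcomps <- bind_rows(lapply(REGIMES, function(rg) {
    interaction_variance_component(by_regime[[rg]],
                                   dispersion = glms[[rg]]$dispersion)
  }))
  ratio <- lmm_share_and_ratio_test(by_regime$WSS, by_regime$SSS)
  resid_boot <- residual_cell_bootstrap(
    by_regime$WSS, by_regime$SSS, n_boot = config$n_bootstrap,
    alpha = config$alpha, seed = substream_seed(config$seed, "residual_boot")
  )
  wvb <- within_vs_between_comparison(kept)
  structure(
    list(
      glm_fits = glms, varcomps = varcomps, ratio_test = ratio,
      residual_bootstrap = resid_boot, within_vs_between = wvb,
      n_used = nrow(kept), n_excluded = nrow(records) - nrow(kept),
      config = config
    ),
    class = "spermcomp_fit"
  )
}

#' @export
print.spermcomp_fit <- function(x, ...) {
  cat(sprintf("Sperm-competition analysis: %d females used, %d excluded\n\n",
              x$n_used, x$n_excluded))
  for (rg in REGIMES) print(x$glm_fits[[rg]])
  cat("\nInteraction variance components (logit scale):\n")
  print(as.data.frame(x$varcomps), digits = 3)
  print(x$ratio_test)
  print(x$residual_bootstrap)
  cat("Within- vs between-line rank-sum tests:\n")
  print(as.data.frame(x$within_vs_between), digits = 3)
  invisible(x)
}

#' @rdname spermcomp_analysis
#' @param x A `spermcomp_fit` object.
#' @param ... Unused.
#' @export
tidy.spermcomp_fit <- function(x, ...) {
  bind_rows(lapply(x$glm_fits, tidy))
}

#' @rdname spermcomp_analysis
#' @export
glance.spermcomp_fit <- function(x, ...) {
  bind_rows(lapply(x$glm_fits, glance)) %>%
    left_join(x$varcomps %>%
                select("regime", interaction_varcomp = "varcomp",
                       interaction_varcomp_se = "se"),
              by = "regime") %>%
    left_join(x$ratio_test$by_regime %>%
                select("regime", lmm_share_percent = "share_percent"),
              by = "regime") %>%
    left_join(x$residual_bootstrap$by_regime %>%
                select("regime", residual_cell_variance = "cell_variance",
                       residual_ci_lower = "ci_lower",
                       residual_ci_upper = "ci_upper"),
              by = "regime")
}
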