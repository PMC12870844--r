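# Sexual-selection metrics: opportunity for sexual selection (I_s), Bateman
# gradient (mixed model with replicate line as a random intercept), the
# least-squares relative-on-relative slope, and the Jones index
# s'_max = sqrt(I_s) * beta_ss, plus a Z-test of equal Bateman slopes.

#' Exclude individuals with zero mating (and hence zero reproductive) success
#'
#' Individuals that never mated carry no information about how fitness
#' accumulates over successive matings and are removed before estimating
#' selection metrics.
#'
#' @param records Tibble of assay records (see [read_individual_assays()]).
#' @return List with `records` (rows with `matings >= 1`) and `n_excluded`.
#' @examples
#' r <- tibble::tibble(matings = c(0, 1, 2), offspring = c(0, 3, 9))
#' exclude_zero_success(r)$n_excluded
#' @export
exclude_zero_success <- function(records) {
  records <- as_tibble(records)
  keep <- records$matings >= 1
  list(records = records[keep, , drop = FALSE], n_excluded = sum(!keep))
}

#' Relativize values by their group mean
#'
#' Divides each value by the mean of its group, so every group's relative
#' values average exactly one. This is the standardization behind relative
#' mating and reproductive success.
#'
#' @param values Non-negative numeric vector.
#' @param grouping Group labels, one per value (a single group if omitted).
#' @return Numeric vector of `values / group mean`.
#' @examples
#' relativize(c(1, 2, 3))
#' @export
relativize <- function(values, grouping = rep("all", length(values))) {
  stopifnot(length(values) == length(grouping))
  if (any(values < 0, na.rm = TRUE)) abort("Values must be non-negative.")
  out <- numeric(length(values))
  for (g in unique(grouping)) {
    idx <- grouping == g
    m <- mean(values[idx])
    if (!is.finite(m) || m <= 0) {
      abort(sprintf("Group %s has mean 0; cannot relativize.", sQuote(g)))
    }
    out[idx] <- values[idx] / m
  }
  out
}

#' Opportunity for sexual selection
#'
#' The variance (sample variance, divisor n - 1) of relative mating
#' success: an upper bound on standardized selection through mating.
#'
#' @param relative_matings Numeric vector of relative mating successes
#'   (>= 2 values).
#' @return Non-negative scalar `I_s`.
#' @examples
#' opportunity_for_selection(c(0.5, 1, 1.5))
#' @export
opportunity_for_selection <- function(relative_matings) {
  if (length(relative_matings) < 2L) {
    abort("Need >= 2 values to estimate a variance.")
  }
  var(relative_matings)
}

#' Bateman gradient from a line-level mixed model
#'
#' Fits relative reproductive success on absolute mating count with a
#' random intercept per replicate line (REML), assuming a common gradient
#' across lines. With a single line, or when the estimated line variance is
#' zero (singular fit), the model degrades gracefully to ordinary least
#' squares.
#'
#' @param records Tibble for one sex and regime with columns `matings`,
#'   `offspring`, `line_id`; zero-mating individuals already excluded.
#' @param relative_offspring Optional precomputed relative reproductive
#'   success; defaults to `offspring / mean(offspring)`.
#' @return One-row tibble: `slope`, `se`, `df`, `t_value`, `p_value`,
#'   `method` ("lmm" or "ols"), `n`.
#' @export
bateman_gradient <- function(records, relative_offspring = NULL) {
  records <- as_tibble(records)
  if (length(unique(records$matings)) < 2L) {
    abort("Mating counts show no variance; the slope is unidentifiable.")
  }
  y <- relative_offspring %||% relativize(records$offspring)
  df_fit <- tibble(y = y, matings = records$matings,
                   line_id = as.character(records$line_id))
  n_lines <- length(unique(df_fit$line_id))
  use_ols <- n_lines < 2L
  fit <- NULL
  cc <- NULL
  if (!use_ols) {
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(y ~ matings + (1 | line_id), data = df_fit, REML = TRUE)
    ))
    if (lme4::isSingular(fit, tol = 1e-6)) {
      use_ols <- TRUE
    } else {
      # a non-PD Hessian can make the Wald vcov unusable: degrade to OLS
      cc <- tryCatch(suppressWarnings(coef(summary(fit))),
                     error = function(e) NULL)
      if (is.null(cc) || !is.finite(cc["matings", "Std. Error"])) {
        use_ols <- TRUE
      }
    }
  }
  if (use_ols) {
    ols <- lm(y ~ matings, data = df_fit)
    sm <- suppressWarnings(summary(ols))$coefficients
    slope <- sm["matings", "Estimate"]
    se <- sm["matings", "Std. Error"]
    dfree <- ols$df.residual
    method <- "ols"
  } else {
    slope <- cc["matings", "Estimate"]
    se <- cc["matings", "Std. Error"]
    # Wald df: conservative residual-style df for the t statistic
    dfree <- nrow(df_fit) - n_lines - 1L
    method <- "lmm"
  }
  t_value <- if (se > 0) slope / se else Inf * sign(slope)
  p_value <- if (se > 0) 2 * pt(-abs(t_value), df = max(dfree, 1L)) else 0
  tibble(slope = slope, se = se, df = dfree, t_value = t_value,
         p_value = p_value, method = method, n = nrow(df_fit))
}

#' Least-squares slope of relative reproductive on relative mating success
#'
#' @param relative_offspring,relative_matings Equal-length numeric vectors.
#' @return The OLS slope `beta_ss`.
#' @examples
#' ss_slope(c(0.4, 1, 1.6), c(0.5, 1, 1.5))
#' @export
ss_slope <- function(relative_offspring, relative_matings) {
  stopifnot(length(relative_offspring) == length(relative_matings),
            length(relative_matings) >= 2L)
  vx <- var(relative_matings)
  if (vx == 0) abort("Relative mating success has zero variance.")
  cov(relative_matings, relative_offspring) / vx
}

#' Jones index: maximum standardized strength of sexual selection
#'
#' @param I_s Opportunity for sexual selection (>= 0).
#' @param beta_ss Relative-scale selection slope.
#' @return `sqrt(I_s) * beta_ss`.
#' @examples
#' jones_index(0.25, 1.2)
#' @export
jones_index <- function(I_s, beta_ss) {
  if (I_s < 0) abort("`I_s` must be >= 0.")
  sqrt(I_s) * beta_ss
}

#' Z-test of equal slopes between two independent estimates
#'
#' @param b1,b2 Slope estimates.
#' @param se1,se2 Their (positive) standard errors.
#' @return One-row tibble: `z`, `p_value` (two-sided normal).
#' @examples
#' slope_equality_test(1.0, 0.2, 0.3, 0.2)
#' @export
slope_equality_test <- function(b1, se1, b2, se2) {
  if (se1 <= 0 || se2 <= 0) abort("Standard errors must be > 0.")
  z <- (b1 - b2) / sqrt(se1^2 + se2^2)
  tibble(z = z, p_value = 2 * pnorm(-abs(z)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimate sexual-selection metrics per sex and regime
#'
#' Full sexual-selection pipeline: validates the records, excludes
#' zero-mating individuals, relativizes mating and reproductive success
#' within each sex-by-regime group (or per mating population), and computes
#' the opportunity for sexual selection `I_s` (with a nonparametric
#' percentile bootstrap CI over individuals), the mixed-model Bateman
#' gradient `beta_B`, the least-squares slope `beta_ss`, and the Jones
#' index `s_max`, plus a between-regime test of equal Bateman slopes per
#' sex.
#'
#' @param records Assay records (tibble or path-read table).
#' @param config A [run_config()]; supplies the bootstrap count, CI level
#'   and seed.
#' @param relativize_by `"regime"` (default: sex-specific means per regime)
#'   or `"population"` (means per mating population).
#' @return An object of class `"sexsel_fit"`; use [tidy()] for the per-group
#'   metrics and [glance()] for the slope-equality tests.
#' @examples
#' rec <- simulate_mating_assays(synthetic_truth(), seed = 1)
#' fit <- sexsel_estimates(rec, run_config(seed = 1, n_bootstrap = 200))
#' tidy(fit)
#' @export
sexsel_estimates <- function(records, config = run_config(),
                             relativize_by = c("regime", "population")) {
  relativize_by <- match.arg(relativize_by)
  records <- validate_assay_records(records)
  groups <- tidyr::expand_grid(sex = SEXES, regime = REGIMES)
  rows <- vector("list", nrow(groups))
  fits <- list()
  boot_seed <- substream_seed(config$seed, "sexsel_bootstrap")
  for (i in seq_len(nrow(groups))) {
    sx <- groups$sex[i]
    rg <- groups$regime[i]
    sub <- records %>% filter(.data$sex == sx, .data$regime == rg)
    if (nrow(sub) == 0L) next
    excl <- exclude_zero_success(sub)
    kept <- excl$records
    if (nrow(kept) < 3L) {
      abort(sprintf("Too few non-zero individuals for %s/%s.", sx, rg))
    }
    # per-population relativization is only defined where populations hold
    # more than one scored individual (male assays score a single focal
    # male per population, so they always fall back to the regime mean)
    grouping <- rep("all", nrow(kept))
    if (relativize_by == "population") {
      if (all(table(kept$mating_population_id) >= 2L)) {
        grouping <- kept$mating_population_id
      } else {
        inform(sprintf(
          "Per-population relativization unavailable for %s/%s (singleton populations); using the regime mean.",
          sx, rg
        ))
      }
    }
    rel_m <- relativize(kept$matings, grouping)
    rel_o <- relativize(kept$offspring, grouping)
    I_s <- opportunity_for_selection(rel_m)
    ci <- is_bootstrap_ci(kept$matings, grouping, config$n_bootstrap,
                          config$alpha,
                          seed = substream_seed(boot_seed, paste(sx, rg)))
    bg <- bateman_gradient(kept, relative_offspring = rel_o)
    b_ss <- ss_slope(rel_o, rel_m)
    rows[[i]] <- tibble(
      sex = sx, regime = rg, n_used = nrow(kept), n_excluded = excl$n_excluded,
      I_s = I_s, I_s_ci_lower = ci[1L], I_s_ci_upper = ci[2L],
      beta_B = bg$slope, beta_B_se = bg$se, beta_B_p = bg$p_value,
      beta_B_method = bg$method, beta_ss = b_ss,
      s_max = jones_index(I_s, b_ss)
    )
  }
  est <- bind_rows(rows)
  slope_tests <- est %>%
    group_by(.data$sex) %>%
    summarise(
      test = list(slope_equality_test(
        .data$beta_B[.data$regime == "SSS"], .data$beta_B_se[.data$regime == "SSS"],
        .data$beta_B[.data$regime == "WSS"], .data$beta_B_se[.data$regime == "WSS"]
      )),
      .groups = "drop"
    ) %>%
    tidyr::unnest("test")
  structure(list(estimates = est, slope_tests = slope_tests,
                 relativize_by = relativize_by, config = config),
            class = "sexsel_fit")
}

# percentile bootstrap over individuals for I_s, re-relativizing per draw
is_bootstrap_ci <- function(matings, grouping, n_boot, alpha, seed) {
  n <- length(matings)
  stats <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      g <- grouping[idx]
      if (any(tapply(matings[idx], g, mean) == 0)) return(NA_real_)
      var(relativize(matings[idx], g))
    }, numeric(1))
  })
  quantile(stats, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE, names = FALSE)
}

#' @export
print.sexsel_fit <- function(x, ...) {
  cat("Sexual-selection metrics (relativized per",
      if (x$relativize_by == "regime") "sex x regime" else "mating population",
      ")\n\n")
  print(as.data.frame(x$estimates), digits = 3)
  cat("\nEqual-slopes tests (SSS vs WSS):\n")
  print(as.data.frame(x$slope_tests), digits = 3)
  invisible(x)
}

#' @rdname sexsel_estimates
#' @param x A `sexsel_fit` object.
#' @param ... Unused.
#' @export
tidy.sexsel_fit <- function(x, ...) x$estimates

#' @rdname sexsel_estimates
#' @export
glance.sexsel_fit <- function(x, ...) x$slope_tests
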