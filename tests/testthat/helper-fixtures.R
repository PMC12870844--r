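# Fixture builders and independent oracles shared across test files.

# tiny well-formed assay table
make_assays <- function() {
  tibble::tibble(
    individual_id = sprintf("i%d", 1:8),
    sex = rep(c("male", "female"), each = 4),
    line_id = rep(c("WSS_L1", "SSS_L1"), times = 4),
    regime = rep(c("WSS", "SSS"), times = 4),
    mating_population_id = sprintf("p%d", 1:8),
    matings = c(1L, 2L, 0L, 3L, 2L, 1L, 4L, 0L),
    offspring = c(10L, 25L, 0L, 31L, 18L, 12L, 40L, 0L)
  )
}

# balanced crossed double-mating table with fully controllable counts
make_crossed <- function(regime = "WSS", n_lines = 2, per_cell = 3,
                         eggs = 40L, hatch_fun = function(fl, ml, i) 20L) {
  rows <- list()
  for (fl in seq_len(n_lines)) {
    for (ml in seq_len(n_lines)) {
      for (i in seq_len(per_cell)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          female_id = sprintf("%s_f%d_m%d_%d", regime, fl, ml, i),
          regime = regime,
          female_line = sprintf("%s_L%d", regime, fl),
          male_line = sprintf("%s_L%d", regime, ml),
          eggs_total = eggs, hatched = as.integer(hatch_fun(fl, ml, i)),
          first_mating_ok = TRUE, second_mating_ok = TRUE
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

# independent textbook BCa oracle: bias correction from the bootstrap CDF,
# acceleration from the jackknife skewness, quantiles by the same continuous
# rule as the implementation (the quantile convention is shared deliberately;
# z0 and a are recomputed from first principles here)
bca_oracle <- function(t0, t_boot, t_jack, alpha = 0.05) {
  B <- length(t_boot)
  z0 <- qnorm(min(max(sum(t_boot < t0) / B, 1 / (2 * B)), 1 - 1 / (2 * B)))
  jbar <- mean(t_jack)
  num <- sum((jbar - t_jack)^3)
  den <- 6 * sum((jbar - t_jack)^2)^1.5
  a <- if (den > 0) num / den else 0
  lo <- pnorm(z0 + (z0 + qnorm(alpha / 2)) / (1 - a * (z0 + qnorm(alpha / 2))))
  hi <- pnorm(z0 + (z0 + qnorm(1 - alpha / 2)) /
                (1 - a * (z0 + qnorm(1 - alpha / 2))))
  as.numeric(quantile(t_boot, c(lo, hi), type = 6))
}

# naive leave-one-out medians (oracle for the closed-form version)
naive_jackknife_medians <- function(x) {
  vapply(seq_along(x), function(i) median(x[-i]), numeric(1))
}
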