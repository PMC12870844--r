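test_that("zero-success exclusion removes exactly the never-mated", {
  r <- make_assays()
  out <- exclude_zero_success(r)
  expect_equal(out$n_excluded, 2L)
  expect_true(all(out$records$matings >= 1))
  # identity when nothing to exclude; degenerate when everything is
  expect_equal(exclude_zero_success(out$records)$n_excluded, 0L)
  allzero <- dplyr::mutate(r, matings = 0L, offspring = 0L)
  res <- exclude_zero_success(allzero)
  expect_equal(nrow(res$records), 0L)
  expect_equal(res$n_excluded, nrow(r))
})

test_that("relativization divides by group means and errors on zero groups", {
  expect_equal(relativize(c(2, 2, 2)), c(1, 1, 1))
  expect_equal(relativize(c(1, 2, 3)), c(0.5, 1, 1.5))
  g <- c("a", "a", "b", "b")
  out <- relativize(c(1, 3, 10, 30), g)
  expect_equal(as.numeric(tapply(out, g, mean)), c(1, 1))
  expect_error(relativize(c(0, 0)), "mean 0")
})

test_that("opportunity for selection is the sample variance", {
  expect_equal(opportunity_for_selection(c(1, 1, 1, 1)), 0)
  expect_equal(opportunity_for_selection(c(0.5, 1, 1.5)), 0.25)
  expect_error(opportunity_for_selection(1), ">= 2")
})

test_that("least-squares slope and Jones index match hand arithmetic", {
  expect_equal(ss_slope(c(0.5, 1, 1.5), c(0.5, 1, 1.5)), 1.0)
  expect_equal(ss_slope(c(1, 1, 1), c(0.5, 1, 1.5)), 0.0)
  expect_equal(ss_slope(c(0.4, 1.0, 1.6), c(0.5, 1.0, 1.5)), 1.2)
  expect_error(ss_slope(c(1, 2), c(1, 1)), "zero variance")
  expect_equal(jones_index(0, 5), 0)
  expect_equal(jones_index(0.25, 1.2), 0.6)
  expect_equal(jones_index(1, -0.04), -0.04) # negative index is legal
  expect_error(jones_index(-0.1, 1), ">= 0")
})

test_that("slope-equality Z test matches the normal-tail oracle", {
  t0 <- slope_equality_test(1, 0.2, 1, 0.2)
  expect_equal(t0$z, 0)
  expect_equal(t0$p_value, 1)
  t1 <- slope_equality_test(1.0, 0.2, 0.3, 0.2)
  expect_equal(t1$z, 0.7 / sqrt(0.08), tolerance = 1e-12)
  expect_equal(t1$p_value, 2 * pnorm(-0.7 / sqrt(0.08)), tolerance = 1e-12)
  expect_equal(round(t1$z, 4), 2.4749)
  expect_equal(round(t1$p_value, 4), 0.0133)
  expect_error(slope_equality_test(1, 0, 1, 0.1), "> 0")
})

test_that("Bateman gradient recovers an exact linear relationship", {
  d <- tibble::tibble(matings = 1:6, offspring = 0L,
                      line_id = "L1")
  rel <- 0.2 + 0.4 * d$matings
  bg <- bateman_gradient(d, relative_offspring = rel)
  expect_equal(bg$slope, 0.4, tolerance = 1e-10)
  expect_equal(bg$se, 0, tolerance = 1e-10)
  expect_equal(bg$method, "ols") # single line degrades to OLS
  expect_error(
    bateman_gradient(tibble::tibble(matings = c(2, 2), offspring = c(1, 2),
                                    line_id = "L1")),
    "unidentifiable"
  )
})

test_that("the line random intercept removes between-line confounding", {
  # two lines share within-line slope 0.4 but differ in intercept, and
  # their mating distributions differ, so pooled OLS is biased; oracle is
  # the common within-line OLS slope
  d <- tibble::tibble(
    line_id = rep(c("L1", "L2"), each = 25),
    matings = c(rep(1:5, 5), rep(6:10, 5))
  )
  set.seed(42)
  d$rel <- ifelse(d$line_id == "L1", 0, 1) + 0.4 * d$matings +
    rnorm(50, 0, 0.05)
  ols_within <- mean(c(
    coef(lm(rel ~ matings, data = d[d$line_id == "L1", ]))[2],
    coef(lm(rel ~ matings, data = d[d$line_id == "L2", ]))[2]
  ))
  pooled <- unname(coef(lm(rel ~ matings, data = d))[2])
  bg <- bateman_gradient(d, relative_offspring = d$rel)
  expect_equal(bg$slope, ols_within, tolerance = 0.05)
  # pooled OLS is visibly dragged toward the between-line axis
  expect_gt(abs(pooled - 0.4), abs(bg$slope - 0.4))
})

test_that("sexsel metrics are invariant to within-regime count rescaling", {
  truth <- synthetic_truth()
  rec <- simulate_mating_assays(truth, seed = 14)
  cfg <- run_config(seed = 2, n_bootstrap = 120)
  base <- tidy(sexsel_estimates(rec, cfg))
  scaled <- dplyr::mutate(rec, offspring = offspring * 7L)
  out <- tidy(sexsel_estimates(scaled, cfg))
  expect_equal(out$I_s, base$I_s)
  expect_equal(out$beta_ss, base$beta_ss, tolerance = 1e-10)
  expect_equal(out$s_max, base$s_max, tolerance = 1e-10)
  # beta_B regresses relative RS on absolute matings: unchanged by the
  # offspring rescaling too (the response is relative), while scaling the
  # mating axis would change it by the reciprocal factor
  expect_equal(out$beta_B, base$beta_B, tolerance = 1e-10)
})

test_that("relativizing per mating population is supported", {
  rec <- simulate_mating_assays(synthetic_truth(), seed = 8)
  cfg <- run_config(seed = 1, n_bootstrap = 120)
  fit <- sexsel_estimates(rec, cfg, relativize_by = "population")
  expect_s3_class(fit, "sexsel_fit")
  expect_equal(nrow(tidy(fit)), 4L)
  expect_false(identical(tidy(fit)$I_s,
                         tidy(sexsel_estimates(rec, cfg))$I_s))
})

test_that("the full sexsel pipeline is deterministic under a fixed config", {
  rec <- simulate_mating_assays(synthetic_truth(), seed = 4)
  cfg <- run_config(seed = 9, n_bootstrap = 150)
  expect_identical(tidy(sexsel_estimates(rec, cfg)),
                   tidy(sexsel_estimates(rec, cfg)))
})
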