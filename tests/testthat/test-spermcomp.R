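test_that("the competing-female filter applies all inclusion rules", {
  d <- make_crossed(per_cell = 1)
  d$hatched[1] <- 0L            # P2 = 0: focal male never competed
  d$second_mating_ok[2] <- FALSE
  d$first_mating_ok[3] <- FALSE
  kept <- filter_competing_females(d)
  expect_equal(nrow(kept), nrow(d) - 3L)
  expect_true(all(kept$hatched >= 1 & kept$eggs_total >= 1))
})

test_that("P2 is the hatched share of eggs laid", {
  d <- tibble::tibble(eggs_total = c(40L, 40L, 3L), hatched = c(20L, 40L, 1L))
  expect_equal(compute_p2(d), c(0.5, 1, 1 / 3))
  expect_error(compute_p2(tibble::tibble(eggs_total = 0L, hatched = 0L)),
               "zero eggs")
})

test_that("identical cells give an all-zero deviance table", {
  # every cell holds the same three females, so cell means are identical
  # and all term deviances (and F) are exactly zero, while within-cell
  # variation keeps the dispersion estimable
  d <- make_crossed(n_lines = 2, per_cell = 3,
                    hatch_fun = function(fl, ml, i) c(18L, 20L, 22L)[i])
  fit <- fit_crossed_glm(d)
  tab <- tidy(fit)
  expect_equal(tab$deviance[tab$term != "residual"], rep(0, 3),
               tolerance = 1e-10)
  expect_equal(tab$f_statistic[tab$term != "residual"], rep(0, 3),
               tolerance = 1e-10)
  expect_gt(fit$dispersion, 0)
})

test_that("the sequential deviance table matches nested refits exactly", {
  dm <- filter_competing_females(
    simulate_double_matings(synthetic_truth(), seed = 31)
  )
  d <- dplyr::filter(dm, regime == "SSS")
  fit <- fit_crossed_glm(d)
  tab <- fit$deviance_table
  # oracle: deviance differences of explicitly nested binomial fits
  d2 <- dplyr::mutate(d, male_line = factor(male_line),
                      female_line = factor(female_line))
  dev <- function(f) glm(f, family = binomial(), data = d2)$deviance
  d0 <- dev(cbind(hatched, eggs_total - hatched) ~ 1)
  d1 <- dev(cbind(hatched, eggs_total - hatched) ~ male_line)
  d12 <- dev(cbind(hatched, eggs_total - hatched) ~ male_line + female_line)
  d123 <- dev(cbind(hatched, eggs_total - hatched) ~ male_line * female_line)
  expect_equal(tab$deviance[tab$term == "male_line"], d0 - d1,
               tolerance = 1e-8)
  expect_equal(tab$deviance[tab$term == "female_line"], d1 - d12,
               tolerance = 1e-8)
  expect_equal(tab$deviance[tab$term == "male_line:female_line"], d12 - d123,
               tolerance = 1e-8)
  expect_equal(tab$deviance[tab$term == "residual"], d123, tolerance = 1e-8)
  # deviance additivity: term deviances + residual = null deviance
  expect_equal(sum(tab$deviance), d0, tolerance = 1e-6 * d0)
  # interaction df for a complete 4x4 cross
  expect_equal(tab$df[tab$term == "male_line:female_line"], 9L)
  # eta^2 is the interaction share of total deviance
  expect_equal(fit$eta_squared_interaction,
               (d12 - d123) / d0, tolerance = 1e-6)
  # predicted mean lies between the extreme cell means
  cell_p2 <- dplyr::summarise(
    dplyr::group_by(d, male_line, female_line),
    p = sum(hatched) / sum(eggs_total), .groups = "drop"
  )
  expect_gte(fit$predicted_mean_p2, min(cell_p2$p))
  expect_lte(fit$predicted_mean_p2, max(cell_p2$p))
})

test_that("empty design cells are reported by name", {
  d <- make_crossed(n_lines = 2, per_cell = 2)
  d <- d[!(d$male_line == "WSS_L2" & d$female_line == "WSS_L1"), ]
  expect_error(fit_crossed_glm(d), "Empty design cell")
})

test_that("saturated cells trigger the shrunken-count fallback, not failure", {
  d <- make_crossed(n_lines = 2, per_cell = 2,
                    hatch_fun = function(fl, ml, i) {
                      if (fl == 1 && ml == 1) 40L else 20L
                    })
  expect_warning(fit <- fit_crossed_glm(d), "saturated")
  expect_true(is.finite(fit$dispersion))
})

test_that("arcsine-square-root transform and the self-comparison F", {
  expect_equal(asin(sqrt(0.25)), pi / 6, tolerance = 1e-12)
  dm <- filter_competing_females(
    simulate_double_matings(synthetic_truth(), seed = 13)
  )
  wss <- dplyr::filter(dm, regime == "WSS")
  sss_alias <- dplyr::mutate(wss, regime = "SSS") # identical data twice
  out <- lmm_share_and_ratio_test(wss, sss_alias)
  expect_equal(out$test$f_statistic, 1)
  expect_equal(out$test$p_one_sided, 0.5)
  expect_equal(out$test$df1, 9)
  expect_equal(out$test$df2, 9)
  expect_true(all(out$by_regime$share_percent >= 0 &
                    out$by_regime$share_percent <= 100))
})

test_that("interaction variance component estimation is deterministic", {
  dm <- filter_competing_females(
    simulate_double_matings(synthetic_truth(), seed = 17)
  )
  sss <- dplyr::filter(dm, regime == "SSS")
  a <- interaction_variance_component(sss)
  b <- interaction_variance_component(sss)
  expect_identical(a$varcomp, b$varcomp)
  expect_gte(a$varcomp, 0)
  expect_true(is.finite(a$se) && a$se > 0)
  # the moments route agrees on order of magnitude
  m <- interaction_variance_component(sss, method = "moments")
  expect_lt(abs(m$varcomp - a$varcomp), 0.5)
})

test_that("residual cell bootstrap: BCa matches the oracle and tests behave", {
  dm <- filter_competing_females(
    simulate_double_matings(synthetic_truth(), seed = 23)
  )
  wss <- dplyr::filter(dm, regime == "WSS")
  sss <- dplyr::filter(dm, regime == "SSS")
  out <- residual_cell_bootstrap(wss, sss, n_boot = 400, seed = 5)
  expect_equal(out$by_regime$n_cells, c(16L, 16L))
  expect_equal(out$test$df1[out$test$type == "variance_ratio_one_sided"], 15)
  expect_gte(min(out$by_regime$cell_variance), 0)
  # Bartlett on two identical groups of cell means is exactly zero
  cm <- out$cell_means$WSS
  bt <- bartlett.test(c(cm, cm), factor(rep(1:2, each = length(cm))))
  expect_equal(unname(bt$statistic), 0, tolerance = 1e-12)
  # BCa interval on a fixed 16-value sample matches the textbook oracle
  x <- out$cell_means$SSS
  t0 <- var(x)
  t_boot <- withr::with_seed(99, {
    vapply(1:2000, function(i) var(x[sample.int(16, 16, replace = TRUE)]),
           numeric(1))
  })
  t_jack <- vapply(1:16, function(i) var(x[-i]), numeric(1))
  ours <- bca_interval(t0, t_boot, t_jack)
  oracle <- bca_oracle(t0, t_boot, t_jack)
  expect_equal(unname(ours), oracle, tolerance = 1e-3)
})

test_that("rank-sum comparison handles identity, separation and ties", {
  # identical groups: statistic at its null mean, two-sided p maximal
  d0 <- dplyr::bind_rows(
    make_crossed("WSS", n_lines = 2, per_cell = 2,
                 hatch_fun = function(fl, ml, i) 10L + 2L * i),
    make_crossed("SSS", n_lines = 2, per_cell = 2,
                 hatch_fun = function(fl, ml, i) 10L + 2L * i)
  )
  out0 <- within_vs_between_comparison(d0)
  expect_true(all(out0$p_two_sided >= 0.99))
  # complete separation at n = (3, 3): smallest attainable one-sided exact
  # p is 1/choose(6,3) = 0.05 (enumeration over the 20 rank arrangements)
  one_regime <- function(rg) tibble::tibble(
    female_id = sprintf("%s%d", rg, 1:6), regime = rg,
    female_line = paste0(rg, "_L1"),
    male_line = paste0(rg, c("_L1", "_L1", "_L1", "_L2", "_L2", "_L2")),
    eggs_total = 100L,
    hatched = c(90L, 92L, 94L, 10L, 12L, 14L) +
      if (rg == "SSS") 1L else 0L,
    first_mating_ok = TRUE, second_mating_ok = TRUE
  )
  d1 <- dplyr::bind_rows(one_regime("WSS"), one_regime("SSS"))
  out1 <- within_vs_between_comparison(d1)
  expect_equal(out1$p_one_sided[out1$scope == "WSS"], 1 / 20,
               tolerance = 1e-10)
  expect_equal(out1$p_one_sided[out1$scope == "combined"], 1 / choose(12, 6),
               tolerance = 1e-10)
  # tied groups do not error
  dt <- dplyr::bind_rows(make_crossed("WSS", n_lines = 2, per_cell = 2),
                         make_crossed("SSS", n_lines = 2, per_cell = 2))
  expect_equal(within_vs_between_comparison(dt)$p_two_sided,
               rep(1, 3), tolerance = 1e-9)
})

test_that("the assembled sperm-competition report is internally consistent", {
  dm <- simulate_double_matings(synthetic_truth(), seed = 41)
  fit <- spermcomp_analysis(dm, run_config(seed = 2, n_bootstrap = 150))
  g <- glance(fit)
  expect_setequal(g$regime, c("WSS", "SSS"))
  expect_true(all(g$predicted_mean_p2 > 0 & g$predicted_mean_p2 < 1))
  expect_true(all(g$interaction_varcomp >= 0))
  expect_true(all(g$lmm_share_percent >= 0 & g$lmm_share_percent <= 100))
  expect_equal(fit$n_used + fit$n_excluded, nrow(dm))
})
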