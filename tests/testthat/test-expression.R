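test_that("cpm and the expressed-transcript filter follow their contracts", {
  counts <- matrix(c(2, 50, 0, 0), 2, 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  out <- cpm(counts, c(1e6, 2.5e7))
  expect_equal(out["g1", "s1"], 2.0)
  expect_equal(out["g2", "s1"], 50.0)
  expect_equal(out["g2", "s2"], 0.0)
  expect_error(cpm(counts, c(0, 1)), "> 0")

  m <- matrix(c(2.1, 3, 5, 2.01,   # retained: all strictly above 2
                2.0, 3, 5, 4),     # excluded: one sample exactly at 2
              nrow = 2, byrow = TRUE,
              dimnames = list(c("keep", "drop"), sprintf("s%d", 1:4)))
  expect_equal(filter_expressed(m, colnames(m), 2), "keep")
  expect_error(filter_expressed(m, character(0)), "empty")
})

test_that("normalization modes behave as declared", {
  samples <- tibble::tibble(
    sample_id = sprintf("s%d", 1:4),
    sex = rep("male", 4), regime = rep(c("WSS", "SSS"), each = 2),
    line_id = sprintf("L%d", 1:4)
  )
  counts <- matrix(c(1e6, 0, 30, 50,
                     0, 20, 40, 60), 2, 4, byrow = TRUE,
                   dimnames = list(c("g1", "g2"), samples$sample_id))
  ed <- expression_data(NULL, samples, counts = counts,
                        lib_sizes = rep(1e6, 4))
  ed <- normalize_expression(ed, "log_cpm")
  expect_equal(ed$values["g1", "s1"], log2(1e6 + 0.5), tolerance = 1e-12)
  expect_equal(ed$values["g1", "s2"], log2(0.5)) # zero count -> -1
  expect_equal(ed$values["g1", "s2"], -1)
  # precomputed passes through untouched
  ed2 <- normalize_expression(ed, "precomputed")
  expect_identical(ed2$values, ed$values)
  expect_error(normalize_expression(expression_data(NULL, samples,
                                                    counts = counts),
                                    "precomputed"),
               "already")
})

test_that("replicate divergence and the ratio match hand arithmetic", {
  expect_equal(replicate_divergence(c(5, 5, 5, 5)), 0)
  expect_equal(replicate_divergence(c(1, 2, 3, 4)), 1.0)
  expect_equal(replicate_divergence(c(0, 10)), 5.0)
  expect_error(replicate_divergence(3), ">= 2")
  expect_equal(divergence_ratio(0.7, 0.7), 1.0)
  expect_equal(divergence_ratio(1.5, 1.0), 1.5)
  expect_true(is.na(divergence_ratio(1.5, 0))) # undefined, flagged as NA
})

test_that("divergence is scale-equivariant and location-invariant", {
  ed <- simulate_expression(synthetic_truth(), n_genes = 300,
                            geneset_spec = c(SFP = 20L), seed = 6)
  base <- divergence_table(ed, "female")
  ed_scaled <- ed
  ed_scaled$values <- ed$values * 3
  scaled <- divergence_table(ed_scaled, "female")
  expect_equal(scaled$d_WSS, 3 * base$d_WSS, tolerance = 1e-12)
  expect_equal(scaled$d_SSS, 3 * base$d_SSS, tolerance = 1e-12)
  expect_equal(scaled$ratio, base$ratio, tolerance = 1e-12)
  ed_shift <- ed
  ed_shift$values <- ed$values + 11.5
  shifted <- divergence_table(ed_shift, "female")
  expect_equal(shifted$d_WSS, base$d_WSS, tolerance = 1e-9)
  expect_equal(shifted$ratio, base$ratio, tolerance = 1e-9)
})

test_that("bootstrap median summary degenerates and matches its oracle", {
  const <- bootstrap_median_summary(rep(1.3, 10), n_boot = 200, seed = 1)
  expect_equal(const$boot_mean_median, 1.3)
  expect_equal(c(const$ci_lower, const$ci_upper), c(1.3, 1.3))

  x <- c(0.8, 0.9, 0.95, 1.0, 1.02, 1.1, 1.2, 1.35, 1.5, 2.0)
  ours <- bootstrap_median_summary(x, n_boot = 2000, seed = 42)
  # reconstruct the identical bootstrap replicates and feed the oracle
  t_boot <- withr::with_seed(42, {
    vapply(1:2000, function(i) median(x[sample.int(10, 10, replace = TRUE)]),
           numeric(1))
  })
  oracle <- bca_oracle(median(x), t_boot, naive_jackknife_medians(x))
  expect_equal(c(ours$ci_lower, ours$ci_upper), oracle, tolerance = 1e-3)
  expect_equal(ours$boot_mean_median, mean(t_boot), tolerance = 1e-12)
  # resampling consistency: bootstrap mean median near the sample median
  expect_lt(abs(ours$boot_mean_median - median(x)),
            3 * sd(t_boot) / sqrt(length(t_boot)) + 0.05)
  expect_error(bootstrap_median_summary(c(1, 2), n_boot = 200), ">= 3")
  expect_error(bootstrap_median_summary(1:10, n_boot = 50), ">= 100")
})

test_that("closed-form jackknife medians equal the naive leave-one-out", {
  for (n in c(3, 4, 7, 10, 11, 16)) {
    x <- withr::with_seed(n, rnorm(n))
    expect_equal(sexseldiv:::jackknife_medians(x), naive_jackknife_medians(x))
  }
  # with duplicated values too
  x <- c(1, 1, 2, 2, 3, 3, 3)
  expect_equal(sexseldiv:::jackknife_medians(x), naive_jackknife_medians(x))
})

test_that("set-versus-background tests cover identity and separation", {
  same <- set_vs_background_tests(c(1, 1.1, 1.2), c(1, 1.1, 1.2))
  expect_equal(same$ks_D, 0)
  expect_equal(same$ks_p, 1)
  sep <- set_vs_background_tests(rep(2, 4), rep(1, 4))
  expect_equal(sep$ks_D, 1)
  expect_error(set_vs_background_tests(numeric(0), 1:3), "nonempty")
})

test_that("set-vs-background KS p is uniform under equal replicate SDs", {
  # a larger set keeps the discrete KS statistic on a fine grid, so the
  # meta-test of uniformity is meaningful
  eq_truth <- synthetic_truth(
    replicate_sd_by_regime_and_geneset = tibble::tibble(
      gene_set = rep(c("background", "SFP"), each = 2),
      regime = rep(c("WSS", "SSS"), 2), sd = rep(0.5, 4)
    )
  )
  ks_p <- vapply(1:200, function(s) {
    ed <- simulate_expression(eq_truth, n_genes = 2000,
                              geneset_spec = c(SFP = 200L), seed = s)
    tab <- divergence_table(ed, "male")
    in_set <- tab$gene_id %in% ed$gene_sets$SFP
    set_vs_background_tests(tab$ratio[in_set], tab$ratio[!in_set])$ks_p
  }, numeric(1))
  meta <- suppressWarnings(ks.test(ks_p, "punif"))
  expect_gt(meta$p.value, 0.01)
})

test_that("a shifted set is detected by the one-sided Mann-Whitney test", {
  # power property: SD ratio 1.5 for a 50-gene set against a large
  # background is reliably detected
  shift_truth <- synthetic_truth()
  hits <- vapply(1:50, function(s) {
    ed <- simulate_expression(shift_truth, n_genes = 2000,
                              geneset_spec = c(SFP = 50L), seed = 700 + s)
    tab <- divergence_table(ed, "male")
    in_set <- tab$gene_id %in% ed$gene_sets$SFP
    set_vs_background_tests(tab$ratio[in_set],
                            tab$ratio[!in_set])$mw_p_one_sided < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.95)
})

test_that("the best-hit ortholog filter applies threshold and tie-breaks", {
  hits <- tibble::tibble(
    query_id = c("q1", "q1", "q2", "q3", "q3"),
    subject_id = c("sA", "sB", "sC", "sD", "sE"),
    percent_identity = c(95, 92, 89.9, 91, 91),
    alignment_length = 100L,
    evalue = c(1e-50, 1e-10, 1e-60, 1e-20, 1e-20),
    bitscore = c(200, 150, 300, 180, 200)
  )
  map <- ortholog_best_hit_filter(hits, min_identity = 90)
  expect_equal(map$subject_id[map$query_id == "q1"], "sA") # lowest e-value
  expect_false("q2" %in% map$query_id)                     # below threshold
  expect_equal(map$subject_id[map$query_id == "q3"], "sE") # bitscore tie-break
  # exact-threshold identity is retained (>=)
  at90 <- dplyr::mutate(hits[4, ], percent_identity = 90)
  expect_equal(nrow(ortholog_best_hit_filter(at90)), 1L)
  # e-value tie AND bitscore tie: lexicographic subject id
  tie <- tibble::tibble(
    query_id = "q", subject_id = c("sZ", "sA"), percent_identity = 95,
    alignment_length = 100L, evalue = 1e-5, bitscore = 100
  )
  expect_equal(ortholog_best_hit_filter(tie)$subject_id, "sA")
})

test_that("the assembled divergence analysis reports sets and undefined genes", {
  ed <- simulate_expression(synthetic_truth(), n_genes = 400,
                            geneset_spec = c(SFP = 30L, FRP = 30L), seed = 3)
  # force one undefined ratio: make a gene constant across WSS females
  f_wss <- ed$samples$sample_id[ed$samples$sex == "female" &
                                  ed$samples$regime == "WSS"]
  ed$values["g00200", f_wss] <- 5
  fit <- expression_divergence(ed, ed$gene_sets,
                               run_config(seed = 2, n_bootstrap = 150))
  g <- glance(fit)
  expect_setequal(g$set, c("all_male", "all_female", "SFP", "FRP"))
  expect_equal(g$n_undefined[g$set == "all_female"], 1L)
  expect_equal(fit$tests$set, c("SFP", "FRP"))
  expect_true(all(fit$tests$ks_D >= 0 & fit$tests$ks_D <= 1))
  # determinism under a fixed config
  fit2 <- expression_divergence(ed, ed$gene_sets,
                                run_config(seed = 2, n_bootstrap = 150))
  expect_identical(glance(fit), glance(fit2))
})
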