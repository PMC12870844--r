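# Synthetic-data generators. Each one is deterministic given (truth, sizes,
# seed): all draws happen inside a named substream of the top-level seed, so
# adding a generator never perturbs another generator's output.

#' Simulate mating-population assay records
#'
#' Emulates competitive mating assays in which five males and five females
#' share a dish and every copulation is observed. Male assays contain a
#' single fertile focal male (the others are sterilized), so each male-assay
#' population yields one focal-male record; female assays use all-fertile
#' males and yield five female records per population.
#'
#' Lifetime mating counts are Poisson with the regime-specific mean from
#' `truth`; expected reproductive success is linear in mating count with the
#' regime's Bateman slope expressed on the relative-fitness scale (so the
#' slope of relative reproductive success on absolute mating count equals
#' the truth value), plus an additive line effect, with Poisson noise around
#' the (floored at zero) linear predictor. An individual that never mated
#' has zero reproductive success by construction.
#'
#' @param truth A [synthetic_truth()] object.
#' @param n_populations_per_line Male-assay mating populations per replicate
#'   line (default 5).
#' @param lines_per_regime Replicate lines per regime (default 4).
#' @param seed Integer top-level seed.
#' @param n_female_populations_per_line Female-assay populations per line
#'   (default 3).
#' @param mean_rs Named numeric, target mean reproductive success per sex
#'   (offspring counts; males aggregate the output of five females, hence
#'   the larger default).
#' @return A tibble of assay records: `individual_id`, `sex`, `line_id`,
#'   `regime`, `mating_population_id`, `matings`, `offspring`.
#' @examples
#' head(simulate_mating_assays(synthetic_truth(), seed = 1))
#' @export
simulate_mating_assays <- function(truth, n_populations_per_line = 5L,
                                   lines_per_regime = 4L, seed = 1L,
                                   n_female_populations_per_line = 3L,
                                   mean_rs = c(male = 100, female = 30)) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_populations_per_line < 1 || lines_per_regime < 1 ||
      n_female_populations_per_line < 1) {
    abort("Population and line counts must be >= 1.")
  }
  withr::with_seed(substream_seed(seed, "mating_assays"), {
    out <- vector("list", 0L)
    for (regime in REGIMES) {
      rate <- truth$mating_rate_by_regime[[regime]]
      slope <- truth$bateman_slope_by_regime[[regime]]
      for (sex in SEXES) {
        mu_rs <- mean_rs[[sex]]
        b_abs <- slope * mu_rs
        a <- mu_rs * (1 - slope * rate)
        n_pop <- if (sex == "male") n_populations_per_line else n_female_populations_per_line
        per_pop <- if (sex == "male") 1L else 5L
        for (line in seq_len(lines_per_regime)) {
          line_id <- sprintf("%s_L%d", regime, line)
          line_eff <- rnorm(1L, 0, truth$line_effect_sd)
          for (pop in seq_len(n_pop)) {
            pop_id <- sprintf("%s_%s_P%d", line_id, substr(sex, 1, 1), pop)
            matings <- rpois(per_pop, rate)
            lp <- pmax(0, a + b_abs * matings + line_eff)
            offspring <- rpois(per_pop, lp)
            offspring[matings == 0L] <- 0L # no mate, no offspring
            out[[length(out) + 1L]] <- tibble(
              individual_id = sprintf("%s_I%d", pop_id, seq_len(per_pop)),
              sex = sex, line_id = line_id, regime = regime,
              mating_population_id = pop_id,
              matings = as.integer(matings), offspring = as.integer(offspring)
            )
          }
        }
      }
    }
    bind_rows(out)
  })
}

#' Poisson specification for eggs laid per female
#'
#' Returns a draw function for per-female total egg counts, guaranteed
#' positive (a zero draw, vanishingly rare at realistic means, is bumped to
#' one so the binomial denominator is always valid).
#'
#' @param mean Positive mean egg count (default 40).
#' @return A function of `n` returning `n` positive integers.
#' @export
eggs_poisson <- function(mean = 40) {
  if (!is.numeric(mean) || mean <= 0) abort("Egg-count mean must be > 0.")
  function(n) pmax(1L, rpois(n, mean))
}

# beta-binomial with intra-class correlation rho; rho = 0 degrades to binomial
rbetabinom_icc <- function(n, size, prob, rho) {
  if (rho <= 0) return(rbinom(n, size, prob))
  shape_sum <- (1 - rho) / rho
  p <- rbeta(n, prob * shape_sum, (1 - prob) * shape_sum)
  rbinom(n, size, p)
}

#' Simulate a fully crossed double-mating design
#'
#' Emulates sperm-competition assays in which each female is first mated to
#' a sterilized male of her own line and then to a fertile focal male from
#' one of the regime's lines, giving a complete female-line x male-line
#' cross within each regime. Hatched counts are beta-binomial around
#' `plogis(logit(baseline_p2) + male line + female line + cell interaction)`
#' with the cell interaction drawn once per (male line, female line) cell
#' from `Normal(0, interaction_sd^2)` and intra-female correlation
#' `overdispersion_rho`.
#'
#' @param truth A [synthetic_truth()] object.
#' @param lines_per_regime Lines per regime (default 4, giving 16 cells).
#' @param n_females_per_cell Females per cell (default 7).
#' @param eggs_per_female Draw function for per-female egg totals, e.g.
#'   [eggs_poisson()].
#' @param seed Integer top-level seed.
#' @return A tibble of double-mating records: `female_id`, `regime`,
#'   `female_line`, `male_line`, `eggs_total`, `hatched`, `first_mating_ok`,
#'   `second_mating_ok`.
#' @examples
#' head(simulate_double_matings(synthetic_truth(), seed = 1))
#' @export
simulate_double_matings <- function(truth, lines_per_regime = 4L,
                                    n_females_per_cell = 7L,
                                    eggs_per_female = eggs_poisson(40),
                                    seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (lines_per_regime < 1 || n_females_per_cell < 1) {
    abort("Line and per-cell female counts must be >= 1.")
  }
  if (!is.function(eggs_per_female)) {
    abort("`eggs_per_female` must be a draw function (see eggs_poisson()).")
  }
  probe <- withr::with_seed(1L, eggs_per_female(5L))
  if (!is.numeric(probe) || any(probe < 1) || any(probe != floor(probe))) {
    abort("`eggs_per_female` must return positive integers.")
  }
  withr::with_seed(substream_seed(seed, "double_matings"), {
    out <- vector("list", 0L)
    for (regime in REGIMES) {
      mu0 <- logit(truth$baseline_p2_by_regime[[regime]])
      isd <- truth$interaction_sd_by_regime[[regime]]
      a_m <- rnorm(lines_per_regime, 0, truth$line_effect_sd)
      b_f <- rnorm(lines_per_regime, 0, truth$line_effect_sd)
      for (fl in seq_len(lines_per_regime)) {
        for (ml in seq_len(lines_per_regime)) {
          cell_eff <- rnorm(1L, 0, isd)
          p_cell <- inv_logit(mu0 + a_m[ml] + b_f[fl] + cell_eff)
          eggs <- eggs_per_female(n_females_per_cell)
          hatched <- rbetabinom_icc(n_females_per_cell, eggs, p_cell,
                                    truth$overdispersion_rho)
          out[[length(out) + 1L]] <- tibble(
            female_id = sprintf("%s_F%d_M%d_%d", regime, fl, ml,
                                seq_len(n_females_per_cell)),
            regime = regime,
            female_line = sprintf("%s_L%d", regime, fl),
            male_line = sprintf("%s_L%d", regime, ml),
            eggs_total = as.integer(eggs), hatched = as.integer(hatched),
            first_mating_ok = TRUE, second_mating_ok = TRUE
          )
        }
      }
    }
    bind_rows(out)
  })
}

#' Simulate a replicate-line expression matrix with designated gene sets
#'
#' Builds one sample per (sex, regime, replicate line) on the normalized
#' (log-like) expression scale. Each gene has a fixed baseline; its value in
#' a given line is baseline + Normal(0, sd^2) where sd comes from the
#' truth's replicate-SD table for the gene's set (genes outside every named
#' set use the "background" SDs). The deviations are independent across
#' (gene, sex, regime, line).
#'
#' @param truth A [synthetic_truth()] object.
#' @param n_genes Total gene count.
#' @param geneset_spec Named integer vector: genes per designated set (sets
#'   are disjoint by construction; sizes must sum to <= `n_genes`). Set
#'   names must appear in the truth's replicate-SD table.
#' @param n_lines_per_regime Replicate lines per regime (default 4).
#' @param seed Integer top-level seed.
#' @return An object of class `"expression_data"` (see [expression_data()])
#'   with the gene-set membership in `$gene_sets` and the generating truth
#'   in `$truth`.
#' @examples
#' ed <- simulate_expression(synthetic_truth(), n_genes = 200,
#'                           geneset_spec = c(SFP = 10, FRP = 10), seed = 1)
#' dim(ed$values)
#' @export
simulate_expression <- function(truth, n_genes = 20000L,
                                geneset_spec = c(SFP = 50L, FRP = 96L),
                                n_lines_per_regime = 4L, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_genes < 1) abort("`n_genes` must be >= 1.")
  if (length(geneset_spec) > 0) {
    if (is.null(names(geneset_spec)) || any(!nzchar(names(geneset_spec)))) {
      abort("`geneset_spec` must be a named vector of set sizes.")
    }
    if (anyDuplicated(names(geneset_spec))) {
      abort("Gene sets must be disjoint: duplicated set name in `geneset_spec`.")
    }
    if (sum(geneset_spec) > n_genes) {
      abort("Gene-set sizes exceed `n_genes`.")
    }
  }
  sd_tab <- truth$replicate_sd_by_regime_and_geneset
  missing_sets <- setdiff(names(geneset_spec), sd_tab$gene_set)
  if (length(missing_sets) > 0) {
    abort(sprintf("No replicate SDs in truth for set(s): %s.",
                  paste(missing_sets, collapse = ", ")))
  }
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  set_of <- rep("background", n_genes)
  idx <- 0L
  gene_sets <- list()
  for (nm in names(geneset_spec)) {
    take <- idx + seq_len(geneset_spec[[nm]])
    set_of[take] <- nm
    gene_sets[[nm]] <- gene_ids[take]
    idx <- idx + geneset_spec[[nm]]
  }
  samples <- tidyr::expand_grid(
    sex = SEXES, regime = REGIMES, line = seq_len(n_lines_per_regime)
  ) %>%
    mutate(
      line_id = sprintf("%s_L%d", .data$regime, .data$line),
      sample_id = sprintf("%s_%s_L%d", substr(.data$sex, 1, 1), .data$regime,
                          .data$line)
    ) %>%
    select("sample_id", "sex", "regime", line_id = "line_id")
  sd_lookup <- setNames(sd_tab$sd, paste(sd_tab$gene_set, sd_tab$regime))
  withr::with_seed(substream_seed(seed, "expression"), {
    baseline <- runif(n_genes, 2, 12)
    values <- matrix(0, nrow = n_genes, ncol = nrow(samples),
                     dimnames = list(gene_ids, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      sds <- sd_lookup[paste(set_of, samples$regime[j])]
      values[, j] <- baseline + rnorm(n_genes, 0, sds)
    }
    ed <- expression_data(values, samples)
    ed$gene_sets <- gene_sets
    ed$truth <- truth
    ed
  })
}

#' Container for a normalized gene-by-sample expression matrix
#'
#' @param values Numeric gene x sample matrix with row (gene) and column
#'   (sample) names; normalized expression.
#' @param samples Data frame with one row per sample: `sample_id`, `sex`,
#'   `regime`, `line_id`. The design requires exactly one sample per
#'   (sex, regime, line).
#' @param counts Optional raw-count matrix with the same dimnames.
#' @param lib_sizes Optional named positive library sizes per sample.
#' @return A list with class `"expression_data"`.
#' @export
expression_data <- function(values, samples, counts = NULL, lib_sizes = NULL) {
  samples <- as_tibble(samples)
  need <- c("sample_id", "sex", "regime", "line_id")
  if (!all(need %in% names(samples))) {
    abort(sprintf("`samples` needs columns: %s.", paste(need, collapse = ", ")))
  }
  check_sex(samples$sex)
  check_regime(samples$regime)
  if (anyDuplicated(samples[, c("sex", "regime", "line_id")])) {
    abort("Exactly one sample per (sex, regime, line) is required.")
  }
  if (!is.null(values)) {
    if (!is.matrix(values) || is.null(rownames(values)) || is.null(colnames(values))) {
      abort("`values` must be a matrix with gene rownames and sample colnames.")
    }
    if (!setequal(colnames(values), samples$sample_id)) {
      abort("Matrix columns and sample sheet disagree.")
    }
    values <- values[, samples$sample_id, drop = FALSE]
  }
  if (!is.null(counts)) {
    if (!is.matrix(counts) || any(counts < 0)) {
      abort("`counts` must be a non-negative matrix.")
    }
    if (!setequal(colnames(counts), samples$sample_id)) {
      abort("Count columns and sample sheet disagree.")
    }
    counts <- counts[, samples$sample_id, drop = FALSE]
  }
  if (!is.null(lib_sizes) && any(lib_sizes <= 0)) {
    abort("Library sizes must be > 0.")
  }
  structure(
    list(values = values, samples = samples, counts = counts,
         lib_sizes = lib_sizes),
    class = "expression_data"
  )
}

#' @export
print.expression_data <- function(x, ...) {
  ng <- if (!is.null(x$values)) nrow(x$values) else nrow(x$counts)
  cat(sprintf("<expression_data> %d genes x %d samples (%s)\n",
              ng, nrow(x$samples),
              if (is.null(x$values)) "counts only" else "normalized"))
  invisible(x)
}
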