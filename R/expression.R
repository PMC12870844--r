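# Between-replicate expression divergence: per-gene mean absolute deviation
# from the regime mean across replicate lines, the SSS/WSS divergence ratio,
# bootstrap-median set summaries with BCa intervals, KS/MW set-versus-
# background tests, and the best-hit ortholog filter that defines the
# reproductive-protein sets from homology-search output.

#' Counts per million
#'
#' @param counts Non-negative gene x sample matrix of raw counts.
#' @param lib_sizes Positive library sizes, one per column (defaults to the
#'   column sums).
#' @return Matrix of `count / library size * 1e6`.
#' @examples
#' cpm(matrix(c(2, 50), 1, 2), c(1e6, 2.5e7))
#' @export
cpm <- function(counts, lib_sizes = colSums(counts)) {
  if (any(lib_sizes <= 0)) abort("Library sizes must be > 0.")
  if (length(lib_sizes) != ncol(counts)) {
    abort("One library size per sample column is required.")
  }
  sweep(counts, 2L, lib_sizes, "/") * 1e6
}

#' Expressed-transcript filter
#'
#' A gene counts as expressed when its cpm is strictly greater than the
#' threshold in every in-scope sample.
#'
#' @param cpm_matrix Gene x sample cpm matrix with dimnames.
#' @param samples_in_scope Sample ids defining the comparison scope.
#' @param threshold Positive cpm cutoff (default 2; strict `>`).
#' @return Character vector of retained gene ids.
#' @export
filter_expressed <- function(cpm_matrix, samples_in_scope,
                             threshold = 2) {
  if (length(samples_in_scope) == 0L) abort("The sample scope is empty.")
  if (threshold <= 0) abort("`threshold` must be > 0.")
  missing <- setdiff(samples_in_scope, colnames(cpm_matrix))
  if (length(missing) > 0L) {
    abort(sprintf("Unknown sample(s) in scope: %s.",
                  paste(missing, collapse = ", ")))
  }
  sub <- cpm_matrix[, samples_in_scope, drop = FALSE]
  rownames(cpm_matrix)[rowSums(sub > threshold) == ncol(sub)]
}

#' Populate the normalized expression values of an expression_data object
#'
#' `log_cpm` computes `log2(cpm + 0.5)` from the raw counts; `precomputed`
#' passes already-normalized values through unchanged (the plug-in point
#' for an external variance-stabilizing transformation).
#'
#' @param ed An [expression_data()] object.
#' @param mode `"log_cpm"` or `"precomputed"`.
#' @return The object with `$values` populated.
#' @export
normalize_expression <- function(ed, mode = c("log_cpm", "precomputed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ed, "expression_data"))
  if (mode == "precomputed") {
    if (is.null(ed$values)) {
      abort("`precomputed` mode requires values to be present already.")
    }
    return(ed)
  }
  if (is.null(ed$counts)) abort("`log_cpm` mode requires raw counts.")
  lib <- ed$lib_sizes %||% colSums(ed$counts)
  ed$values <- log2(cpm(ed$counts, lib) + 0.5)
  ed
}

#' Between-replicate divergence of one gene within one regime
#'
#' The mean absolute deviation of the replicate-line expression values
#' around their regime mean.
#'
#' @param values Numeric vector of per-line values (>= 2 replicates).
#' @return Non-negative scalar divergence.
#' @examples
#' replicate_divergence(c(1, 2, 3, 4))
#' @export
replicate_divergence <- function(values) {
  if (length(values) < 2L) abort("Need >= 2 replicate values.")
  mean(abs(values - mean(values)))
}

#' Divergence ratio of strong- over weak-selection regimes
#'
#' @param d_sss,d_wss Non-negative divergences.
#' @return `d_sss / d_wss`, or `NA` (flagged undefined) when `d_wss` is 0;
#'   a ratio of 1 means equally divergent evolution under both regimes.
#' @export
divergence_ratio <- function(d_sss, d_wss) {
  if (any(c(d_sss, d_wss) < 0)) abort("Divergences must be >= 0.")
  ifelse(d_wss > 0, d_sss / d_wss, NA_real_)
}

#' Per-gene divergence table for one sex
#'
#' Computes, for every gene, the between-replicate divergence within each
#' regime over that sex's replicate-line samples, and their SSS/WSS ratio.
#'
#' @param ed A normalized [expression_data()] object.
#' @param sex `"male"` or `"female"`.
#' @param genes Optional gene ids to restrict to (default: all rows).
#' @return Tibble: `gene_id`, `d_WSS`, `d_SSS`, `ratio` (`NA` when
#'   `d_WSS = 0`).
#' @export
divergence_table <- function(ed, sex, genes = NULL) {
  stopifnot(inherits(ed, "expression_data"))
  if (is.null(ed$values)) abort("Normalize the expression data first.")
  check_sex(sex)
  cols <- lapply(REGIMES, function(rg) {
    ids <- ed$samples %>%
      filter(.data$sex == !!sex, .data$regime == rg) %>%
      pull("sample_id")
    if (length(ids) < 2L) {
      abort(sprintf("Need >= 2 replicate samples for %s/%s.", sex, rg))
    }
    ids
  })
  names(cols) <- REGIMES
  m <- ed$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing) > 0L) {
      abort(sprintf("Unknown gene id(s): %s.",
                    paste(head(missing, 3L), collapse = ", ")))
    }
    m <- m[genes, , drop = FALSE]
  }
  mad_rows <- function(sub) {
    rowMeans(abs(sub - rowMeans(sub)))
  }
  d_wss <- mad_rows(m[, cols$WSS, drop = FALSE])
  d_sss <- mad_rows(m[, cols$SSS, drop = FALSE])
  tibble(
    gene_id = rownames(m), d_WSS = unname(d_wss), d_SSS = unname(d_sss),
    ratio = divergence_ratio(unname(d_sss), unname(d_wss))
  )
}

#' Gene-set versus transcriptome-background distribution tests
#'
#' Two-sample Kolmogorov-Smirnov test of the divergence-ratio distributions
#' and a one-sided Mann-Whitney U test of the prediction that the gene set
#' is stochastically greater than the background. Both raw results are
#' always returned; `mw_gated` reports the MW p only when the KS test
#' rejects at `alpha`, mirroring the gated testing scheme.
#'
#' @param set_ratios,background_ratios Nonempty numeric vectors.
#' @param alpha Gate level for reporting the MW test (default 0.05).
#' @return One-row tibble: `n_set`, `n_background`, `ks_D`, `ks_p`,
#'   `mw_p_one_sided`, `mw_gated`.
#' @export
set_vs_background_tests <- function(set_ratios, background_ratios,
                                    alpha = 0.05) {
  set_ratios <- set_ratios[is.finite(set_ratios)]
  background_ratios <- background_ratios[is.finite(background_ratios)]
  if (length(set_ratios) == 0L || length(background_ratios) == 0L) {
    abort("Both the set and the background must be nonempty.")
  }
  ks <- suppressWarnings(ks.test(set_ratios, background_ratios))
  mw <- suppressWarnings(wilcox.test(set_ratios, background_ratios,
                                     alternative = "greater"))
  tibble(
    n_set = length(set_ratios), n_background = length(background_ratios),
    ks_D = unname(ks$statistic), ks_p = ks$p.value,
    mw_p_one_sided = mw$p.value,
    mw_gated = ifelse(ks$p.value < alpha, mw$p.value, NA_real_)
  )
}

#' Best-hit ortholog filter for tabular homology output
#'
#' Drops hits below the identity threshold (`>=` retains), then keeps, per
#' query, the single hit with the lowest e-value; ties are broken by the
#' higher bit score, then by subject id, so the assignment is
#' deterministic. Different queries may map to the same subject.
#'
#' @param hits Tibble from [read_blast_tabular()].
#' @param min_identity Percent identity threshold (default 90).
#' @return Tibble `query_id`, `subject_id`, `percent_identity`, `evalue`,
#'   `bitscore` with one row per retained query.
#' @export
ortholog_best_hit_filter <- function(hits, min_identity = 90) {
  hits <- as_tibble(hits)
  hits %>%
    filter(.data$percent_identity >= min_identity) %>%
    arrange(.data$query_id, .data$evalue, dplyr::desc(.data$bitscore),
            .data$subject_id) %>%
    group_by(.data$query_id) %>%
    slice(1L) %>%
    ungroup() %>%
    select("query_id", "subject_id", "percent_identity", "evalue", "bitscore")
}

#' Full expression-divergence analysis
#'
#' For each sex: applies the expressed-transcript cpm filter (when raw
#' counts are available), computes per-gene divergences and ratios over the
#' regime's replicate lines, summarises each designated gene set and the
#' transcriptome background by the mean bootstrap median of the ratio with
#' a BCa interval, and tests each set against the background by KS and
#' (gated) one-sided MW tests. Genes with zero weak-regime divergence have
#' an undefined ratio; they are excluded from summaries and counted.
#'
#' @param ed An [expression_data()] object (normalized, or counts plus
#'   `config$normalization = "log_cpm"`).
#' @param gene_sets Named list of gene-id vectors; the sex each set is
#'   evaluated in is given by `set_sex` (sets are compared against the full
#'   background of their own sex).
#' @param config A [run_config()].
#' @param set_sex Named character: which sex each set belongs to (default:
#'   `"SFP"` sets male, everything else female).
#' @param exclude_set_from_background Drop set members from the background
#'   before testing (default FALSE: the background is the full
#'   transcriptome of that sex).
#' @return Object of class `"divergence_fit"`; [tidy()] returns the
#'   per-gene table, [glance()] the per-set summary.
#' @examples
#' ed <- simulate_expression(synthetic_truth(), n_genes = 500,
#'                           geneset_spec = c(SFP = 20, FRP = 20), seed = 1)
#' fit <- expression_divergence(ed, ed$gene_sets,
#'                              run_config(seed = 1, n_bootstrap = 200))
#' glance(fit)
#' @export
expression_divergence <- function(ed, gene_sets = list(),
                                  config = run_config(),
                                  set_sex = NULL,
                                  exclude_set_from_background = FALSE) {
  stopifnot(inherits(ed, "expression_data"))
  if (is.null(ed$values)) {
    ed <- normalize_expression(ed, mode = config$normalization)
  }
  if (is.null(set_sex)) {
    set_sex <- setNames(
      ifelse(grepl("SFP", names(gene_sets), ignore.case = TRUE),
             "male", "female"),
      names(gene_sets)
    )
  }
  boot_seed <- substream_seed(config$seed, "expression_bootstrap")
  per_sex <- list()
  for (sx in SEXES) {
    expressed <- if (!is.null(ed$counts)) {
      scope <- ed$samples %>% filter(.data$sex == sx) %>% pull("sample_id")
      filter_expressed(cpm(ed$counts, ed$lib_sizes %||% colSums(ed$counts)),
                       scope, config$cpm_threshold)
    } else {
      rownames(ed$values)
    }
    per_sex[[sx]] <- divergence_table(ed, sx, genes = expressed)
  }
  summarise_set <- function(name, sex, ratios) {
    ratios_def <- ratios[is.finite(ratios)]
    bs <- bootstrap_median_summary(
      ratios_def, n_boot = config$n_bootstrap, alpha = config$alpha,
      seed = substream_seed(boot_seed, name)
    )
    tibble(
      set = name, sex = sex, n_genes = length(ratios),
      n_undefined = sum(!is.finite(ratios)),
      observed_median = bs$observed_median,
      boot_mean_median = bs$boot_mean_median,
      ci_lower = bs$ci_lower, ci_upper = bs$ci_upper
    )
  }
  set_rows <- list()
  test_rows <- list()
  for (sx in SEXES) {
    bg_name <- sprintf("all_%s", sx)
    set_rows[[bg_name]] <- summarise_set(bg_name, sx, per_sex[[sx]]$ratio)
  }
  for (nm in names(gene_sets)) {
    sx <- set_sex[[nm]]
    tab <- per_sex[[sx]]
    members <- tab %>% filter(.data$gene_id %in% gene_sets[[nm]])
    if (nrow(members) == 0L) {
      warn(sprintf("No expressed genes for set %s in %s samples.", nm, sx))
      next
    }
    bg <- if (exclude_set_from_background) {
      tab %>% filter(!.data$gene_id %in% gene_sets[[nm]])
    } else {
      tab
    }
    set_rows[[nm]] <- summarise_set(nm, sx, members$ratio)
    test_rows[[nm]] <- set_vs_background_tests(
      members$ratio, bg$ratio, alpha = config$alpha
    ) %>% mutate(set = nm, sex = sx, .before = 1L)
  }
  structure(
    list(
      per_gene = bind_rows(lapply(names(per_sex), function(sx) {
        per_sex[[sx]] %>% mutate(sex = sx, .before = 1L)
      })),
      per_set = bind_rows(set_rows),
      tests = bind_rows(test_rows),
      gene_sets = gene_sets, config = config
    ),
    class = "divergence_fit"
  )
}

#' @export
print.divergence_fit <- function(x, ...) {
  cat("Expression divergence-ratio analysis\n\nSet summaries:\n")
  print(as.data.frame(x$per_set), digits = 4)
  if (nrow(x$tests) > 0L) {
    cat("\nSet vs background tests:\n")
    print(as.data.frame(x$tests), digits = 4)
  }
  invisible(x)
}

#' @rdname expression_divergence
#' @param x A `divergence_fit` object.
#' @param ... Unused.
#' @export
tidy.divergence_fit <- function(x, ...) x$per_gene

#' @rdname expression_divergence
#' @export
glance.divergence_fit <- function(x, ...) x$per_set
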