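# Readers and writers for the pipeline's tabular formats. Assay and
# double-mating tables are CSV with header; expression matrices, sample
# sheets and homology hits are TSV; gene sets are one id per line.

#' Read individual mating-assay records from delimited text
#'
#' @param path CSV (or other delimited) file with header columns
#'   `individual_id`, `sex`, `line_id`, `regime`, `mating_population_id`,
#'   `matings`, `offspring`. Extra columns are ignored with a warning.
#' @param delim Field delimiter (default `","`).
#' @return A validated tibble of assay records.
#' @export
read_individual_assays <- function(path, delim = ",") {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  need <- c("individual_id", "sex", "line_id", "regime",
            "mating_population_id", "matings", "offspring")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(sprintf("Missing required column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(df), need)
  if (length(extra) > 0) {
    warn(sprintf("Ignoring unrecognized column(s): %s.",
                 paste(extra, collapse = ", ")))
  }
  df <- df[, need]
  validate_assay_records(df)
}

#' Validate a table of individual assay records
#'
#' Checks the closed sex/regime vocabularies, non-negative integer counts,
#' and the structural rule that an individual with zero matings cannot have
#' offspring.
#'
#' @param df Data frame of assay records.
#' @return The records as a tibble, invisibly validated.
#' @export
validate_assay_records <- function(df) {
  df <- as_tibble(df)
  check_sex(df$sex)
  check_regime(df$regime)
  check_nonneg_int(df$matings, "matings")
  check_nonneg_int(df$offspring, "offspring")
  bad <- which(df$matings == 0 & df$offspring > 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "Row(s) %s have offspring without any mating; impossible in these assays.",
      paste(head(bad, 5L), collapse = ", ")
    ))
  }
  df
}

#' Read double-mating (sperm-competition) records from delimited text
#'
#' @param path CSV file with header columns `female_id`, `regime`,
#'   `female_line`, `male_line`, `eggs_total`, `hatched`,
#'   `first_mating_ok`, `second_mating_ok`.
#' @param delim Field delimiter (default `","`).
#' @return A validated tibble of double-mating records.
#' @export
read_double_matings <- function(path, delim = ",") {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  need <- c("female_id", "regime", "female_line", "male_line",
            "eggs_total", "hatched", "first_mating_ok", "second_mating_ok")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(sprintf("Missing required column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(df), need)
  if (length(extra) > 0) {
    warn(sprintf("Ignoring unrecognized column(s): %s.",
                 paste(extra, collapse = ", ")))
  }
  df <- df[, need]
  validate_double_matings(df)
}

#' Validate a table of double-mating records
#'
#' @param df Data frame of double-mating records.
#' @return The records as a tibble.
#' @export
validate_double_matings <- function(df) {
  df <- as_tibble(df)
  check_regime(df$regime)
  check_nonneg_int(df$eggs_total, "eggs_total")
  check_nonneg_int(df$hatched, "hatched")
  bad <- which(df$hatched > df$eggs_total)
  if (length(bad) > 0) {
    abort(sprintf("Row(s) %s have hatched > eggs_total.",
                  paste(head(bad, 5L), collapse = ", ")))
  }
  if (!is.logical(df$first_mating_ok) || !is.logical(df$second_mating_ok)) {
    abort("Mating-success flags must be logical.")
  }
  df
}

#' Read tabular homology-search output (12-column outfmt-6 style)
#'
#' Parses whitespace/tab-delimited rows of query id, subject id, percent
#' identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, e-value and bit score, keeping the columns the
#' ortholog filter consumes.
#'
#' @param path Path to the tabular hit file (no header). An empty file
#'   yields an empty tibble.
#' @return Tibble with columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `evalue`, `bitscore`.
#' @export
read_blast_tabular <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble(query_id = character(), subject_id = character(),
                  percent_identity = numeric(), alignment_length = integer(),
                  evalue = numeric(), bitscore = numeric()))
  }
  fields <- strsplit(lines, "[ \t]+")
  n_fields <- lengths(fields)
  bad <- which(n_fields != 12L)
  if (length(bad) > 0) {
    abort(sprintf("Row %d has %d fields; expected 12.", bad[1L],
                  n_fields[bad[1L]]))
  }
  m <- do.call(rbind, fields)
  out <- tibble(
    query_id = m[, 1L], subject_id = m[, 2L],
    percent_identity = as.numeric(m[, 3L]),
    alignment_length = as.integer(m[, 4L]),
    evalue = as.numeric(m[, 11L]), bitscore = as.numeric(m[, 12L])
  )
  if (any(is.na(out$percent_identity)) || any(out$percent_identity < 0) ||
      any(out$percent_identity > 100)) {
    abort("Percent identity must parse to [0, 100].")
  }
  if (any(is.na(out$evalue)) || any(out$evalue < 0)) {
    abort("E-values must parse to non-negative reals.")
  }
  if (any(is.na(out$alignment_length)) || any(out$alignment_length < 1)) {
    abort("Alignment lengths must be positive integers.")
  }
  out
}

#' Read an expression matrix and its sample sheet
#'
#' @param matrix_path TSV; first column gene id, remaining columns one per
#'   sample.
#' @param samples_path TSV sample sheet with columns `sample_id`, `sex`,
#'   `regime`, `line_id`.
#' @param what `"values"` if the matrix holds normalized expression,
#'   `"counts"` if it holds raw counts (library sizes are then the column
#'   sums unless supplied later).
#' @return An [expression_data()] object.
#' @export
read_expression <- function(matrix_path, samples_path,
                            what = c("values", "counts")) {
  what <- match.arg(what)
  for (p in c(matrix_path, samples_path)) {
    if (!file.exists(p)) abort(sprintf("File not found: %s", p))
  }
  mat_df <- readr::read_tsv(matrix_path, show_col_types = FALSE, progress = FALSE)
  genes <- as.character(mat_df[[1L]])
  m <- as.matrix(mat_df[, -1L, drop = FALSE])
  rownames(m) <- genes
  samples <- readr::read_tsv(samples_path, show_col_types = FALSE,
                             progress = FALSE)
  if (what == "values") {
    expression_data(values = m, samples = samples)
  } else {
    expression_data(values = NULL, samples = samples, counts = m,
                    lib_sizes = colSums(m))
  }
}

#' Read a gene set (one gene id per line)
#'
#' @param path Plain-text file, one id per line; blank lines ignored.
#' @return Character vector of gene ids.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  ids <- readr::read_lines(path, progress = FALSE)
  ids[nzchar(trimws(ids))]
}

#' Write a simulated dataset to a directory in the pipeline's file formats
#'
#' Emits `assays.csv`, `double_matings.csv`, `expression.tsv`,
#' `samples.tsv`, one `geneset_<name>.txt` per designated set, and a
#' flat `truth.tsv` ground-truth record, all re-readable by the package's
#' readers.
#'
#' @param dir Output directory (created if needed).
#' @param truth A [synthetic_truth()] object.
#' @param seed Integer top-level seed.
#' @param n_genes Genes in the expression matrix.
#' @param geneset_spec Named set sizes for [simulate_expression()].
#' @return Invisibly, a named list of the written paths.
#' @export
write_synthetic_dataset <- function(dir, truth = synthetic_truth(), seed = 1L,
                                    n_genes = 2000L,
                                    geneset_spec = c(SFP = 50L, FRP = 96L)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  assays <- simulate_mating_assays(truth, seed = seed)
  dm <- simulate_double_matings(truth, seed = seed)
  ed <- simulate_expression(truth, n_genes = n_genes,
                            geneset_spec = geneset_spec, seed = seed)
  paths <- list(
    assays = file.path(dir, "assays.csv"),
    double_matings = file.path(dir, "double_matings.csv"),
    expression = file.path(dir, "expression.tsv"),
    samples = file.path(dir, "samples.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  readr::write_csv(assays, paths$assays)
  readr::write_csv(dm, paths$double_matings)
  readr::write_tsv(
    tibble(gene_id = rownames(ed$values)) %>%
      dplyr::bind_cols(as_tibble(ed$values)),
    paths$expression
  )
  readr::write_tsv(ed$samples, paths$samples)
  for (nm in names(ed$gene_sets)) {
    p <- file.path(dir, sprintf("geneset_%s.txt", nm))
    readr::write_lines(ed$gene_sets[[nm]], p)
    paths[[paste0("geneset_", nm)]] <- p
  }
  scalars <- tibble(
    key = c(sprintf("bateman_slope_%s", REGIMES),
            sprintf("mating_rate_%s", REGIMES),
            sprintf("interaction_sd_%s", REGIMES),
            sprintf("baseline_p2_%s", REGIMES),
            "line_effect_sd", "overdispersion_rho"),
    value = c(truth$bateman_slope_by_regime, truth$mating_rate_by_regime,
              truth$interaction_sd_by_regime, truth$baseline_p2_by_regime,
              truth$line_effect_sd, truth$overdispersion_rho)
  )
  sds <- truth$replicate_sd_by_regime_and_geneset %>%
    mutate(key = paste0("replicate_sd_", .data$gene_set, "_", .data$regime)) %>%
    select("key", value = "sd")
  readr::write_tsv(dplyr::bind_rows(scalars, sds), paths$truth)
  invisible(paths)
}
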