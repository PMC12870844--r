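#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' Computes the BCa confidence interval for a statistic from its observed
#' value, a vector of bootstrap replicates, and jackknife leave-one-out
#' values of the same statistic. The bias correction z0 is the normal
#' quantile of the proportion of bootstrap statistics below the observed
#' value; the acceleration is the standard jackknife skewness term
#' a = sum((mean(j) - j)^3) / (6 * (sum((mean(j) - j)^2))^(3/2)).
#'
#' Degenerate inputs are handled conservatively: if the bootstrap
#' distribution or the jackknife values are constant, the interval collapses
#' to percentile limits (or to the constant itself).
#'
#' @param t0 Observed statistic.
#' @param t_boot Numeric vector of bootstrap replicate statistics.
#' @param t_jack Numeric vector of jackknife leave-one-out statistics.
#' @param alpha Total tail mass; the interval is `(alpha/2, 1 - alpha/2)`.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' set.seed(1)
#' x <- rnorm(20)
#' tb <- replicate(999, median(sample(x, replace = TRUE)))
#' tj <- vapply(seq_along(x), function(i) median(x[-i]), numeric(1))
#' bca_interval(median(x), tb, tj)
#' @export
bca_interval <- function(t0, t_boot, t_jack, alpha = 0.05) {
  stopifnot(is.numeric(t0), length(t0) == 1L, length(t_boot) >= 2L,
            length(t_jack) >= 2L, alpha > 0, alpha < 1)
  t_boot <- t_boot[is.finite(t_boot)]
  if (length(t_boot) < 2L || diff(range(t_boot)) == 0) {
    v <- if (length(t_boot) > 0) t_boot[1L] else t0
    return(c(lower = v, upper = v))
  }
  prop_below <- mean(t_boot < t0)
  # clamp: all-below/all-above would give infinite z0
  prop_below <- min(max(prop_below, 1 / (2 * length(t_boot))),
                    1 - 1 / (2 * length(t_boot)))
  z0 <- qnorm(prop_below)
  d <- mean(t_jack) - t_jack
  denom <- sum(d^2)^1.5
  a <- if (denom > 0) sum(d^3) / (6 * denom) else 0
  zlo <- qnorm(alpha / 2)
  zhi <- qnorm(1 - alpha / 2)
  adj <- function(z) pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  probs <- c(adj(zlo), adj(zhi))
  qs <- quantile(t_boot, probs = probs, names = FALSE, type = 6)
  c(lower = qs[1L], upper = qs[2L])
}

# Leave-one-out medians without refitting: after sorting, removing a value
# on one side of the median always yields the same order statistic, so only
# two (n even) or three (n odd) distinct values occur.
jackknife_medians <- function(x) {
  n <- length(x)
  ord <- order(x)
  s <- x[ord]
  out <- numeric(n)
  if (n %% 2L == 0L) {
    k <- n %/% 2L
    vals <- c(rep(s[k + 1L], k), rep(s[k], n - k))
  } else {
    m <- (n + 1L) %/% 2L
    vals <- c(rep((s[m] + s[m + 1L]) / 2, m - 1L),
              (s[m - 1L] + s[m + 1L]) / 2,
              rep((s[m - 1L] + s[m]) / 2, n - m))
  }
  out[ord] <- vals
  out
}

#' Bootstrap-median summary of a set of divergence ratios
#'
#' Resamples the values with replacement `n_boot` times, records the median
#' of each resample, and reports the mean of those bootstrap medians along
#' with the BCa interval for the median (jackknife acceleration over the
#' values themselves).
#'
#' @param values Numeric vector (>= 3 values).
#' @param n_boot Bootstrap replicates (>= 100).
#' @param alpha CI tail mass (default 0.05).
#' @param seed Integer seed for the resampling stream.
#' @return A one-row tibble: `n`, `observed_median`, `boot_mean_median`,
#'   `ci_lower`, `ci_upper`.
#' @examples
#' bootstrap_median_summary(c(0.9, 1.0, 1.1, 1.4, 0.8, 1.2), n_boot = 200, seed = 1)
#' @export
bootstrap_median_summary <- function(values, n_boot = 9999L, alpha = 0.05,
                                     seed = 1L) {
  values <- values[is.finite(values)]
  if (length(values) < 3L) abort("Need >= 3 finite values for a bootstrap summary.")
  if (n_boot < 100L) abort("`n_boot` must be >= 100.")
  t0 <- median(values)
  n <- length(values)
  t_boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot),
           function(i) median(values[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  t_jack <- jackknife_medians(values)
  ci <- bca_interval(t0, t_boot, t_jack, alpha = alpha)
  tibble(
    n = n, observed_median = t0, boot_mean_median = mean(t_boot),
    ci_lower = ci[["lower"]], ci_upper = ci[["upper"]]
  )
}
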