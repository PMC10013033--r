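#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum test used for all between-group contrasts (channel
#' fluctuation, edge correlation, criticality metrics, MMN amplitude).
#' For untied samples with both group sizes below 50 the exact null
#' distribution of the rank sum is used (this covers, and is stricter than,
#' exactness for total n <= 12); otherwise the normal approximation with tie
#' and continuity correction is applied.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param alternative one of `"two.sided"`, `"greater"`, `"less"`;
#'   `"greater"` tests a location shift of `x` above `y`.
#' @return an object of class `dnm_test`: list with `statistic` (the
#'   Mann-Whitney U for `x`), `p_value`, `alternative`, `method`.
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4, 5), alternative = "less")$p_value # 0.1
#' @export
rank_sum_test <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L)
    stop_invalid("rank_sum_test: both samples must be non-empty")
  if (anyNA(x) || anyNA(y))
    stop_invalid("rank_sum_test: NA values are not allowed")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    warning("rank_sum_test: all observations tied; p = 1")
    return(new_dnm_test(length(x) * length(y) / 2, 1, alternative,
                        "Wilcoxon rank-sum (degenerate: all tied)"))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, correct = TRUE)
  )
  p <- wt$p.value
  if (is.na(p)) p <- 1
  new_dnm_test(unname(wt$statistic), min(max(p, .Machine$double.xmin), 1),
               alternative, "Wilcoxon rank-sum")
}

#' Paired t-test
#'
#' Standard paired t with n - 1 degrees of freedom. Differences with zero
#' variance are rejected (the t statistic is undefined there).
#'
#' @inheritParams rank_sum_test
#' @return a `dnm_test` object with the t statistic.
#' @export
paired_t_test <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y) || length(x) < 2L)
    stop_invalid("paired_t_test: x and y must have equal length >= 2")
  d <- x - y
  if (stats::var(d) == 0)
    stop_invalid("paired_t_test: differences have zero variance")
  tt <- stats::t.test(x, y, paired = TRUE, alternative = alternative)
  new_dnm_test(unname(tt$statistic),
               min(max(tt$p.value, .Machine$double.xmin), 1),
               alternative, "paired t")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone in rank order and capped at 1.
#'
#' @param p numeric vector of raw p-values, all in (0, 1].
#' @return adjusted p-values in the input order.
#' @examples
#' fdr_adjust(c(0.002, 0.01, 0.03, 0.04)) # 0.008 0.020 0.040 0.040
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p <= 0) || any(p > 1))
    stop_invalid("fdr_adjust: p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

new_dnm_test <- function(statistic, p_value, alternative, method) {
  structure(list(statistic = statistic, p_value = p_value,
                 alternative = alternative, method = method),
            class = "dnm_test")
}

#' @export
print.dnm_test <- function(x, ...) {
  cat(sprintf("%s test (%s): statistic = %.4g, p = %.4g\n",
              x$method, x$alternative, x$statistic, x$p_value))
  invisible(x)
}
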