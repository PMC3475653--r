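#' Correlate SIF scores with a quantitative phenotype
#'
#' Ordinary least squares of phenotype on score.  `r2` is the squared
#' Pearson correlation; the p-value comes from the exact two-tailed t test
#' on \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} (appropriate at the very small n
#' of mutant panels).  With `log_log = TRUE` both variables are
#' log-transformed first (all values must then be positive).  An optional
#' `weights` vector (for example inverse phenotype variances) switches to
#' weighted least squares for the fit coefficients; `r2`/`p` always refer
#' to the unweighted Pearson correlation, which is what is reported and
#' compared across conditions.
#'
#' @param scores numeric vector of SIF scores.
#' @param phenotypes numeric vector of matched phenotype values.
#' @param log_log correlate on the log-log scale.
#' @param weights optional non-negative weights for the fitted line.
#' @return list with `r2`, `p_two_tailed`, `n`, `intercept`, `slope`.
#' @export
correlate <- function(scores, phenotypes, log_log = FALSE, weights = NULL) {
  stopifnot(length(scores) == length(phenotypes))
  keep <- stats::complete.cases(scores, phenotypes)
  x <- scores[keep]; y <- phenotypes[keep]
  if (length(x) < 3L) stop("need at least 3 matched pairs (got ", length(x), ")")
  if (log_log) {
    if (any(x <= 0) || any(y <= 0)) stop("log-log correlation requires positive values")
    x <- log(x); y <- log(y)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in scores or phenotypes")
  }
  n <- length(x)
  r <- stats::cor(x, y)
  r2 <- r^2
  tstat <- r * sqrt(n - 2) / sqrt(max(1 - r2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  fit <- if (is.null(weights)) stats::lm(y ~ x) else stats::lm(y ~ x, weights = weights[keep])
  list(
    r2 = r2, p_two_tailed = p, n = n,
    intercept = unname(stats::coef(fit)[1L]),
    slope = unname(stats::coef(fit)[2L])
  )
}

#' Filter a score/phenotype table to one impact class
#'
#' @param table data.frame with an `impact_class` column.
#' @param class `"F"` or `"S"`.
#' @return the matching rows, input order preserved.
#' @export
stratify <- function(table, class) {
  if (!class %in% c("F", "S")) stop("unknown impact class '", class, "' (use 'F' or 'S')")
  if (!"impact_class" %in% names(table)) stop("`table` needs an 'impact_class' column")
  out <- table[table$impact_class == class, , drop = FALSE]
  if (nrow(out) == 0L) stop("empty stratum for class '", class, "'")
  out
}
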