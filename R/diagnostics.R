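#' Genomic inflation factor
#'
#' Converts p-values to 1-df chi-square quantiles and divides their median
#' by the null median 0.4549 (`qchisq(0.5, 1)`). A calibrated scan gives
#' lambda near 1; systematically inflated statistics give lambda above 1.
#'
#' @param pvalues Vector of p-values in (0, 1\].
#' @return Lambda (positive scalar; 0 when every p = 1).
#' @export
genomic_lambda <- function(pvalues) {
  p <- pvalues[!is.na(pvalues)]
  stopifnot(all(p > 0 & p <= 1))
  if (length(p) < 100L)
    warning("lambda computed from fewer than 100 tests; interpret with care")
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}

#' Main-effect misspecification guard for known-locus scans
#'
#' Interaction tests with additively coded main effects inherit residual
#' main effects when a locus's true effect is not log-additive; the residual
#' leaks into every interaction test at that locus and inflates lambda.
#' Guard rule: if lambda over a locus's genome-wide interaction p-values
#' exceeds `threshold` (default 1.05), the locus should be rerun with 2-df
#' unrestricted main-effect coding (`model = "ardi_umain"`); otherwise the
#' additive-main ARDI results stand. The threshold is strict: lambda equal
#' to 1.05 keeps the additive coding.
#'
#' @param pvalues Interaction p-values of one locus's scan.
#' @param threshold Inflation threshold.
#' @param locus_id Optional label carried into the report.
#' @return List of class `inflation_report`: `lambda`, `n_tests`,
#'   `locus_id`, `coding_used` (`"additive"` or `"unrestricted_main"`),
#'   `rerun` flag.
#' @export
inflation_guard <- function(pvalues, threshold = 1.05, locus_id = NA) {
  lam <- genomic_lambda(pvalues)
  rerun <- lam > threshold
  structure(list(lambda = lam, n_tests = sum(!is.na(pvalues)),
                 locus_id = locus_id,
                 coding_used = if (rerun) "unrestricted_main" else "additive",
                 rerun = rerun, threshold = threshold),
            class = "inflation_report")
}

#' @export
print.inflation_report <- function(x, ...) {
  cat(sprintf("inflation report%s: lambda = %.3f over %d tests -> %s\n",
              if (!is.na(x$locus_id)) paste0(" (", x$locus_id, ")") else "",
              x$lambda, x$n_tests,
              if (x$rerun) "rerun with unrestricted main-effect coding"
              else "additive main-effect coding retained"))
  invisible(x)
}

#' Quantile-quantile data for p-values
#'
#' Observed p-values sorted ascending against uniform expected quantiles
#' `(i - 0.5)/n`, both on the -log10 scale.
#'
#' @param pvalues Vector of p-values in (0, 1\].
#' @return Data frame with `expected` and `observed` columns.
#' @export
qq_data <- function(pvalues) {
  p <- sort(pvalues[!is.na(pvalues)])
  n <- length(p)
  data.frame(expected = -log10((seq_len(n) - 0.5) / n),
             observed = -log10(p))
}

#' QQ plot of interaction p-values
#'
#' @param pvalues Vector of p-values.
#' @param main Plot title.
#' @return The [qq_data()] frame, invisibly.
#' @export
qq_plot <- function(pvalues, main = "QQ plot") {
  d <- qq_data(pvalues)
  graphics::plot(d$expected, d$observed, pch = 20,
                 xlab = expression(Expected ~ -log[10](p)),
                 ylab = expression(Observed ~ -log[10](p)), main = main)
  graphics::abline(0, 1, col = "grey50")
  invisible(d)
}
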