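#' Permutation test result container
#'
#' Houses an observed statistic, its null replicate values and the empirical
#' p-value computed as \eqn{p = (r + 1) / (n + 1)}, where \eqn{r} is the
#' number of null replicates at least as extreme as the observed value in
#' the tested direction. This estimator never returns 0; when no replicate
#' reaches the observed value the result is reported (and printed) as
#' \eqn{p < 1/(n+1)}.
#'
#' @param observed Observed statistic.
#' @param null_values Numeric vector of null replicate statistics.
#' @param direction `"greater"`, `"less"` or `"two-sided"` (two-sided counts
#'   replicates whose distance from the null mean is at least the observed
#'   distance).
#' @param seed Integer seed used for the randomization, for the record.
#' @param statistic Short label of the statistic.
#' @return Object of class `perm_result` with fields `observed`,
#'   `null_values`, `n_replicates`, `r_extreme`, `p_empirical`, `direction`,
#'   `at_floor` (TRUE when r = 0), `seed`, `statistic`.
#' @export
perm_result <- function(observed, null_values, direction = c("greater",
                        "less", "two-sided"), seed = NA_integer_,
                        statistic = "statistic") {
  direction <- match.arg(direction)
  null_values <- as.numeric(null_values)
  n <- length(null_values)
  if (n < 1L) stop("at least one null replicate is required")
  r <- switch(direction,
    greater = sum(null_values >= observed),
    less = sum(null_values <= observed),
    "two-sided" = {
      ctr <- mean(null_values)
      sum(abs(null_values - ctr) >= abs(observed - ctr))
    })
  structure(list(observed = observed, null_values = null_values,
                 n_replicates = n, r_extreme = r,
                 p_empirical = (r + 1) / (n + 1), direction = direction,
                 at_floor = (r == 0L), seed = seed, statistic = statistic),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  p_str <- if (x$at_floor) sprintf("< %.4g", 1 / (x$n_replicates + 1))
           else sprintf("= %.4g", x$p_empirical)
  cat(sprintf("Permutation test (%s, %s)\n", x$statistic, x$direction))
  cat(sprintf("  observed %.6g; null mean %.6g (sd %.3g, n = %d)\n",
              x$observed, mean(x$null_values), stats::sd(x$null_values),
              x$n_replicates))
  cat(sprintf("  empirical P %s\n", p_str))
  invisible(x)
}

#' Format an empirical p-value for reports
#' @param x A `perm_result`.
#' @return Character scalar, e.g. `"0.007"` or `"<0.001"`.
#' @export
format_p <- function(x) {
  if (x$at_floor) sprintf("<%.3g", 1 / (x$n_replicates + 1))
  else sprintf("%.3g", x$p_empirical)
}
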