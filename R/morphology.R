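# Morphometric distribution fitting: fibril/nanocomplex width samples.

#' Normal-distribution fit of a dimension sample
#'
#' Fits a normal distribution to measured widths (or lengths): the sample
#' mean and the n-1 (unbiased) standard deviation, reported as mean +/- sd
#' as in width-histogram summaries.
#'
#' @param values measurements (nm), all > 0, n >= 10.
#' @param stage optional stage label (e.g. "seed", "1h", "48h").
#' @param min_n minimum sample size (10 for width samples).
#' @return An object of class `normal_fit`: list with `mean`, `sd`, `n`,
#'   `stage`.
#' @examples
#' fit_normal(gen_normal_sample(34, 9, 160, seed = 7))
#' @export
fit_normal <- function(values, stage = NULL, min_n = 10L) {
  values <- as.numeric(values)
  if (length(values) < min_n)
    stop_input(sprintf("need at least %d values", min_n))
  if (any(!is.finite(values))) stop_input("non-finite values")
  structure(list(mean = mean(values), sd = stats::sd(values),
                 n = length(values), stage = stage),
            class = "normal_fit")
}

#' @export
print.normal_fit <- function(x, ...) {
  cat(sprintf("<normal_fit> %.4g +/- %.4g (n = %d%s)\n", x$mean, x$sd, x$n,
              if (!is.null(x$stage)) paste0(", ", x$stage) else ""))
  invisible(x)
}

#' Welch comparison of two stage distributions
#'
#' Welch two-sample t-comparison of means computed from summary statistics
#' (mean, sd, n) of two fitted stages, e.g. seed widths vs 1-h nanocomplex
#' widths. Supporting statistic only; degenerate zero-variance inputs
#' return p = 1 when the means agree and p = 0 otherwise.
#'
#' @param a,b `normal_fit` objects with n >= 10.
#' @return List with `delta_mean` (`mean(b) - mean(a)`), `welch_t`, `df`,
#'   `p`.
#' @export
compare_stages <- function(a, b) {
  stopifnot(inherits(a, "normal_fit"), inherits(b, "normal_fit"))
  if (a$n < 10 || b$n < 10) stop_input("both fits need n >= 10")
  delta <- b$mean - a$mean
  va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
  se2 <- va + vb
  if (se2 == 0) {
    return(list(delta_mean = delta, welch_t = if (delta == 0) 0 else Inf,
                df = Inf, p = if (delta == 0) 1 else 0))
  }
  t <- delta / sqrt(se2)
  df <- se2^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  list(delta_mean = delta, welch_t = t, df = df,
       p = 2 * stats::pt(-abs(t), df))
}
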