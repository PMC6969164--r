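#' Kinetic model parameters
#'
#' Parameter bundle for the two kinetic models used to describe templated
#' assembly: the empirical logistic curve
#' \deqn{y(t) = 1 / (1 + \exp(-k (t - t_{0.5})))}
#' with growth rate `k` (1/h) and midpoint `t_half` (h), and the
#' Johnson-Mehl-Avrami-Kolmogorov (JMAK) phase-transformation curve
#' \deqn{y(t) = 1 - \exp(-(K t)^n)}
#' with rate constant `K` and integer growth dimensionality `n`.
#'
#' @param model `"logistic"` or `"avrami"`.
#' @param k logistic growth rate, > 0 (1/h).
#' @param t_half logistic midpoint time (h), the time at 50% assembly.
#' @param K Avrami rate constant, > 0 (1/h).
#' @param n Avrami exponent (growth dimensionality), integer >= 1.
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params("logistic", k = 1, t_half = 10)
#' kinetic_params("avrami", K = 0.1, n = 2)
#' @export
kinetic_params <- function(model = c("logistic", "avrami"),
                           k = NULL, t_half = NULL, K = NULL, n = NULL) {
  model <- match.arg(model)
  if (model == "logistic") {
    if (is.null(k) || is.null(t_half))
      stop_input("logistic model needs k and t_half")
    if (k <= 0) stop_input("k must be > 0")
    out <- list(model = model, k = k, t_half = t_half)
  } else {
    if (is.null(K) || is.null(n))
      stop_input("avrami model needs K and n")
    if (K <= 0) stop_input("K must be > 0")
    if (n < 1 || n != round(n)) stop_input("n must be an integer >= 1")
    out <- list(model = model, K = K, n = as.integer(n))
  }
  structure(out, class = "kinetic_params")
}

#' Evaluate a kinetic model curve
#'
#' @param params a [kinetic_params()].
#' @param times numeric times (h).
#' @return Fraction completion at each time.
#' @export
kinetic_curve <- function(params, times) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$model == "logistic") {
    1 / (1 + exp(-params$k * (times - params$t_half)))
  } else {
    1 - exp(-(params$K * times)^params$n)
  }
}

#' Fraction-completion kinetic trace
#'
#' `(time, fraction)` pairs for one assembly experiment. Fractions are kept
#' raw (noise may push them slightly outside [0, 1]); clamping before fitting
#' would bias the kinetic estimates near the plateaus.
#'
#' @param times strictly increasing times (h).
#' @param fractions fraction completion per time point.
#' @param label experiment identifier.
#' @param seed_conc optional seed concentration (weight percent of peptide).
#' @param monomer_conc optional silk fibroin concentration (mg/ml).
#' @return An object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(times, fractions, label = "",
                          seed_conc = NULL, monomer_conc = NULL) {
  times <- as.numeric(times)
  fractions <- as.numeric(fractions)
  if (length(times) != length(fractions))
    stop_input("times and fractions must have equal length")
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop_input("times must be finite and strictly increasing")
  structure(list(times = times, fractions = fractions, label = label,
                 seed_conc = seed_conc, monomer_conc = monomer_conc),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("<kinetic_trace> %d points, t = %g..%g h%s\n",
              length(x$times), min(x$times), max(x$times),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Write / read a kinetic trace as commented-header CSV
#'
#' Two columns `time_h,fraction` with `# label=` and optional
#' `# seed_conc_pct=` header comments.
#'
#' @param x a [kinetic_trace()].
#' @param path file path.
#' @export
write_trace_csv <- function(x, path) {
  stopifnot(inherits(x, "kinetic_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# label=%s", x$label), con)
  if (!is.null(x$seed_conc))
    writeLines(sprintf("# seed_conc_pct=%.12g", x$seed_conc), con)
  writeLines("time_h,fraction", con)
  writeLines(sprintf("%.12g,%.12g", x$times, x$fractions), con)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path)
  lab <- sub("^# label=", "", grep("^# label=", lines, value = TRUE)[1])
  sc <- grep("^# seed_conc_pct=", lines, value = TRUE)
  sc <- if (length(sc)) as.numeric(sub("^# seed_conc_pct=", "", sc[1])) else NULL
  body <- utils::read.csv(text = lines[!grepl("^#", lines)])
  kinetic_trace(body$time_h, body$fraction,
                label = if (is.na(lab)) "" else lab, seed_conc = sc)
}
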