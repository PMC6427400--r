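# Statistical species characterization: descriptive measures, boxplot-fence
# outlier removal, physiological octave-error gating, Shapiro-Wilk normality
# gating and Student-t confidence intervals, combined into a per-species
# profile of normal models for the frequency features.

#' Descriptive measures of a sample
#'
#' Mean, sample standard error and standard deviation (n-1 denominator),
#' bias-corrected excess kurtosis and skewness (zero for a normal
#' distribution), range, minimum, maximum and n.
#'
#' @param sample numeric vector, n >= 2.
#' @return a one-row data.frame with columns `mean`, `std_error`, `std_dev`,
#'   `kurtosis`, `skewness`, `range`, `min`, `max`, `n`.
#' @export
describe_sample <- function(sample) {
  sample <- sample[!is.na(sample)]
  n <- length(sample)
  if (n < 2L) stop("need at least 2 values")
  s <- stats::sd(sample)
  data.frame(
    mean = mean(sample), std_error = s / sqrt(n), std_dev = s,
    kurtosis = if (n >= 4L) e1071::kurtosis(sample, type = 2L) else NA_real_,
    skewness = if (n >= 3L) e1071::skewness(sample, type = 2L) else NA_real_,
    range = diff(range(sample)), min = min(sample), max = max(sample), n = n
  )
}

#' Boxplot-fence outlier removal
#'
#' Values strictly outside the boxplot fences Q1 - 1.5 IQR and
#' Q3 + 1.5 IQR are treated as outliers and removed; quartiles use linear
#' interpolation between order statistics. Applied once (no iteration).
#'
#' @param sample numeric vector, n >= 4.
#' @return list with `kept`, `removed`, `fences` (c(lower, upper)).
#' @export
boxplot_outliers <- function(sample) {
  sample <- sample[!is.na(sample)]
  if (length(sample) < 4L) stop("need at least 4 values")
  q <- stats::quantile(sample, c(0.25, 0.75), names = FALSE, type = 7L)
  iqr <- q[2L] - q[1L]
  fences <- c(q[1L] - 1.5 * iqr, q[2L] + 1.5 * iqr)
  out <- sample < fences[1L] | sample > fences[2L]
  list(kept = sample[!out], removed = sample[out], fences = fences)
}

#' Physiological validity (octave-error) gate
#'
#' Removes measurements outside a physiologically plausible band for the
#' species. Values beyond the gates are octave errors of the extractor --
#' FFT peaks landing on the 2nd component (about twice the true fundamental)
#' or autocorrelation picking half the true frequency -- not biological
#' variation, so they are excluded before the distribution is modeled.
#'
#' @param sample numeric vector.
#' @param gates c(low, high) in the feature's units; use -Inf/Inf for an
#'   open side.
#' @return list with `kept` and `removed`.
#' @export
octave_gate <- function(sample, gates) {
  if (gates[1L] >= gates[2L]) stop("need gates[1] < gates[2]")
  sample <- sample[!is.na(sample)]
  out <- sample < gates[1L] | sample > gates[2L]
  list(kept = sample[!out], removed = sample[out])
}

#' Shapiro-Wilk normality gate
#'
#' Wraps the Shapiro-Wilk test (Royston's approximation); the gate passes
#' when p > 0.05.
#'
#' @param sample numeric vector, 3 <= n <= 5000, not constant.
#' @return list with `W`, `p_value`, `normal` (p > 0.05).
#' @export
shapiro_gate <- function(sample) {
  sample <- sample[!is.na(sample)]
  n <- length(sample)
  if (n < 3L || n > 5000L) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (diff(range(sample)) == 0) stop("Shapiro-Wilk undefined for constant sample")
  sw <- stats::shapiro.test(sample)
  list(W = unname(sw$statistic), p_value = sw$p.value,
       normal = sw$p.value > 0.05)
}

#' Student-t confidence interval for a population mean
#'
#' Half width = t_{(1+conf)/2, n-1} * sd / sqrt(n); the interval is
#' mean +/- half width.
#'
#' @param mean sample mean.
#' @param sd sample standard deviation.
#' @param n sample size (>= 2).
#' @param confidence confidence level in (0, 1), default 0.95.
#' @return a `normal_model`: list with `mu`, `sigma`, `n`, `ci_half_width`,
#'   `confidence`.
#' @export
t_confidence_interval <- function(mean, sd, n, confidence = 0.95) {
  if (n < 2L) stop("need n >= 2")
  if (confidence <= 0 || confidence >= 1) stop("confidence must be in (0, 1)")
  half <- stats::qt((1 + confidence) / 2, df = n - 1L) * sd / sqrt(n)
  normal_model(mean, sd, n, half, confidence)
}

#' A per-feature normal model
#' @param mu mean. @param sigma standard deviation. @param n sample size.
#' @param ci_half_width CI half width. @param confidence confidence level.
#' @return a `normal_model` list.
#' @export
normal_model <- function(mu, sigma, n, ci_half_width = NA_real_,
                         confidence = 0.95) {
  structure(list(mu = mu, sigma = sigma, n = as.integer(n),
                 ci_half_width = ci_half_width, confidence = confidence),
            class = "normal_model")
}

#' @export
print.normal_model <- function(x, ...) {
  cat(sprintf("Normal(mu = %.2f, sigma = %.2f), n = %d, %.0f%% CI +/- %.2f\n",
              x$mu, x$sigma, x$n, 100 * x$confidence, x$ci_half_width))
  invisible(x)
}

#' Default octave-error gates per species
#'
#' For *A. fraterculus* the FFT-derived features are gated above 200 Hz
#' (peaks above 200 Hz are 2nd-component mislocations, not the fundamental);
#' for *C. capitata* the FFT-derived features are gated to (70, 280) Hz.
#' The autocorrelation feature is left ungated.
#'
#' @param species `"fraterculus"` or `"capitata"`.
#' @return named list of c(low, high) per feature.
#' @export
default_gates <- function(species = c("fraterculus", "capitata")) {
  species <- match.arg(species)
  fft_gate <- switch(species,
    fraterculus = c(-Inf, 200),
    capitata = c(70, 280))
  list(f0_aut = c(-Inf, Inf), f0_fft = fft_gate, f1_minus_f0 = fft_gate)
}

#' Build a species profile from per-event features
#'
#' For each modeled feature (default `f0_aut`, `f0_fft`, `f1_minus_f0`):
#' octave-error gating, boxplot-fence outlier removal, Shapiro-Wilk
#' normality gate (failure produces a warning flag, not an abort), then
#' descriptive measures and the Student-t confidence interval. Provenance
#' counts (events in, gated, outliers removed) are recorded per feature.
#'
#' @param features data.frame from [event_features()].
#' @param species species label.
#' @param gates named list of c(low, high) per feature; default
#'   [default_gates()] when `species` names a known species, otherwise
#'   ungated.
#' @param feature_names features to model.
#' @param min_events minimum number of events required (default 10).
#' @param confidence confidence level for the t interval.
#' @return a `species_profile`: list with `species`, `models` (named list of
#'   `normal_model`), `measures` (data.frame of descriptive measures),
#'   `shapiro` (per-feature W/p/normal), `gates`, `counts`.
#' @export
build_profile <- function(features, species,
                          gates = NULL,
                          feature_names = c("f0_aut", "f0_fft", "f1_minus_f0"),
                          min_events = 10L, confidence = 0.95) {
  if (nrow(features) < min_events)
    stop("need at least ", min_events, " standard-group events; got ",
         nrow(features))
  if (is.null(gates)) {
    gates <- if (species %in% c("fraterculus", "capitata"))
      default_gates(species)
    else stats::setNames(rep(list(c(-Inf, Inf)), length(feature_names)),
                         feature_names)
  }
  models <- list(); measures <- NULL; shapiro <- list(); counts <- list()
  for (fn in feature_names) {
    x <- features[[fn]]
    x <- x[!is.na(x)]
    if (length(x) < 4L) next  # feature absent or too sparse: skip, keep others
    g <- gates[[fn]] %||% c(-Inf, Inf)
    gated <- octave_gate(x, g)
    bx <- boxplot_outliers(gated$kept)
    sw <- tryCatch(shapiro_gate(bx$kept), error = function(e) NULL)
    if (!is.null(sw) && !sw$normal)
      warning("feature '", fn, "' fails Shapiro-Wilk (p = ",
              signif(sw$p_value, 3), "); normal model fitted anyway")
    d <- describe_sample(bx$kept)
    d$feature <- fn
    measures <- rbind(measures, d)
    models[[fn]] <- t_confidence_interval(d$mean, d$std_dev, d$n, confidence)
    shapiro[[fn]] <- sw
    counts[[fn]] <- list(events_in = length(x), gated = length(gated$removed),
                         outliers = length(bx$removed), used = d$n)
  }
  if (length(models) == 0L) stop("no feature with enough valid measurements")
  structure(list(species = species, models = models, measures = measures,
                 shapiro = shapiro, gates = gates, counts = counts),
            class = "species_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.species_profile <- function(x, ...) {
  cat("species_profile:", x$species, "\n")
  for (fn in names(x$models)) {
    m <- x$models[[fn]]
    cat(sprintf("  %-12s mu = %7.2f  sd = %5.2f  n = %3d  CI +/- %.2f\n",
                fn, m$mu, m$sigma, m$n, m$ci_half_width))
  }
  invisible(x)
}
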