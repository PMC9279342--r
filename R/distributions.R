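# DistributionSummary: pooled per-frame samples of an observable (SASA, Rg)
# reduced to mean / median / sd / histogram.

#' Summarize pooled per-frame samples of an observable
#'
#' @param samples numeric vector, one value per analyzed frame (pooled over
#'   replicates)
#' @param observable short name, e.g. `"SASA V520"` or `"core Rg"`
#' @param nbins number of histogram bins (equal width over the sample range)
#' @param breaks optional explicit histogram break points overriding `nbins`
#' @return object of class `DistributionSummary` with fields `observable`,
#'   `samples`, `mean`, `median`, `sd`, `n` and `histogram` (list of
#'   `breaks`, `counts`); histogram counts always sum to `n`
#' @export
summarize_distribution <- function(samples, observable = "", nbins = 30L,
                                   breaks = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("no samples to summarize")
  if (!all(is.finite(samples))) stop("non-finite samples")
  if (is.null(breaks)) {
    lo <- min(samples)
    hi <- max(samples)
    if (hi - lo < .Machine$double.eps * max(1, abs(hi))) {
      lo <- lo - 0.5
      hi <- hi + 0.5
    }
    breaks <- seq(lo, hi, length.out = nbins + 1L)
  }
  h <- graphics::hist(samples, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  structure(list(observable = observable,
                 samples = samples,
                 mean = mean(samples),
                 median = stats::median(samples),
                 sd = stats::sd(samples),
                 n = length(samples),
                 histogram = list(breaks = h$breaks, counts = h$counts)),
            class = "DistributionSummary")
}

#' @export
print.DistributionSummary <- function(x, ...) {
  cat(sprintf("%s: n = %d, mean = %.4g, median = %.4g, sd = %.4g\n",
              x$observable, x$n, x$mean, x$median, x$sd))
  invisible(x)
}
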