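# Two-channel array intensity simulation.
#
# A marker's samples live in (theta, intensity) space: theta in [0, 1] is the
# normalized angle between the two allele channels (0 = pure A signal,
# 1 = pure B), intensity the combined signal strength. Real markers fall into
# four recurrent patterns: three compact clusters near 0/0.5/1 (type 1), the
# same with a fraction of low-intensity failures (type 2), three clusters
# with the extreme clusters shifted towards the middle, indicative of a
# duplicated locus (type 3), and five clusters from two simultaneously
# scored loci (type 4, never genotype-called).

PATTERN_TYPES <- c("TYPE1", "TYPE2", "TYPE3", "TYPE4")

#' Construct an intensity set
#'
#' @param theta numeric vector in \[0, 1\].
#' @param intensity non-negative numeric vector of the same length.
#' @param labels optional integer cluster labels (truth, for simulations).
#' @return An object of class `intensity_set` (a data.frame).
#' @export
intensity_set <- function(theta, intensity, labels = NULL) {
  stopifnot(length(theta) == length(intensity))
  if (any(theta < 0 | theta > 1)) stop("theta must lie in [0, 1]", call. = FALSE)
  if (any(intensity < 0)) stop("intensity must be non-negative", call. = FALSE)
  out <- data.frame(theta = theta, intensity = intensity)
  if (!is.null(labels)) out$label <- labels
  class(out) <- c("intensity_set", "data.frame")
  out
}

#' Default cluster geometry for each simulated pattern type
#'
#' @param pattern one of `"TYPE1"`..`"TYPE4"`.
#' @param shift theta shift of the extreme clusters for TYPE3.
#' @param sd_theta within-cluster theta spread.
#' @param low_frac fraction of low-intensity (failed) points for TYPE2.
#' @return List of simulation parameters.
#' @export
intensity_params <- function(pattern, shift = 0.2, sd_theta = 0.03,
                             low_frac = 0.08) {
  pattern <- match.arg(pattern, PATTERN_TYPES)
  switch(pattern,
    TYPE1 = list(means = c(0.02, 0.5, 0.98), weights = c(0.35, 0.3, 0.35),
                 sd_theta = sd_theta, low_frac = 0),
    TYPE2 = list(means = c(0.02, 0.5, 0.98), weights = c(0.35, 0.3, 0.35),
                 sd_theta = sd_theta, low_frac = low_frac),
    TYPE3 = list(means = c(0 + shift, 0.5, 1 - shift * 1.4),
                 weights = c(0.35, 0.3, 0.35), sd_theta = sd_theta,
                 low_frac = 0),
    TYPE4 = list(means = c(0.02, 0.26, 0.5, 0.74, 0.98),
                 weights = rep(0.2, 5), sd_theta = sd_theta, low_frac = 0)
  )
}

#' Simulate per-marker two-channel intensity clusters
#'
#' Draws `n_samples` (theta, intensity) points from the cluster geometry of
#' the requested pattern type. Good points have log-normal intensity around
#' 1; the low-intensity fraction of TYPE2 sits around 0.1, below the default
#' calling floor, with theta smeared uniformly.
#'
#' @param pattern one of `"TYPE1"`..`"TYPE4"`.
#' @param n_samples number of samples (>= 10).
#' @param params list as returned by [intensity_params()]; defaults to the
#'   pattern's standard geometry.
#' @param seed RNG seed.
#' @return An [intensity_set()] with true cluster labels (`0` marks
#'   low-intensity failed points).
#' @export
simulate_intensities <- function(pattern, n_samples = 274, params = NULL,
                                 seed = 1) {
  pattern <- match.arg(pattern, PATTERN_TYPES)
  if (n_samples < 10) stop("need at least 10 samples", call. = FALSE)
  if (is.null(params)) params <- intensity_params(pattern)
  with_seed(seed, {
    n_low <- stats::rbinom(1, n_samples, params$low_frac)
    n_good <- n_samples - n_low
    lab <- sample(rep(seq_along(params$means),
                      length.out = max(n_good, length(params$means))))[seq_len(n_good)]
    # guarantee every cluster is populated, then fill multinomially
    extra <- n_good - length(params$means)
    if (extra >= 0) {
      lab <- c(seq_along(params$means),
               sample(seq_along(params$means), extra, replace = TRUE,
                      prob = params$weights))
    }
    # truncated normal on [0, 1]: no point masses at the boundaries
    mu <- params$means[lab]
    if (params$sd_theta > 0) {
      lo <- stats::pnorm((0 - mu) / params$sd_theta)
      hi <- stats::pnorm((1 - mu) / params$sd_theta)
      theta <- mu + params$sd_theta *
        stats::qnorm(lo + stats::runif(n_good) * (hi - lo))
    } else {
      theta <- mu
    }
    inten <- stats::rlnorm(n_good, meanlog = 0, sdlog = 0.2)
    if (n_low > 0) {
      theta <- c(theta, stats::runif(n_low))
      inten <- c(inten, stats::rlnorm(n_low, meanlog = log(0.1), sdlog = 0.25))
      lab <- c(lab, rep(0L, n_low))
    }
    intensity_set(pmin(pmax(theta, 0), 1), inten, labels = lab)
  })
}
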