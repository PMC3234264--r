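# Intensity-cluster pattern classification and genotype calling.

# Deterministic 1-D Gaussian mixture EM. Initialization by evenly spaced
# quantiles keeps the fit reproducible without random restarts, which is
# adequate for well-separated genotype clusters at a few hundred samples.
.fit_gmm1d <- function(x, k, max_iter = 300, tol = 1e-8) {
  n <- length(x)
  mu <- as.numeric(stats::quantile(x, probs = (seq_len(k) - 0.5) / k,
                                   names = FALSE, type = 8))
  sd0 <- max(stats::sd(x) / k, 1e-3)
  sigma <- rep(sd0, k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j)
      w[j] * stats::dnorm(x, mu[j], sigma[j]), numeric(n))
    dens <- matrix(dens, nrow = n)
    rs <- rowSums(dens)
    rs[rs < 1e-300] <- 1e-300
    ll <- sum(log(rs))
    gamma <- dens / rs
    nk <- colSums(gamma)
    nk[nk < 1e-8] <- 1e-8
    w <- nk / n
    mu <- colSums(gamma * x) / nk
    sigma <- sqrt(colSums(gamma * (x - rep(mu, each = n))^2) / nk)
    sigma <- pmax(sigma, 5e-4)  # variance floor against collapse
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  ord <- order(mu)
  list(means = mu[ord], sds = sigma[ord], weights = w[ord],
       loglik = ll, k = k,
       bic = -2 * ll + (3 * k - 1) * log(n))
}

# Merge mixture components whose means are closer than `min_sep`
# (moment-matched, weight-proportional), repeatedly for the closest pair.
.merge_close <- function(means, sds, w, min_sep) {
  while (length(means) > 1 && min(diff(means)) < min_sep) {
    j <- which.min(diff(means))
    wj <- w[j] + w[j + 1]
    mu <- (w[j] * means[j] + w[j + 1] * means[j + 1]) / wj
    v <- (w[j] * (sds[j]^2 + means[j]^2) +
            w[j + 1] * (sds[j + 1]^2 + means[j + 1]^2)) / wj - mu^2
    means <- c(means[seq_len(j - 1)], mu, means[-seq_len(j + 1)])
    sds <- c(sds[seq_len(j - 1)], sqrt(max(v, 1e-8)), sds[-seq_len(j + 1)])
    w <- c(w[seq_len(j - 1)], wj, w[-seq_len(j + 1)])
  }
  list(means = means, sds = sds, weights = w)
}

#' Construct a cluster model for genotype calling
#'
#' @param means ascending theta means of the components.
#' @param sds component theta standard deviations.
#' @param weights component weights summing to 1.
#' @param intensity_floor points below this intensity are never called.
#' @param pattern optional pattern type the model was derived from.
#' @return An object of class `cluster_model`.
#' @export
cluster_model <- function(means, sds, weights = rep(1 / length(means), length(means)),
                          intensity_floor = 0.3, pattern = NA_character_) {
  stopifnot(length(means) == length(sds), length(means) == length(weights))
  if (is.unsorted(means)) stop("component means must be ascending", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-6) stop("weights must sum to 1", call. = FALSE)
  structure(list(means = means, sds = sds, weights = weights,
                 intensity_floor = intensity_floor, pattern = pattern),
            class = "cluster_model")
}

#' Classify the intensity-cluster pattern of a marker
#'
#' Fits 1-D Gaussian mixtures with 1 to 6 components to the theta values of
#' points above the intensity floor, selects the component count by BIC, and
#' maps the selected model to a pattern type: 3 components with extreme means
#' near 0 and 1 give TYPE1 (or TYPE2 when the below-floor fraction exceeds
#' `type2_frac`); 3 components with shifted extremes give TYPE3; 5 components
#' give TYPE4. Anything else — including TYPE3 geometries whose adjacent
#' components are closer than `min_separation` (clusters too close and
#' shifted to score) — is reported as `UNSCORABLE`.
#'
#' @param points an [intensity_set()] with >= 30 points.
#' @param intensity_floor calling floor (default 0.3).
#' @param shift_tol extreme-component means must lie within this distance of
#'   0 and 1 for TYPE1/TYPE2 (default 0.12).
#' @param type2_frac below-floor fraction separating TYPE1 from TYPE2
#'   (default 0.02).
#' @param min_separation minimum adjacent-component separation for a
#'   scorable 3-cluster marker (default 0.08).
#' @return List with `pattern` (`"TYPE1"`..`"TYPE4"` or `"UNSCORABLE"`),
#'   `model` (a [cluster_model()]), `k`, and `low_fraction`.
#' @export
classify_pattern <- function(points, intensity_floor = 0.3, shift_tol = 0.12,
                             type2_frac = 0.02, min_separation = 0.08) {
  stopifnot(inherits(points, "intensity_set"))
  if (nrow(points) < 30) stop("need at least 30 points", call. = FALSE)
  ok <- points$intensity >= intensity_floor
  low_frac <- mean(!ok)
  x <- points$theta[ok]
  if (length(x) < 30) stop("fewer than 30 points above the intensity floor",
                           call. = FALSE)
  if (stats::sd(x) < 1e-8) stop("degenerate theta variance", call. = FALSE)
  fits <- lapply(1:6, function(k) .fit_gmm1d(x, k))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "bic"))]]
  # Components closer than the minimum calling separation cannot act as
  # distinct genotype clusters (a skewed cluster is routinely split in two by
  # BIC); merge them before deciding the pattern.
  merged <- .merge_close(best$means, best$sds, best$weights, min_separation)
  k_eff <- length(merged$means)
  model <- cluster_model(merged$means, merged$sds, merged$weights,
                         intensity_floor = intensity_floor)
  pattern <- "UNSCORABLE"
  if (k_eff == 5) {
    pattern <- "TYPE4"
  } else if (k_eff == 3) {
    if (merged$means[1] <= shift_tol && merged$means[3] >= 1 - shift_tol) {
      pattern <- if (low_frac > type2_frac) "TYPE2" else "TYPE1"
    } else {
      pattern <- "TYPE3"
    }
  }
  model$pattern <- pattern
  list(pattern = pattern, model = model, k = k_eff, low_fraction = low_frac)
}

#' Call genotypes from a fitted cluster model
#'
#' Assigns each point to the nearest of the three genotype components
#' (ascending theta means map to `AA`, `AB`, `BB`; TYPE3 models are thereby
#' shift-corrected, since assignment uses the fitted — shifted — means, not
#' the nominal 0/0.5/1 anchors). Points below the intensity floor, or farther
#' than `z_max` component standard deviations from every mean (the space
#' between calling regions), are set to `FAILED`. Five-component (TYPE4)
#' models cannot be called.
#'
#' @param model a [cluster_model()] with exactly 3 components.
#' @param points an [intensity_set()].
#' @param z_max half-width of each calling region in component SDs.
#' @return Character vector of calls (`AA`/`AB`/`BB`/`FAILED`).
#' @export
call_genotypes <- function(model, points, z_max = 3.5) {
  stopifnot(inherits(model, "cluster_model"), inherits(points, "intensity_set"))
  if (length(model$means) == 5 || identical(model$pattern, "TYPE4")) {
    stop("TYPE4 (five-cluster) markers cannot be genotype-called",
         call. = FALSE)
  }
  if (length(model$means) != 3) {
    stop("genotype calling requires a 3-component model", call. = FALSE)
  }
  sds <- pmax(model$sds, 1e-6)
  z <- vapply(1:3, function(j) abs(points$theta - model$means[j]) / sds[j],
              numeric(nrow(points)))
  z <- matrix(z, ncol = 3)
  comp <- max.col(-z, ties.method = "first")
  calls <- c("AA", "AB", "BB")[comp]
  zmin <- z[cbind(seq_len(nrow(z)), comp)]
  calls[zmin > z_max | points$intensity < model$intensity_floor] <- "FAILED"
  calls
}
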