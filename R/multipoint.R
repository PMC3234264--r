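# Multipoint distance estimation along a fixed marker order.
#
# Along an ordered chromosome, the parental origin of a fixed inbred line is
# a two-state Markov chain: the probability of switching origin between
# adjacent markers k and k+1 is the line-level recombinant fraction R_k of
# that interval. Observed homozygous calls pin the state; missing and
# heterozygous calls are marginalized by a forward-backward pass. Interval
# R_k values are maximized by EM and converted to centiMorgan through the
# intermating-aware map function (and to pseudo-cM with t = 0).

#' Multipoint interval distances by EM
#'
#' @param calls markers x lines (or markers x samples) call matrix restricted
#'   to the ordered markers of one chromosome, rows in map order.
#' @param t intermating generations used for the cM correction.
#' @param tol EM convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_iter maximum EM iterations.
#' @return List with `R` (per-interval line-level recombinant fractions),
#'   `loglik` (natural-log likelihood), `d_cM` and `d_pseudo_cM` (interval
#'   lengths), `pos_cM` and `pos_pseudo_cM` (cumulative positions starting at
#'   0), and `n_iter`.
#' @export
multipoint_distances <- function(calls, t, tol = 1e-6, max_iter = 200) {
  m <- nrow(calls)
  if (m < 2) stop("need at least two ordered markers", call. = FALSE)
  x <- .origin_code(calls)           # lines x markers
  n <- nrow(x)
  # emission indicators: can the line be in state 1 (parent-1) / state 2?
  e1 <- x >= 0L   # observed +1 or missing
  e2 <- x <= 0L
  storage.mode(e1) <- "double"; storage.mode(e2) <- "double"
  # init from adjacent two-point fractions
  R <- vapply(seq_len(m - 1), function(k) {
    joint <- x[, k] != 0 & x[, k + 1] != 0
    if (sum(joint) == 0) return(0.1)
    min(max(mean(x[joint, k] != x[joint, k + 1]), 1e-4), 0.45)
  }, numeric(1))
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    # forward
    a1 <- 0.5 * e1[, 1]; a2 <- 0.5 * e2[, 1]
    sc <- a1 + a2
    if (any(sc == 0)) stop("non-finite likelihood: impossible observation",
                           call. = FALSE)
    a1 <- a1 / sc; a2 <- a2 / sc
    loglik <- sum(log(sc))
    A1 <- matrix(0, n, m); A2 <- matrix(0, n, m)
    A1[, 1] <- a1; A2[, 1] <- a2
    for (k in seq_len(m - 1)) {
      r <- R[k]
      b1 <- (a1 * (1 - r) + a2 * r) * e1[, k + 1]
      b2 <- (a1 * r + a2 * (1 - r)) * e2[, k + 1]
      sc <- b1 + b2
      if (any(sc == 0)) stop("non-finite likelihood: impossible observation",
                             call. = FALSE)
      loglik <- loglik + sum(log(sc))
      a1 <- b1 / sc; a2 <- b2 / sc
      A1[, k + 1] <- a1; A2[, k + 1] <- a2
    }
    # backward, accumulating expected interval switches
    b1 <- rep(1, n); b2 <- rep(1, n)
    xi <- numeric(m - 1)
    for (k in (m - 1):1) {
      r <- R[k]
      f1 <- e1[, k + 1] * b1
      f2 <- e2[, k + 1] * b2
      num_sw <- A1[, k] * r * f2 + A2[, k] * r * f1
      den <- A1[, k] * ((1 - r) * f1 + r * f2) +
             A2[, k] * (r * f1 + (1 - r) * f2)
      xi[k] <- sum(num_sw / den)
      nb1 <- (1 - r) * f1 + r * f2
      nb2 <- r * f1 + (1 - r) * f2
      scb <- nb1 + nb2
      b1 <- nb1 / scb; b2 <- nb2 / scb
    }
    R <- pmin(pmax(xi / n, 1e-6), 0.4999)
    if (!is.finite(loglik)) stop("non-finite likelihood", call. = FALSE)
    if (abs(loglik - ll_old) < tol) break
    ll_old <- loglik
  }
  r_meiotic <- iril_r_inverse(R, t)
  r_pseudo <- iril_r_inverse(R, 0)
  d <- haldane_d(r_meiotic)
  dp <- haldane_d(r_pseudo)
  list(R = R, loglik = loglik,
       d_cM = d, d_pseudo_cM = dp,
       pos_cM = c(0, cumsum(d)), pos_pseudo_cM = c(0, cumsum(dp)),
       n_iter = it)
}
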