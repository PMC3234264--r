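# Scaffold -> framework -> bin placement ordering engine.
#
# Ordering decisions use a composite chain score: the log10-likelihood of an
# order is the sum of the maximized pairwise log10-likelihoods of adjacent
# markers (pairwise-complete lines). Inserting a candidate between markers L
# and R changes the score by pl(c,L) + pl(c,R) - pl(L,R); end insertions add
# a single term. A placement score is the margin between the best and
# second-best insertion position. Final distances are re-estimated by the
# multipoint EM, which marginalizes missing data properly.

# Precompute the group context used by all ordering operations.
.group_ctx <- function(calls, t) {
  tp <- twopoint_matrix(calls)
  rcap <- pmin(tp$R, 0.49)
  d <- haldane_d(iril_r_inverse(rcap, t))
  d[is.na(d)] <- Inf
  list(ids = rownames(calls), pl = tp$pl, R = tp$R, n = tp$n, lod = tp$lod,
       d = d, inf = diag(tp$n), t = t)
}

# Insertion score deltas: candidates x (k + 1) positions for `order`.
.insertion_deltas <- function(ctx, cand, ord) {
  k <- length(ord)
  plc <- ctx$pl[cand, ord, drop = FALSE]
  out <- matrix(NA_real_, length(cand), k + 1)
  out[, 1] <- plc[, 1]
  out[, k + 1] <- plc[, k]
  if (k > 1) {
    plo <- ctx$pl[cbind(ord[-k], ord[-1])]
    for (j in seq_len(k - 1)) {
      out[, j + 1] <- plc[, j] + plc[, j + 1] - plo[j]
    }
  }
  out
}

.top2 <- function(v) {
  o <- order(v, decreasing = TRUE)
  c(best = v[o[1]], second = if (length(v) > 1) v[o[2]] else -Inf,
    pos = o[1] - 1)  # pos = number of markers to the left
}

.chain_score <- function(ctx, ord) {
  if (length(ord) < 2) return(0)
  sum(ctx$pl[cbind(ord[-length(ord)], ord[-1])])
}

# Sliding window-3 permutation improvement of an order (2-opt style).
.optimize_order <- function(ctx, ord, max_sweeps = 10) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  k <- length(ord)
  if (k < 3) return(ord)
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (w in seq_len(k - 2)) {
      idx <- w:(w + 2)
      left <- if (w > 1) ord[w - 1] else NA
      right <- if (w + 3 <= k) ord[w + 3] else NA
      local <- function(trip) {
        s <- ctx$pl[trip[1], trip[2]] + ctx$pl[trip[2], trip[3]]
        if (!is.na(left)) s <- s + ctx$pl[left, trip[1]]
        if (!is.na(right)) s <- s + ctx$pl[trip[3], right]
        s
      }
      cur <- local(ord[idx])
      scores <- vapply(perms, function(p) local(ord[idx][p]), numeric(1))
      b <- which.max(scores)
      if (scores[b] > cur + 1e-10) {
        ord[idx] <- ord[idx][perms[[b]]]
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  ord
}

# Minimum margin (log10) of the current order over window-3 permutations
# covering position `at`.
.window_margin <- function(ctx, ord, at) {
  perms <- list(c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  k <- length(ord)
  if (k < 3) return(Inf)
  margin <- Inf
  for (w in max(1, at - 2):min(k - 2, at)) {
    idx <- w:(w + 2)
    left <- if (w > 1) ord[w - 1] else NA
    right <- if (w + 3 <= k) ord[w + 3] else NA
    local <- function(trip) {
      s <- ctx$pl[trip[1], trip[2]] + ctx$pl[trip[2], trip[3]]
      if (!is.na(left)) s <- s + ctx$pl[left, trip[1]]
      if (!is.na(right)) s <- s + ctx$pl[trip[3], right]
      s
    }
    cur <- local(ord[idx])
    best_alt <- max(vapply(perms, function(p) local(ord[idx][p]), numeric(1)))
    margin <- min(margin, cur - best_alt)
  }
  margin
}

#' Build a scaffold map for one linkage group
#'
#' Starting from a seed marker, candidates are accreted greedily: a marker is
#' admitted when its best insertion position beats the second-best by at
#' least `score_threshold` (log10) and it keeps all adjacent scaffold
#' spacings at or above `min_spacing_cM`; after each insertion the order is
#' re-optimized locally. Replicate scaffolds are grown from `n_replicates`
#' different seeds (most-informative markers spread across the group) and
#' reconciled by dropping markers whose relative order is not supported by
#' every replicate.
#'
#' @param calls markers x samples call matrix of one linkage group
#'   (parent-origin coded, framework-stage filtered).
#' @param t intermating generations.
#' @param min_spacing_cM minimum scaffold spacing (default 10 cM).
#' @param score_threshold log10 placement-score threshold (default 3).
#' @param n_replicates number of seed replicates (default 10).
#' @return List with `order` (consensus marker ids), `replicates`, `seeds`.
#' @export
build_scaffold <- function(calls, t, min_spacing_cM = 10, score_threshold = 3,
                           n_replicates = 10) {
  if (nrow(calls) < 3) stop("group must contain at least 3 markers",
                            call. = FALSE)
  ctx <- .group_ctx(calls, t)
  m <- length(ctx$ids)
  n_rep <- min(n_replicates, m)
  # seeds: most informative first, then spread by maximin two-point R
  seeds <- integer(0)
  informative <- ctx$inf >= stats::median(ctx$inf)
  seeds[1] <- which.max(ctx$inf)
  while (length(seeds) < n_rep) {
    cand <- setdiff(which(informative), seeds)
    if (length(cand) == 0) cand <- setdiff(seq_len(m), seeds)
    if (length(cand) == 0) break
    dist_to <- apply(ctx$R[cand, seeds, drop = FALSE], 1,
                     function(r) min(r, na.rm = TRUE))
    dist_to[!is.finite(dist_to)] <- 0.5
    seeds <- c(seeds, cand[which.max(dist_to)])
  }
  replicates <- lapply(seeds, function(seed)
    .grow_scaffold(ctx, seed, min_spacing_cM, score_threshold))
  base <- replicates[[which.max(vapply(replicates, length, 1L))]]
  if (length(base) == 1) {
    warning("no marker passed the scaffold placement threshold; ",
            "scaffold reduced to its seed", call. = FALSE)
  }
  # consensus: drop base markers involved in any cross-replicate order conflict
  drop <- rep(FALSE, length(base))
  base_rank <- stats::setNames(seq_along(base), base)
  for (rep_ord in replicates) {
    shared <- intersect(base, rep_ord)
    if (length(shared) < 3) next
    rb <- rank(base_rank[shared])
    rr <- rank(match(shared, rep_ord))
    if (stats::cor(rb, rr, method = "kendall") < 0) rr <- rev(rr)
    for (i in seq_along(shared)) {
      for (j in seq_along(shared)) {
        if (i < j && sign(rb[i] - rb[j]) != sign(rr[i] - rr[j])) {
          drop[match(shared[c(i, j)], base)] <- TRUE
        }
      }
    }
  }
  list(order = base[!drop], replicates = replicates, seeds = ctx$ids[seeds])
}

.grow_scaffold <- function(ctx, seed, min_spacing_cM, score_threshold) {
  ord <- ctx$ids[seed]
  m <- length(ctx$ids)
  repeat {
    cand <- setdiff(seq_len(m), match(ord, ctx$ids))
    cand_ids <- ctx$ids[cand]
    if (length(cand) == 0) break
    k <- length(ord)
    if (k == 1) {
      score <- ctx$lod[cand_ids, ord]
      pos <- rep(1, length(cand))
    } else {
      deltas <- .insertion_deltas(ctx, cand_ids, ord)
      tops <- t(apply(deltas, 1, .top2))
      score <- tops[, "best"] - tops[, "second"]
      pos <- tops[, "pos"]
    }
    # spacing: distance to both would-be neighbors must be >= min_spacing
    ok_space <- vapply(seq_along(cand), function(i) {
      j <- pos[i]
      nb <- c(if (j >= 1) ord[j], if (j < k) ord[j + 1])
      all(ctx$d[cand_ids[i], nb] >= min_spacing_cM)
    }, logical(1))
    admissible <- which(score >= score_threshold & ok_space)
    if (length(admissible) == 0) break
    pick <- admissible[which.max(score[admissible])]
    j <- pos[pick]
    ord <- append(ord, cand_ids[pick], after = j)
    ord <- .optimize_order(ctx, ord)
  }
  ord
}

#' Extend a scaffold into a framework map
#'
#' Candidates (ordered by information content: fewest missing calls, then
#' highest minor-allele frequency, then id) are tentatively inserted one at a
#' time at their maximum-likelihood position. An insertion is kept only when
#' both the placement margin (best vs second-best position) and the
#' robustness margin of the post-insertion order over every permutation of
#' the 3-marker windows covering the new marker are at least
#' `robustness_threshold` log10 units.
#'
#' @param scaffold character vector of scaffold marker ids (in map order).
#' @param calls markers x samples call matrix of the linkage group
#'   (framework-stage filtered; must contain the scaffold markers).
#' @param t intermating generations.
#' @param robustness_threshold log10 margin (default 3).
#' @return List with `order` (framework marker ids) and `tier` (named vector,
#'   `"scaffold"` or `"framework"`).
#' @export
extend_framework <- function(scaffold, calls, t, robustness_threshold = 3) {
  ctx <- .group_ctx(calls, t)
  stopifnot(all(scaffold %in% ctx$ids))
  ord <- scaffold
  cand <- setdiff(ctx$ids, scaffold)
  if (length(cand)) {
    x <- .origin_code(calls[cand, , drop = FALSE])
    miss <- colSums(x == 0)
    maf <- vapply(seq_along(cand), function(i) {
      v <- x[, i]; v <- v[v != 0]
      if (length(v) == 0) 0 else min(mean(v > 0), mean(v < 0))
    }, numeric(1))
    cand <- cand[order(miss, -maf, cand)]
    for (cid in cand) {
      deltas <- .insertion_deltas(ctx, cid, ord)[1, ]
      tops <- .top2(deltas)
      if (tops["best"] - tops["second"] < robustness_threshold) next
      at <- tops[["pos"]] + 1L
      new_ord <- append(ord, cid, after = tops[["pos"]])
      if (.window_margin(ctx, new_ord, at) < robustness_threshold) next
      ord <- new_ord
    }
  }
  tier <- stats::setNames(ifelse(ord %in% scaffold, "scaffold", "framework"),
                          ord)
  list(order = ord, tier = tier)
}

#' Place additional markers onto a fixed framework (bin mapping)
#'
#' Each candidate is assigned its maximum-likelihood framework interval; the
#' placement score is the log10 margin of the best interval over the best
#' non-adjacent interval (the two intervals flanking a framework marker
#' describe the same point, so ambiguity between them does not count against
#' a placement). Candidates with fewer than 10 informative lines or a margin
#' below `threshold` stay unmapped. The point position inside the interval
#' comes from the recombinant fraction with the left flanking marker,
#' converted to cM (and pseudo-cM), clamped into the interval.
#'
#' @param framework list as returned by [extend_framework()], or a character
#'   vector of framework marker ids in map order.
#' @param framework_calls call matrix of the framework markers (rows may be
#'   in any order; looked up by id).
#' @param cand_calls call matrix of the markers to place (complete-stage
#'   filtered).
#' @param t intermating generations.
#' @param dist multipoint distances for the framework order, as returned by
#'   [multipoint_distances()]; computed when `NULL`.
#' @param threshold log10 placement-score threshold (default 3).
#' @return data.frame with columns `marker`, `placed`, `interval` (markers to
#'   the left of the assigned interval), `cM`, `pseudo_cM`, `score`.
#' @export
place_bins <- function(framework, framework_calls, cand_calls, t,
                       dist = NULL, threshold = 3) {
  ord <- if (is.list(framework)) framework$order else framework
  k <- length(ord)
  stopifnot(k >= 2, all(ord %in% rownames(framework_calls)))
  fcalls <- framework_calls[ord, , drop = FALSE]
  if (is.null(dist)) dist <- multipoint_distances(fcalls, t)
  xf <- .origin_code(fcalls)
  xc <- .origin_code(cand_calls)
  s <- crossprod(xc, xf)
  nmat <- crossprod((xc != 0) + 0, (xf != 0) + 0)
  disc <- (nmat - s) / 2
  p <- disc / nmat
  pc <- pmin(pmax(p, 1e-9), 0.5)
  plc <- disc * log10(pc) + (nmat - disc) * log10(1 - pc)
  plc[nmat == 0] <- 0
  # adjacent framework pair scores
  tpf <- twopoint_matrix(fcalls)
  plo <- tpf$pl[cbind(seq_len(k - 1), 2:k)]
  nc <- ncol(xc)
  res <- data.frame(marker = rownames(cand_calls), placed = FALSE,
                    interval = NA_integer_, cM = NA_real_,
                    pseudo_cM = NA_real_, score = NA_real_)
  for (i in seq_len(nc)) {
    deltas <- numeric(k + 1)
    deltas[1] <- plc[i, 1]
    deltas[k + 1] <- plc[i, k]
    if (k > 1) {
      for (j in seq_len(k - 1)) {
        deltas[j + 1] <- plc[i, j] + plc[i, j + 1] - plo[j]
      }
    }
    j <- which.max(deltas) - 1L
    flank <- c(if (j >= 1) j, if (j < k) j + 1)
    if (max(nmat[i, flank]) < 10) next
    # margin against the best interval not adjacent to the winner: the two
    # intervals flanking a framework marker describe the same point position,
    # so ambiguity between them is not positional ambiguity
    rival <- deltas[abs(seq_len(k + 1) - (j + 1)) > 1]
    score <- if (length(rival)) deltas[j + 1] - max(rival) else Inf
    res$interval[i] <- j
    res$score[i] <- score
    if (score < threshold) next
    res$placed[i] <- TRUE
    pos <- .bin_position(i, j, k, p, dist, t)
    res$cM[i] <- pos[1]
    res$pseudo_cM[i] <- pos[2]
  }
  res
}

# cM / pseudo-cM point position of candidate i placed j markers from the
# left end of a framework with k markers.
.bin_position <- function(i, j, k, p, dist, t) {
  to_d <- function(R, tt) haldane_d(iril_r_inverse(min(max(R, 0), 0.49), tt))
  if (j == 0) {
    d <- to_d(p[i, 1], t); dp <- to_d(p[i, 1], 0)
    return(c(max(dist$pos_cM[1] - d, 0), max(dist$pos_pseudo_cM[1] - dp, 0)))
  }
  if (j == k) {
    d <- to_d(p[i, k], t); dp <- to_d(p[i, k], 0)
    return(c(dist$pos_cM[k] + d, dist$pos_pseudo_cM[k] + dp))
  }
  len <- dist$pos_cM[j + 1] - dist$pos_cM[j]
  lenp <- dist$pos_pseudo_cM[j + 1] - dist$pos_pseudo_cM[j]
  if (is.na(p[i, j])) {  # left flank uninformative: anchor on the right
    d <- to_d(p[i, j + 1], t); dp <- to_d(p[i, j + 1], 0)
    return(c(dist$pos_cM[j + 1] - min(d, len),
             dist$pos_pseudo_cM[j + 1] - min(dp, lenp)))
  }
  da <- to_d(p[i, j], t)
  dap <- to_d(p[i, j], 0)
  c(dist$pos_cM[j] + min(da, len), dist$pos_pseudo_cM[j] + min(dap, lenp))
}
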