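# Two-point recombination estimation and linkage grouping.
#
# Genotypes are parent-origin coded: +1 = homozygous parent-1, -1 =
# homozygous parent-2, 0 = missing/heterozygous. The line-level recombinant
# fraction between two markers is the fraction of jointly informative
# (both-homozygous) lines carrying discordant parental origins.

# lines x markers integer coding of a parent-origin call matrix
.origin_code <- function(calls) {
  x <- matrix(0L, nrow(calls), ncol(calls))
  x[calls == "AA"] <- 1L
  x[calls == "BB"] <- -1L
  t(x)  # lines x markers
}

#' Two-point estimate for one marker pair
#'
#' @param g1,g2 genotype call vectors (`AA`/`AB`/`BB`/`FAILED`) of equal
#'   length, parent-origin coded.
#' @return List with `R` (line-level recombinant fraction, truncated to
#'   \[0, 0.5\]), `n` (jointly informative lines), `lod` (log10 likelihood
#'   ratio of the estimate against independence), and `reliable`
#'   (`FALSE` when `n < 10`).
#' @export
estimate_R <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("length mismatch", call. = FALSE)
  check_calls(c(g1, g2))
  a <- ifelse(g1 == "AA", 1L, ifelse(g1 == "BB", -1L, 0L))
  b <- ifelse(g2 == "AA", 1L, ifelse(g2 == "BB", -1L, 0L))
  joint <- a != 0L & b != 0L
  n <- sum(joint)
  if (n == 0) {
    return(list(R = NA_real_, n = 0L, lod = 0, reliable = FALSE))
  }
  disc <- sum(a[joint] != b[joint])
  p <- min(max(disc / n, 1e-9), 1 - 1e-9)
  lod <- disc * log10(p) + (n - disc) * log10(1 - p) - n * log10(0.5)
  list(R = min(disc / n, 0.5), n = n, lod = lod, reliable = n >= 10)
}

#' All-pairs two-point estimates for a call matrix
#'
#' Vectorized computation of the recombinant fraction, informative-line
#' count, log10 LOD against independence, and pairwise composite
#' log10-likelihood used by the ordering heuristics.
#'
#' @param calls markers x samples call matrix (parent-origin coded).
#' @return List of markers x markers matrices: `R` (truncated to 0.5), `n`,
#'   `lod`, `pl` (maximized pairwise log10-likelihood, 0 on the diagonal and
#'   for uninformative pairs).
#' @export
twopoint_matrix <- function(calls) {
  x <- .origin_code(calls)
  s <- crossprod(x)                    # concordant - discordant
  nmat <- crossprod((x != 0L) + 0)     # jointly informative lines
  disc <- (nmat - s) / 2
  p <- disc / nmat
  p[nmat == 0] <- NA_real_
  pc <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  lod <- disc * log10(pc) + (nmat - disc) * log10(1 - pc) - nmat * log10(0.5)
  lod[nmat == 0] <- 0
  # composite pair log-likelihood at the linkage-truncated MLE
  pl_p <- pmin(pmax(p, 1e-9), 0.5)
  pl <- disc * log10(pl_p) + (nmat - disc) * log10(1 - pl_p)
  pl[nmat == 0] <- 0
  rmat <- pmin(p, 0.5)
  ids <- rownames(calls)
  dimnames(rmat) <- dimnames(nmat) <- dimnames(lod) <- dimnames(pl) <-
    list(ids, ids)
  list(R = rmat, n = nmat, lod = lod, pl = pl)
}

#' Assign markers to linkage groups
#'
#' Single-linkage transitive closure of the relation
#' `lod >= lod_threshold & R <= r_threshold`. Groups are numbered by
#' decreasing size, ties by the lexicographically smallest member id.
#'
#' @param tp result of [twopoint_matrix()].
#' @param lod_threshold minimum LOD for a linkage edge (default 10; with
#'   thousands of markers and a couple hundred lines a classical LOD 3 admits
#'   spurious chromosome-joining edges).
#' @param r_threshold maximum recombinant fraction for an edge.
#' @return List with `groups` (list of marker-id vectors) and `assignment`
#'   (named integer vector marker -> group).
#' @export
group_markers <- function(tp, lod_threshold = 10, r_threshold = 0.25) {
  adj <- tp$lod >= lod_threshold & !is.na(tp$R) & tp$R <= r_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  ids <- rownames(tp$R)
  members <- split(ids, comp$membership)
  ord <- order(-vapply(members, length, 1L),
               vapply(members, function(m) min(m), character(1)))
  members <- members[ord]
  names(members) <- NULL
  assignment <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  for (k in seq_along(members)) assignment[members[[k]]] <- k
  list(groups = members, assignment = assignment)
}
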