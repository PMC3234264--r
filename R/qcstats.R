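# Marker- and sample-level quality-control statistics.

#' Per-marker failure rates
#'
#' @param matrix a [geno_matrix()].
#' @param threshold failure-rate threshold for the summary count
#'   (default 0.05, i.e. markers failing in more than 5% of samples).
#' @return List with `rates` (named per-marker failure fractions), `mean_rate`
#'   and `n_above` (markers with rate strictly above `threshold`).
#' @export
marker_failure_rates <- function(matrix, threshold = 0.05) {
  stopifnot(inherits(matrix, "geno_matrix"))
  if (nrow(matrix$calls) == 0) stop("empty genotype matrix", call. = FALSE)
  rates <- rowMeans(matrix$calls == "FAILED")
  list(rates = rates, mean_rate = mean(rates),
       n_above = sum(rates > threshold), threshold = threshold)
}

#' Mean call rates per sample group
#'
#' Call rate of a group is computed per cell: 1 minus the FAILED fraction
#' over all marker-by-sample cells of the group's samples.
#'
#' @param matrix a [geno_matrix()].
#' @param groups data.frame with columns `sample` and `group`, covering each
#'   sample of interest exactly once.
#' @return Named numeric vector of per-group call rates, descending.
#' @export
group_call_rates <- function(matrix, groups) {
  stopifnot(inherits(matrix, "geno_matrix"),
            all(c("sample", "group") %in% names(groups)))
  if (anyDuplicated(groups$sample)) {
    stop("each sample may be assigned to exactly one group", call. = FALSE)
  }
  unknown <- setdiff(groups$sample, matrix$samples)
  if (length(unknown)) {
    stop("unknown sample(s) in grouping: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  rates <- vapply(split(groups$sample, groups$group), function(ss) {
    1 - mean(matrix$calls[, ss, drop = FALSE] == "FAILED")
  }, numeric(1))
  sort(rates, decreasing = TRUE)
}

#' Pedigree consistency of a parent/parent/F1 triplet
#'
#' A marker is informative when all three calls are non-FAILED and both
#' parents are homozygous; it is inconsistent when the F1 call differs from
#' the Mendelian expectation (heterozygous for differing parents, the shared
#' homozygote otherwise).
#'
#' @param p1,p2,f1 character call vectors of equal length.
#' @return List with `n_informative`, `n_inconsistent`, `rate`.
#' @export
triplet_consistency <- function(p1, p2, f1) {
  if (length(p1) != length(p2) || length(p1) != length(f1)) {
    stop("call vectors must have equal length", call. = FALSE)
  }
  check_calls(c(p1, p2, f1))
  informative <- p1 != "FAILED" & p2 != "FAILED" & f1 != "FAILED" &
    p1 != "AB" & p2 != "AB"
  expected <- ifelse(p1 == p2, p1, "AB")
  bad <- informative & f1 != expected
  n_inf <- sum(informative)
  list(n_informative = n_inf, n_inconsistent = sum(bad),
       rate = if (n_inf > 0) sum(bad) / n_inf else NA_real_)
}

#' Discordance rate between duplicate samples
#'
#' @param v1,v2 character call vectors of equal length.
#' @return List with `n_joint` (markers called in both) and `discordance`.
#' @export
duplicate_concordance <- function(v1, v2) {
  if (length(v1) != length(v2)) {
    stop("call vectors must have equal length", call. = FALSE)
  }
  check_calls(c(v1, v2))
  joint <- v1 != "FAILED" & v2 != "FAILED"
  n <- sum(joint)
  list(n_joint = n,
       discordance = if (n > 0) mean(v1[joint] != v2[joint]) else NA_real_)
}

#' Segregation-distortion scan
#'
#' For each marker, the frequency of the parent-1 allele among non-FAILED
#' homozygous calls is tested against the Mendelian expectation of 0.5 with a
#' two-sided exact-binomial rule at the 1% level (equal 0.5% tails): a marker
#' is flagged when either mid-p tail probability falls below 0.5%. The mid-p
#' correction (half weight on the observed count) is used so the attained
#' null flag rate matches the nominal level instead of being conservative
#' under the binomial's discreteness. Markers without informative calls get
#' an undefined frequency and are never flagged.
#'
#' @param matrix a [geno_matrix()] of a biparental population in which `AA`
#'   denotes the parent-1 homozygote (as produced by
#'   [simulate_iril_population()] or [filter_markers()]).
#' @param alpha two-sided test level (default 0.01).
#' @return data.frame with columns `marker`, `n`, `freq`, `flag`.
#' @export
distortion_scan <- function(matrix, alpha = 0.01) {
  stopifnot(inherits(matrix, "geno_matrix"))
  calls <- matrix$calls
  hom <- calls == "AA" | calls == "BB"
  n <- rowSums(hom)
  x <- rowSums(calls == "AA")
  freq <- ifelse(n > 0, x / n, NA_real_)
  half <- 0.5 * stats::dbinom(x, n, 0.5)
  lower_p <- stats::pbinom(x - 1, n, 0.5) + half
  upper_p <- stats::pbinom(x, n, 0.5, lower.tail = FALSE) + half
  flag <- n > 0 & (lower_p < alpha / 2 | upper_p < alpha / 2)
  data.frame(marker = matrix$markers$marker, n = n, freq = freq, flag = flag,
             row.names = NULL)
}

#' Dice similarity matrix and UPGMA dendrogram
#'
#' Each genotype is treated as the multiset of its two alleles (AA = \{A,A\},
#' AB = \{A,B\}); for a sample pair the Dice similarity is the number of
#' shared alleles over the total carried, accumulated across markers called
#' in both samples. The tree is agglomerative UPGMA (average linkage) on
#' distance 1 - similarity.
#'
#' @param matrix a [geno_matrix()] with >= 3 samples.
#' @return List with `similarity` (symmetric matrix, unit diagonal), `tree`
#'   (an `hclust`), and `phylo` (an `ape::phylo`).
#' @export
dice_dendrogram <- function(matrix) {
  stopifnot(inherits(matrix, "geno_matrix"))
  s <- ncol(matrix$calls)
  if (s < 3) stop("need at least 3 samples", call. = FALSE)
  dose <- matrix(match(matrix$calls, GENO_LEVELS) - 1L, nrow = nrow(matrix$calls))
  dose[dose == 3L] <- NA_integer_  # FAILED
  sim <- diag(1, s)
  dimnames(sim) <- list(matrix$samples, matrix$samples)
  for (i in seq_len(s - 1)) {
    for (j in (i + 1):s) {
      joint <- !is.na(dose[, i]) & !is.na(dose[, j])
      nj <- sum(joint)
      if (nj == 0) {
        stop("samples ", matrix$samples[i], " and ", matrix$samples[j],
             " share no jointly called markers", call. = FALSE)
      }
      shared <- sum(2L - abs(dose[joint, i] - dose[joint, j]))
      sim[i, j] <- sim[j, i] <- shared / (2 * nj)
    }
  }
  tree <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  list(similarity = sim, tree = tree, phylo = ape::as.phylo(tree))
}
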