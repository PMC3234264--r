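# Domain types: genome model, population design, noise model, genotype matrix.

#' Construct a genome model
#'
#' A genome model fixes the coordinate frame for simulation and truth
#' assessment: an ordered set of chromosomes, each with a genetic length (cM),
#' a physical length (Mbp), and an ordered marker list carrying both true
#' genetic (cM) and physical (bp) positions.
#'
#' @param chromosomes data.frame with columns `chrom` (id), `len_cM`,
#'   `len_Mbp`.
#' @param markers data.frame with columns `marker`, `chrom`, `cM`, `bp`.
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(chromosomes, markers) {
  stopifnot(all(c("chrom", "len_cM", "len_Mbp") %in% names(chromosomes)),
            all(c("marker", "chrom", "cM", "bp") %in% names(markers)))
  if (anyDuplicated(markers$marker)) stop("duplicated marker ids", call. = FALSE)
  for (cc in chromosomes$chrom) {
    mk <- markers[markers$chrom == cc, ]
    len_cM <- chromosomes$len_cM[chromosomes$chrom == cc]
    len_bp <- chromosomes$len_Mbp[chromosomes$chrom == cc] * 1e6
    if (nrow(mk) == 0) next
    if (is.unsorted(mk$cM, strictly = TRUE) || is.unsorted(mk$bp, strictly = TRUE)) {
      stop("marker cM and bp positions must be strictly increasing within ",
           "chromosome ", cc, call. = FALSE)
    }
    if (any(mk$cM < 0) || any(mk$cM > len_cM)) {
      stop("marker cM positions outside [0, chromosome length] on ", cc,
           call. = FALSE)
    }
    if (any(mk$bp < 1) || any(mk$bp > len_bp)) {
      stop("marker bp positions outside [1, physical length] on ", cc,
           call. = FALSE)
    }
  }
  structure(list(chromosomes = chromosomes, markers = markers),
            class = "genome_model")
}

#' Generate a regular synthetic genome model
#'
#' Convenience generator for simulation studies: `n_chrom` chromosomes of
#' equal genetic/physical length with `n_markers_per_chrom` markers. Markers
#' are evenly spaced with optional uniform jitter so adjacent spacings vary.
#'
#' @param n_chrom number of chromosomes.
#' @param n_markers_per_chrom markers per chromosome.
#' @param len_cM genetic length per chromosome (cM).
#' @param len_Mbp physical length per chromosome (Mbp).
#' @param jitter fraction of the mean spacing used as uniform jitter.
#' @param seed RNG seed for the jitter.
#' @return A `genome_model`.
#' @export
make_genome <- function(n_chrom = 10, n_markers_per_chrom = 200,
                        len_cM = 170, len_Mbp = 200, jitter = 0.3, seed = 1) {
  chromosomes <- data.frame(
    chrom = paste0("chr", seq_len(n_chrom)),
    len_cM = len_cM, len_Mbp = len_Mbp
  )
  markers <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_chrom), function(i) {
      m <- n_markers_per_chrom
      base <- seq(0, len_cM, length.out = m)
      gap <- len_cM / (m - 1)
      cm <- sort(base + stats::runif(m, -jitter * gap / 2, jitter * gap / 2))
      cm <- pmin(pmax(cm, 0), len_cM)
      cm <- cm + seq(0, 1e-6, length.out = m)  # enforce strict order
      cm <- cm / max(cm) * len_cM
      bp_base <- seq(1, len_Mbp * 1e6, length.out = m)
      bp_gap <- (len_Mbp * 1e6 - 1) / (m - 1)
      bp <- sort(round(bp_base + stats::runif(m, -jitter * bp_gap / 2,
                                              jitter * bp_gap / 2)))
      bp <- pmin(pmax(bp, 1), len_Mbp * 1e6)
      bp <- bp + seq_len(m) - cummin(c(0, diff(bp)))[1]  # keep >= 1
      bp <- cummax(bp) + seq_len(m)  # strictly increasing
      bp <- pmin(bp, len_Mbp * 1e6)
      while (any(diff(bp) <= 0)) bp <- cummax(bp + c(0, cumsum(diff(bp) <= 0)))
      data.frame(
        marker = sprintf("m%02d_%04d", i, seq_len(m)),
        chrom = paste0("chr", i), cM = cm, bp = bp
      )
    }))
  })
  genome_model(chromosomes, markers)
}

#' Population design for an IRIL simulation
#'
#' @param n_lines number of inbred lines to derive (>= 2).
#' @param t_intermating generations of random intermating after the F2
#'   (integer >= 0). The IBM/LHRF-style default is 4.
#' @param n_selfing single-seed-descent selfing generations (integer >= 1);
#'   residual per-locus heterozygosity is (1/2)^n_selfing in expectation.
#' @param rng_seed integer seed making the simulation reproducible.
#' @return An object of class `population_design`.
#' @export
population_design <- function(n_lines = 239, t_intermating = 4,
                              n_selfing = 6, rng_seed = 1) {
  if (n_lines < 2) stop("`n_lines` must be >= 2", call. = FALSE)
  if (t_intermating < 0 || t_intermating != round(t_intermating)) {
    stop("`t_intermating` must be a non-negative integer", call. = FALSE)
  }
  if (n_selfing < 1 || n_selfing != round(n_selfing)) {
    stop("`n_selfing` must be a positive integer", call. = FALSE)
  }
  structure(list(n_lines = as.integer(n_lines),
                 t_intermating = as.integer(t_intermating),
                 n_selfing = as.integer(n_selfing),
                 rng_seed = as.integer(rng_seed)),
            class = "population_design")
}

#' Genotyping noise model
#'
#' Describes how raw line genotypes are degraded into array-like calls:
#' random call flips, failed (missing) calls, and per-call quality (GC) scores
#' drawn from a two-component Beta mixture — a high mode for clean calls and a
#' low mode for corrupted ones, so that downstream GC thresholds (0.8 for
#' framework mapping, 0.6 for placement) actually separate the two.
#'
#' @param call_error_rate probability that a non-missing call is flipped to a
#'   different genotype.
#' @param missing_rate probability that a call is set to FAILED.
#' @param gc_good,gc_bad length-2 numeric `c(shape1, shape2)` of the Beta
#'   distributions for clean and corrupted calls respectively.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(call_error_rate = 0.005, missing_rate = 0.04,
                        gc_good = c(30, 2), gc_bad = c(3, 5)) {
  stopifnot_prob(call_error_rate, "call_error_rate")
  stopifnot_prob(missing_rate, "missing_rate")
  stopifnot(length(gc_good) == 2, length(gc_bad) == 2,
            all(gc_good > 0), all(gc_bad > 0))
  structure(list(call_error_rate = call_error_rate,
                 missing_rate = missing_rate,
                 gc_good = gc_good, gc_bad = gc_bad),
            class = "noise_model")
}

#' Construct a genotype matrix
#'
#' The central call container: a markers x samples character matrix with
#' calls in `AA`/`AB`/`BB`/`FAILED`, optional per-call GC quality scores, and
#' a marker annotation table (id, source, dbSNP id, the two alleles).
#'
#' @param calls character matrix (markers x samples) of calls.
#' @param markers data.frame with at least a `marker` column; optional
#'   `source`, `dbsnp`, `allele_a`, `allele_b`, `chrom`.
#' @param samples character vector of sample names (defaults to the column
#'   names of `calls`).
#' @param gc optional numeric matrix of per-call GC scores in \[0, 1\].
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, markers = NULL, samples = colnames(calls),
                        gc = NULL) {
  calls <- as.matrix(calls)
  check_calls(calls)
  if (is.null(markers)) {
    ids <- rownames(calls)
    if (is.null(ids)) ids <- sprintf("m%05d", seq_len(nrow(calls)))
    markers <- data.frame(marker = ids)
  }
  stopifnot(nrow(markers) == nrow(calls))
  if (is.null(samples)) samples <- sprintf("s%03d", seq_len(ncol(calls)))
  stopifnot(length(samples) == ncol(calls))
  if (!is.null(gc)) {
    gc <- as.matrix(gc)
    stopifnot(all(dim(gc) == dim(calls)))
    stopifnot_prob(gc[!is.na(gc)], "gc")
  }
  if (!"allele_a" %in% names(markers)) markers$allele_a <- "A"
  if (!"allele_b" %in% names(markers)) markers$allele_b <- "C"
  rownames(calls) <- markers$marker
  colnames(calls) <- samples
  structure(list(calls = calls, gc = gc, markers = markers, samples = samples),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d markers x %d samples; %s GC scores\n",
              nrow(x$calls), ncol(x$calls),
              if (is.null(x$gc)) "no" else "with"))
  fr <- mean(x$calls == "FAILED")
  cat(sprintf("  FAILED fraction: %.4f\n", fr))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)
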