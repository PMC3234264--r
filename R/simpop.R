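# Synthetic IRIL populations with known truth.
#
# Meiosis uses a no-interference (Haldane) crossover process: recombination
# between adjacent markers at true genetic distance d cM occurs independently
# with probability r = (1 - exp(-2 d / 100)) / 2. Haplotypes are coded 0/1
# for parental origin; a gamete is produced by choosing a starting haplotype
# at random and switching at each interval with probability r.

# Produce one gamete per individual of a population, vectorized over
# individuals. hapA/hapB are m x N origin matrices; r_adj has length m - 1.
.gametes <- function(hapA, hapB, r_adj) {
  m <- nrow(hapA); n <- ncol(hapA)
  start <- matrix(stats::rbinom(n, 1L, 0.5), nrow = 1L)
  if (m > 1L) {
    sw <- matrix(stats::runif((m - 1L) * n) < r_adj, nrow = m - 1L)
    sel <- col_cumsum_mod2(rbind(start, sw + 0L))
  } else {
    sel <- start
  }
  hapA * (1L - sel) + hapB * sel
}

#' Simulate an intermated recombinant inbred line population
#'
#' Simulates, marker-by-marker on the true cM scale of `genome`, the classical
#' IRIL breeding scheme: an F1 fully heterozygous between two homozygous
#' parents, an F2 of `n_lines` plants, `t_intermating` generations of random
#' pairwise intermating (distinct parents, population size held constant),
#' then `n_selfing` generations of single-seed-descent selfing. Crossovers
#' follow a Haldane (Poisson, no interference) process.
#'
#' Allele coding: `AA` = homozygous parent-1, `BB` = homozygous parent-2,
#' `AB` = residual heterozygote. No calls fail at this stage; noise is added
#' separately by [corrupt_genotypes()].
#'
#' @param genome a [genome_model()].
#' @param design a [population_design()].
#' @return A list with elements `genotypes` (a [geno_matrix()]) and `truth`
#'   (true marker order and cM per chromosome, per-line crossover counts, and
#'   the design), reproducible bit-for-bit given `design$rng_seed`.
#' @export
simulate_iril_population <- function(genome, design) {
  stopifnot(inherits(genome, "genome_model"),
            inherits(design, "population_design"))
  if (any(genome$chromosomes$len_cM <= 0)) {
    stop("zero-length chromosome in genome model", call. = FALSE)
  }
  per_chrom <- split(genome$markers, genome$markers$chrom)
  if (!any(vapply(per_chrom, nrow, 1L) >= 2L)) {
    stop("genome must contain at least one chromosome with >= 2 markers",
         call. = FALSE)
  }
  n <- design$n_lines
  with_seed(design$rng_seed, {
    res <- lapply(genome$chromosomes$chrom, function(cc) {
      mk <- per_chrom[[cc]]
      m <- nrow(mk)
      r_adj <- if (m > 1L) haldane_r(diff(mk$cM)) else numeric(0)
      f1A <- matrix(0L, m, n); f1B <- matrix(1L, m, n)
      # F2: two independent F1 gametes per plant
      hapA <- .gametes(f1A, f1B, r_adj)
      hapB <- .gametes(f1A, f1B, r_adj)
      # random intermating, constant population size, distinct parents
      if (design$t_intermating > 0L) {
        for (g in seq_len(design$t_intermating)) {
          p1 <- sample.int(n, n, replace = TRUE)
          p2 <- sample.int(n, n, replace = TRUE)
          clash <- p1 == p2
          p2[clash] <- (p2[clash] %% n) + 1L
          newA <- .gametes(hapA[, p1, drop = FALSE], hapB[, p1, drop = FALSE], r_adj)
          newB <- .gametes(hapA[, p2, drop = FALSE], hapB[, p2, drop = FALSE], r_adj)
          hapA <- newA; hapB <- newB
        }
      }
      # single-seed descent
      for (g in seq_len(design$n_selfing)) {
        newA <- .gametes(hapA, hapB, r_adj)
        newB <- .gametes(hapA, hapB, r_adj)
        hapA <- newA; hapB <- newB
      }
      list(mk = mk, dose = hapA + hapB,
           xo = (if (m > 1L)
                   colSums(abs(diff(hapA)) > 0) + colSums(abs(diff(hapB)) > 0)
                 else rep(0L, n)))
    })
    dose <- do.call(rbind, lapply(res, `[[`, "dose"))
    mk <- do.call(rbind, lapply(res, `[[`, "mk"))
    calls <- matrix(GENO_LEVELS[dose + 1L], nrow = nrow(dose))
    gm <- geno_matrix(calls,
                      markers = data.frame(marker = mk$marker, chrom = mk$chrom,
                                           allele_a = "A", allele_b = "C"),
                      samples = sprintf("L%04d", seq_len(n)))
    truth <- structure(list(
      markers = mk,
      crossovers = Reduce(`+`, lapply(res, `[[`, "xo")),
      design = design,
      edits = NULL
    ), class = "truth_set")
    list(genotypes = gm, truth = truth)
  })
}

#' Degrade simulated genotypes with call errors, failures and GC scores
#'
#' Applies a [noise_model()] to a clean call matrix: every call is flipped to
#' one of the two other genotypes with probability `call_error_rate`, set to
#' `FAILED` with probability `missing_rate`, and assigned a per-call GC
#' quality score drawn from the model's Beta mixture (high mode for clean
#' calls, low mode for flipped ones; `NA` for FAILED calls). The input object
#' is not modified.
#'
#' @param matrix a [geno_matrix()].
#' @param noise a [noise_model()].
#' @param seed integer RNG seed.
#' @return A new `geno_matrix` with GC scores and a `flipped` attribute
#'   (logical matrix of injected call errors).
#' @export
corrupt_genotypes <- function(matrix, noise, seed = 1) {
  stopifnot(inherits(matrix, "geno_matrix"), inherits(noise, "noise_model"))
  calls <- matrix$calls
  with_seed(seed, {
    ncell <- length(calls)
    callable <- calls != "FAILED"
    flip <- callable & (stats::runif(ncell) < noise$call_error_rate)
    if (any(flip)) {
      idx <- which(flip)
      cur <- match(calls[idx], GENO_LEVELS)
      # uniform choice among the two other genotypes
      shift <- sample.int(2L, length(idx), replace = TRUE)
      calls[idx] <- GENO_LEVELS[(cur - 1L + shift) %% 3L + 1L]
    }
    gc <- matrix(NA_real_, nrow(calls), ncol(calls))
    good <- callable & !flip
    gc[good] <- stats::rbeta(sum(good), noise$gc_good[1], noise$gc_good[2])
    gc[flip] <- stats::rbeta(sum(flip), noise$gc_bad[1], noise$gc_bad[2])
    miss <- stats::runif(ncell) < noise$missing_rate
    calls[miss] <- "FAILED"
    gc[miss] <- NA_real_
    out <- geno_matrix(calls, markers = matrix$markers,
                       samples = matrix$samples, gc = gc)
    attr(out, "flipped") <- flip & !miss
    out
  })
}

#' Simulate an F1 genotype vector from two inbred parents
#'
#' Mendelian F1 expectation for homozygous parents: different homozygotes
#' give `AB`, identical homozygotes reproduce the parental call, any `FAILED`
#' parent gives `FAILED`. Calling errors are injected at `error_rate`
#' (uniform among the two other genotypes).
#'
#' @param parent1,parent2 character call vectors of equal length with values
#'   in `AA`/`BB`/`FAILED` (heterozygous parents are rejected).
#' @param error_rate per-marker probability of an injected error.
#' @param seed RNG seed.
#' @return Character vector of F1 calls.
#' @export
make_triplets <- function(parent1, parent2, error_rate = 0, seed = 1) {
  if (length(parent1) != length(parent2)) {
    stop("parent vectors must have equal length", call. = FALSE)
  }
  check_calls(c(parent1, parent2))
  if (any(parent1 == "AB") || any(parent2 == "AB")) {
    stop("parents must be homozygous or FAILED at every marker", call. = FALSE)
  }
  f1 <- ifelse(parent1 == "FAILED" | parent2 == "FAILED", "FAILED",
               ifelse(parent1 == parent2, parent1, "AB"))
  if (error_rate > 0) {
    with_seed(seed, {
      ok <- f1 != "FAILED"
      err <- ok & (stats::runif(length(f1)) < error_rate)
      if (any(err)) {
        idx <- which(err)
        cur <- match(f1[idx], GENO_LEVELS)
        shift <- sample.int(2L, length(idx), replace = TRUE)
        f1[idx] <- GENO_LEVELS[(cur - 1L + shift) %% 3L + 1L]
      }
    })
  }
  f1
}

#' Plant known edits into a physical placement ("wrong assembly")
#'
#' Corrupts a marker placement table with inversions (the bp order of a
#' marker run is reversed), translocations (a run is moved to another
#' chromosome, internal order preserved) and deletions (markers dropped from
#' the assembly, emulating sequences missing from the reference). Overlapping
#' edit spans are rejected. The returned edit log is the ground truth used by
#' colinearity acceptance checks.
#'
#' @param placement data.frame with columns `marker`, `chrom`, `bp`.
#' @param edits list of edits, each a list with `type` in
#'   `"inversion"`/`"translocation"`/`"deletion"`, `chrom`, `start`, `end`
#'   (bp span on `chrom`), and for translocations `to` (target chromosome)
#'   plus optional `at` (target bp offset; random if omitted).
#' @param seed RNG seed (used only for random translocation targets).
#' @return List with `placement` (edited table) and `log` (data.frame of
#'   edits with their member markers).
#' @export
plant_misassembly <- function(placement, edits = list(), seed = 1) {
  stopifnot(all(c("marker", "chrom", "bp") %in% names(placement)))
  if (length(edits) == 0) {
    return(list(placement = placement,
                log = data.frame(type = character(), chrom = character(),
                                 start = numeric(), end = numeric(),
                                 to = character(), markers = character())))
  }
  spans <- do.call(rbind, lapply(edits, function(e)
    data.frame(chrom = e$chrom, start = e$start, end = e$end)))
  for (cc in unique(spans$chrom)) {
    s <- spans[spans$chrom == cc, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
      stop("overlapping edit spans on ", cc, call. = FALSE)
    }
  }
  out <- placement
  log_rows <- list()
  with_seed(seed, {
    for (e in edits) {
      in_span <- out$chrom == e$chrom & out$bp >= e$start & out$bp <= e$end
      members <- out$marker[in_span]
      if (length(members) == 0) {
        stop("edit span contains no markers (", e$chrom, ":", e$start, "-",
             e$end, ")", call. = FALSE)
      }
      idx <- which(in_span)[order(out$bp[in_span])]
      if (e$type == "inversion") {
        out$bp[idx] <- rev(out$bp[idx])
      } else if (e$type == "translocation") {
        at <- e$at
        if (is.null(at)) {
          lim <- max(out$bp[out$chrom == e$to], e$end)
          at <- round(stats::runif(1, 1, lim))
        }
        out$chrom[idx] <- e$to
        out$bp[idx] <- at + out$bp[idx] - min(out$bp[idx])
      } else if (e$type == "deletion") {
        out <- out[-idx, , drop = FALSE]
      } else {
        stop("unknown edit type: ", e$type, call. = FALSE)
      }
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        type = e$type, chrom = e$chrom, start = e$start, end = e$end,
        to = if (is.null(e$to)) NA_character_ else e$to,
        markers = paste(members, collapse = ";")
      )
    }
  })
  rownames(out) <- NULL
  list(placement = out, log = do.call(rbind, log_rows))
}
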