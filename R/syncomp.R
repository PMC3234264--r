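# Comparison of genetic maps with a physical genome assembly.
#
# Genetic linkage groups carry arbitrary labels and orientations; before any
# rank comparison each group is matched to the physical chromosome holding
# the majority of its placed markers and oriented so genetic and physical
# positions correlate positively.

#' Chromosome-assignment concordance between a genetic map and an assembly
#'
#' Each linkage group is matched to its majority physical chromosome; a
#' mapped-and-placed marker is concordant when its own physical chromosome
#' equals the matched chromosome of its linkage group. Unplaced or unmapped
#' markers get no flag.
#'
#' @param map_table map table (see [as_map_table()]) with columns `marker`,
#'   `status`, `chrom`, `cM`; physical columns are taken from the table or
#'   joined from `placement`.
#' @param placement optional placement data.frame (`marker`, `chrom`, `bp`).
#' @return List with `records` (per-marker data.frame incl. `concordant`),
#'   `chrom_match` (linkage group -> physical chromosome), `n_mapped_placed`,
#'   `n_discordant`.
#' @export
concordance <- function(map_table, placement = NULL) {
  df <- map_table
  if (!is.null(placement)) {
    idx <- match(df$marker, placement$marker)
    df$phys_chrom <- placement$chrom[idx]
    df$phys_bp <- placement$bp[idx]
  }
  stopifnot(all(c("phys_chrom", "phys_bp") %in% names(df)))
  mapped <- df$status %in% c("frame", "placed") & !is.na(df$chrom)
  placed <- !is.na(df$phys_chrom)
  chrom_match <- vapply(split(df$phys_chrom[mapped & placed],
                              df$chrom[mapped & placed]),
                        function(pc) names(sort(table(pc), decreasing = TRUE))[1],
                        character(1))
  df$concordant <- NA
  sel <- mapped & placed
  df$concordant[sel] <- df$phys_chrom[sel] == chrom_match[df$chrom[sel]]
  list(records = df, chrom_match = chrom_match,
       n_mapped_placed = sum(sel),
       n_discordant = sum(!df$concordant[sel]))
}

#' Group non-syntenic markers into clusters and singletons
#'
#' Discordant markers are grouped when they sit on the same physical
#' chromosome within `max_gap_bp` of each other and are genetically assigned
#' to the same linkage group.
#'
#' @param conc result of [concordance()].
#' @param max_gap_bp maximum physical gap joining two discordant markers
#'   (default 10 Mbp).
#' @return data.frame with one row per group: `phys_chrom`, `genetic_chrom`,
#'   `start`, `end`, `n_markers`, `kind` (`cluster`/`singleton`), `markers`.
#' @export
cluster_nonsyntenic <- function(conc, max_gap_bp = 1e7) {
  rec <- conc$records
  disc <- rec[!is.na(rec$concordant) & !rec$concordant, , drop = FALSE]
  if (nrow(disc) == 0) {
    return(data.frame(phys_chrom = character(), genetic_chrom = character(),
                      start = numeric(), end = numeric(),
                      n_markers = integer(), kind = character(),
                      markers = character()))
  }
  out <- list()
  for (key in unique(paste(disc$phys_chrom, disc$chrom))) {
    sub <- disc[paste(disc$phys_chrom, disc$chrom) == key, , drop = FALSE]
    sub <- sub[order(sub$phys_bp), , drop = FALSE]
    grp <- cumsum(c(1, diff(sub$phys_bp) > max_gap_bp))
    for (g in unique(grp)) {
      s <- sub[grp == g, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        phys_chrom = s$phys_chrom[1], genetic_chrom = s$chrom[1],
        start = min(s$phys_bp), end = max(s$phys_bp),
        n_markers = nrow(s),
        kind = if (nrow(s) > 1) "cluster" else "singleton",
        markers = paste(s$marker, collapse = ";"))
    }
  }
  res <- do.call(rbind, out)
  res[order(res$phys_chrom, res$start), , drop = FALSE]
}

# Flag framework markers whose physical rank disagrees with their genetic
# rank on one (matched, oriented) chromosome.
.rank_flags <- function(sub, rank_tol, bp_tol) {
  if (stats::cor(sub$cM, sub$phys_bp, method = "spearman") < 0) {
    sub$cM <- max(sub$cM) - sub$cM
  }
  sub <- sub[order(sub$cM, sub$phys_bp), , drop = FALSE]
  rg <- seq_len(nrow(sub))
  rp <- rank(sub$phys_bp, ties.method = "first")
  bp_sorted <- sort(sub$phys_bp)
  expected_bp <- bp_sorted[rg]
  disp_bp <- abs(sub$phys_bp - expected_bp)
  sub$flagged <- abs(rg - rp) > rank_tol | disp_bp > bp_tol
  # implied displacement span: from where the marker sits to where its
  # genetic rank says it should sit; an inversion's end markers span the
  # whole inverted block, so overlapping spans identify one disturbance
  sub$span_lo <- pmin(sub$phys_bp, expected_bp)
  sub$span_hi <- pmax(sub$phys_bp, expected_bp)
  sub
}

#' Call non-colinear regions between a framework map and the assembly
#'
#' Framework markers concordant in chromosome assignment are compared in
#' rank: a marker is discrepant when its physical rank differs from its
#' genetic rank by more than `rank_tol` positions or its physical coordinate
#' differs by more than `bp_tol` from the coordinate expected at its genetic
#' rank. Each discrepant marker implies a displacement span (from where it
#' sits to where its genetic rank expects it); discrepant markers whose
#' spans overlap (within `merge_gap_bp` slack) form a region when at least
#' two; a single discrepant marker becomes a region only when its position
#' overlaps a region of the other population.
#' Regions are named `<chromosome number>.<index><suffix>` with the index
#' ascending in physical start.
#'
#' @param map_table framework-containing map table (only `status == "frame"`
#'   rows are used).
#' @param placement placement data.frame.
#' @param other_regions optional region table from the other population.
#' @param suffix population suffix for region names (e.g. `"I"` or `"L"`).
#' @param rank_tol,bp_tol discrepancy tolerances (default 2 positions /
#'   5 Mbp).
#' @param merge_gap_bp physical gap merging discrepant markers (default
#'   10 Mbp).
#' @param complete_table optional complete map table used to refine region
#'   spans (flagged placed markers inside a region extend it).
#' @return data.frame: `name`, `phys_chrom`, `start`, `end`, `n_markers`,
#'   `support`, `markers`.
#' @export
call_regions <- function(map_table, placement = NULL, other_regions = NULL,
                         suffix = "I", rank_tol = 2, bp_tol = 5e6,
                         merge_gap_bp = 1e7, complete_table = NULL) {
  conc <- concordance(map_table, placement)
  rec <- conc$records
  fw <- rec[rec$status == "frame" & !is.na(rec$concordant) & rec$concordant, ,
            drop = FALSE]
  regions <- list()
  for (cc in unique(fw$phys_chrom)) {
    sub <- fw[fw$phys_chrom == cc, , drop = FALSE]
    if (nrow(sub) < 4) next
    sub <- .rank_flags(sub, rank_tol, bp_tol)
    fl <- sub[sub$flagged, , drop = FALSE]
    if (nrow(fl) == 0) next
    fl <- fl[order(fl$span_lo), , drop = FALSE]
    # merge flagged markers whose displacement spans overlap or nearly touch
    hi <- cummax(fl$span_hi)
    grp <- cumsum(c(1, fl$span_lo[-1] > hi[-nrow(fl)] + merge_gap_bp))
    for (g in unique(grp)) {
      s <- fl[grp == g, , drop = FALSE]
      span <- range(s$phys_bp)
      keep <- nrow(s) >= 2
      support <- "one"
      if (!is.null(other_regions) && nrow(other_regions) > 0) {
        ov <- other_regions$phys_chrom == cc &
          other_regions$start <= span[2] & other_regions$end >= span[1]
        if (any(ov)) {
          support <- "both"
          keep <- TRUE  # single-marker region backed by the other population
        }
      }
      if (!keep) next
      regions[[length(regions) + 1L]] <- data.frame(
        phys_chrom = cc, start = span[1], end = span[2],
        n_markers = nrow(s), support = support,
        markers = paste(s$marker, collapse = ";"))
    }
  }
  if (length(regions) == 0) {
    return(data.frame(name = character(), phys_chrom = character(),
                      start = numeric(), end = numeric(),
                      n_markers = integer(), support = character(),
                      markers = character()))
  }
  res <- do.call(rbind, regions)
  if (!is.null(complete_table)) {
    res <- .refine_regions(res, complete_table, placement, rank_tol, bp_tol)
  }
  res <- res[order(res$phys_chrom, res$start), , drop = FALSE]
  idx <- stats::ave(res$start, res$phys_chrom, FUN = seq_along)
  num <- gsub("\\D", "", res$phys_chrom)
  res <- cbind(name = paste0(ifelse(num == "", res$phys_chrom, num), ".",
                             idx, suffix), res)
  rownames(res) <- NULL
  res
}

# Extend region spans with discrepant complete-map (placed) markers.
.refine_regions <- function(regions, complete_table, placement,
                            rank_tol, bp_tol) {
  conc <- concordance(complete_table, placement)
  rec <- conc$records
  all_m <- rec[rec$status %in% c("frame", "placed") & !is.na(rec$concordant) &
                 rec$concordant, , drop = FALSE]
  for (i in seq_len(nrow(regions))) {
    cc <- regions$phys_chrom[i]
    sub <- all_m[all_m$phys_chrom == cc, , drop = FALSE]
    if (nrow(sub) < 4) next
    sub <- .rank_flags(sub, rank_tol, bp_tol)
    fl <- sub[sub$flagged, , drop = FALSE]
    near <- fl$phys_bp >= regions$start[i] - 5e6 &
      fl$phys_bp <= regions$end[i] + 5e6
    if (any(near)) {
      regions$start[i] <- min(regions$start[i], fl$phys_bp[near])
      regions$end[i] <- max(regions$end[i], fl$phys_bp[near])
    }
  }
  regions
}

#' Marey-map recombination landscape of one chromosome
#'
#' Monotone smoothing of genetic versus physical marker positions and its
#' first derivative, the local recombination rate in cM/Mbp. Outliers beyond
#' `outlier_tol_cM` from a running-median trend are excluded, the remaining
#' scatter is smoothed by local linear regression with a physical bandwidth,
#' monotonicity is enforced by isotonic regression, and the endpoints are
#' pinned to the observed genetic span so the rate integrates to the
#' chromosome's genetic length.
#'
#' @param map_table map table of one population.
#' @param placement placement data.frame.
#' @param chrom physical chromosome to analyse.
#' @param bandwidth_bp smoothing bandwidth (default 10 Mbp).
#' @param grid_n number of uniform grid points (default 200).
#' @param outlier_tol_cM residual tolerance for outlier exclusion.
#' @param min_markers minimum concordant markers required (default 20).
#' @return data.frame with columns `bp`, `cM` (smoothed) and `rate`
#'   (cM/Mbp), of class `marey_landscape`.
#' @export
landscape <- function(map_table, placement = NULL, chrom,
                      bandwidth_bp = 1e7, grid_n = 200,
                      outlier_tol_cM = 15, min_markers = 20) {
  conc <- concordance(map_table, placement)
  rec <- conc$records
  sub <- rec[!is.na(rec$concordant) & rec$concordant &
               rec$phys_chrom == chrom, , drop = FALSE]
  if (nrow(sub) < min_markers) {
    stop("fewer than ", min_markers, " concordant markers on ", chrom,
         call. = FALSE)
  }
  if (stats::cor(sub$cM, sub$phys_bp, method = "spearman") < 0) {
    sub$cM <- max(sub$cM) - sub$cM
  }
  sub <- sub[order(sub$phys_bp), , drop = FALSE]
  trend <- stats::runmed(sub$cM[order(sub$phys_bp)], k = 11)
  keep <- abs(sub$cM - trend) <= outlier_tol_cM
  sub <- sub[keep, , drop = FALSE]
  span_bp <- range(sub$phys_bp)
  span_cM <- range(sub$cM)
  frac <- min(1, max(0.1, 2.5 * bandwidth_bp / diff(span_bp)))
  fit <- stats::loess(cM ~ phys_bp, data = sub, degree = 1, span = frac,
                      family = "symmetric",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(span_bp[1], span_bp[2], length.out = grid_n)
  sm <- stats::predict(fit, newdata = data.frame(phys_bp = grid))
  sm <- pmin(pmax(sm, span_cM[1]), span_cM[2])
  sm <- stats::isoreg(grid, sm)$yf
  sm[1] <- span_cM[1]
  sm[grid_n] <- span_cM[2]
  sm <- cummax(sm)
  rate <- c(diff(sm) / (diff(grid) / 1e6))
  out <- data.frame(bp = grid, cM = sm, rate = c(rate[1], rate))
  class(out) <- c("marey_landscape", "data.frame")
  attr(out, "chrom") <- chrom
  attr(out, "genetic_span_cM") <- diff(span_cM)
  out
}

#' Predict physical positions from genetic positions
#'
#' Homothetic prediction for genetically mapped markers that are absent from
#' (or misplaced in) the assembly: the marker's cM position is linearly
#' interpolated between the nearest flanking concordant framework anchors on
#' its linkage group; beyond the terminal anchors the terminal slope is
#' extrapolated, clamped to the chromosome bounds.
#'
#' @param markers character vector of marker ids to predict.
#' @param map_table map table containing the markers and the anchors.
#' @param placement placement data.frame (anchor coordinates and chromosome
#'   bounds).
#' @return data.frame `marker`, `pred_chrom`, `pred_bp` (`NA` when no
#'   anchors exist on the marker's group).
#' @export
predict_physical <- function(markers, map_table, placement = NULL) {
  conc <- concordance(map_table, placement)
  rec <- conc$records
  out <- data.frame(marker = markers, pred_chrom = NA_character_,
                    pred_bp = NA_real_)
  for (i in seq_along(markers)) {
    row <- rec[rec$marker == markers[i], , drop = FALSE]
    if (nrow(row) == 0 || is.na(row$chrom) || is.na(row$cM)) next
    anchors <- rec[rec$chrom == row$chrom & rec$status == "frame" &
                     !is.na(rec$concordant) & rec$concordant, , drop = FALSE]
    if (nrow(anchors) < 2) next
    pc <- conc$chrom_match[row$chrom]
    anchors <- anchors[order(anchors$cM), , drop = FALSE]
    slope_sign <- sign(stats::cor(anchors$cM, anchors$phys_bp,
                                  method = "spearman"))
    x <- anchors$cM
    y <- anchors$phys_bp
    cm <- row$cM
    if (cm <= min(x)) {
      j <- 1:2
    } else if (cm >= max(x)) {
      j <- (nrow(anchors) - 1):nrow(anchors)
    } else {
      j <- c(max(which(x <= cm)), min(which(x >= cm)))
    }
    if (x[j[2]] == x[j[1]]) {
      bp <- y[j[1]]
    } else {
      bp <- y[j[1]] + (cm - x[j[1]]) / (x[j[2]] - x[j[1]]) * (y[j[2]] - y[j[1]])
    }
    lim <- range(placement$bp[placement$chrom == pc], na.rm = TRUE)
    out$pred_chrom[i] <- pc
    out$pred_bp[i] <- min(max(bp, 1), lim[2])
  }
  out
}

#' Polymorphism deserts: physical spans empty in one population
#'
#' Maximal physical spans of at least `min_span_Mbp` containing zero
#' polymorphic markers of one population but at least `min_other` of the
#' other, suggesting identity by descent between the first population's
#' parents.
#'
#' @param placement placement data.frame for all markers.
#' @param poly_self,poly_other character vectors of marker ids polymorphic in
#'   the focal and the other population.
#' @param min_span_Mbp minimum span (default 10).
#' @param min_other minimum markers of the other population inside the span.
#' @return data.frame `chrom`, `start`, `end`, `span_Mbp`, `n_other`.
#' @export
deserts <- function(placement, poly_self, poly_other, min_span_Mbp = 10,
                    min_other = 5) {
  out <- list()
  pl <- placement[!is.na(placement$chrom), , drop = FALSE]
  for (cc in unique(pl$chrom)) {
    self_bp <- sort(pl$bp[pl$chrom == cc & pl$marker %in% poly_self])
    other_bp <- pl$bp[pl$chrom == cc & pl$marker %in% poly_other]
    if (length(self_bp) < 2) next
    gaps <- which(diff(self_bp) >= min_span_Mbp * 1e6)
    for (g in gaps) {
      lo <- self_bp[g]; hi <- self_bp[g + 1]
      n_other <- sum(other_bp > lo & other_bp < hi)
      if (n_other >= min_other) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = cc, start = lo, end = hi,
          span_Mbp = (hi - lo) / 1e6, n_other = n_other)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      span_Mbp = numeric(), n_other = integer()))
  }
  do.call(rbind, out)
}
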