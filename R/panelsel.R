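# Prioritized SNP panel selection.
#
# Candidates carry a source tag (the large discovery panel, tagged "Panzea",
# versus all other sources), an optional gene annotation, an assay design
# score, an assay class ("II" = one bead type, preferred; "I" = two bead
# types), flanking-SNP flags, and an optional genomic position. Selection
# proceeds in four steps: (1) non-Panzea SNPs in high-confidence genes,
# (2) non-Panzea SNPs outside genes, (3) Panzea SNPs covering genes not yet
# represented, (4) greedy even-spacing fill across the genome.

#' Selection configuration
#'
#' @param target_size desired panel size.
#' @param min_score minimum assay design score admitted by [prefilter()].
#' @param spacing if `TRUE` (default) step 4 fills the largest physical gaps;
#'   if `FALSE` it degenerates to a score-descending fill.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(target_size, min_score = 0.6, spacing = TRUE) {
  stopifnot(target_size >= 1)
  structure(list(target_size = as.integer(target_size),
                 min_score = min_score, spacing = isTRUE(spacing)),
            class = "selection_config")
}

# deterministic preference: one-bead assays first, then higher scores, then id
.pref_order <- function(df) {
  order(df$assay_class != "II", -df$score, df$id)
}

#' Prefilter SNP candidates
#'
#' Removes duplicated candidates (same id, or same position), candidates with
#' known SNPs in both flanking sequences, and candidates below the minimum
#' assay design score.
#'
#' @param candidates data.frame with columns `id`, `source`, `gene`, `score`,
#'   `assay_class`, `flank_left`, `flank_right`, and optional `chrom`, `bp`.
#' @param min_score minimum design score (default 0.6).
#' @return The surviving candidate data.frame.
#' @export
prefilter <- function(candidates, min_score = 0.6) {
  df <- candidates
  df <- df[!duplicated(df$id), , drop = FALSE]
  if (all(c("chrom", "bp") %in% names(df))) {
    pos <- paste(df$chrom, df$bp)
    keep <- is.na(df$chrom) | !duplicated(pos) | is.na(df$bp)
    df <- df[keep, , drop = FALSE]
  }
  df <- df[!(df$flank_left & df$flank_right), , drop = FALSE]
  df <- df[df$score >= min_score, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Four-step prioritized panel selection
#'
#' @param candidates prefiltered candidate data.frame (see [prefilter()]).
#' @param config a [selection_config()].
#' @return data.frame of selected candidates with an added `step` column in
#'   `1:4`; at most `config$target_size` rows.
#' @export
staged_select <- function(candidates, config) {
  stopifnot(inherits(config, "selection_config"))
  if (nrow(candidates) == 0) stop("empty candidate set", call. = FALSE)
  df <- candidates
  df$step <- NA_integer_
  panzea <- df$source == "Panzea"
  in_gene <- !is.na(df$gene)

  take <- function(df, idx, step, room) {
    idx <- idx[order(df$assay_class[idx] != "II", -df$score[idx], df$id[idx])]
    idx <- utils::head(idx, room)
    df$step[idx] <- step
    df
  }
  room <- function() config$target_size - sum(!is.na(df$step))

  df <- take(df, which(!panzea & in_gene & is.na(df$step)), 1L, room())
  df <- take(df, which(!panzea & !in_gene & is.na(df$step)), 2L, room())

  covered <- unique(df$gene[!is.na(df$step) & in_gene])
  cand3 <- which(panzea & in_gene & is.na(df$step) & !(df$gene %in% covered))
  if (length(cand3) && room() > 0) {
    # best candidate per still-uncovered gene, genes in preference order
    ord <- cand3[order(df$assay_class[cand3] != "II", -df$score[cand3],
                       df$id[cand3])]
    ord <- ord[!duplicated(df$gene[ord])]
    df <- take(df, ord, 3L, room())
  }

  while (room() > 0) {
    rest <- which(is.na(df$step))
    if (length(rest) == 0) break
    pick <- NA_integer_
    if (config$spacing && "bp" %in% names(df)) {
      pick <- .pick_in_largest_gap(df, rest)
    }
    if (is.na(pick)) {
      rest <- rest[order(df$assay_class[rest] != "II", -df$score[rest],
                         df$id[rest])]
      pick <- rest[1]
    }
    df$step[pick] <- 4L
  }
  out <- df[!is.na(df$step), , drop = FALSE]
  out <- out[order(out$step, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Find the unselected positioned candidate nearest the midpoint of the
# largest physical gap between already-selected markers (chromosome spans
# bounded by the extreme candidate positions).
.pick_in_largest_gap <- function(df, rest) {
  placed <- !is.na(df$bp) & !is.na(df$chrom)
  rest <- rest[placed[rest]]
  if (length(rest) == 0) return(NA_integer_)
  gaps <- list()
  for (cc in unique(df$chrom[placed])) {
    span <- range(df$bp[placed & df$chrom == cc])
    sel <- sort(df$bp[placed & df$chrom == cc & !is.na(df$step)])
    edges <- unique(c(span[1], sel, span[2]))
    if (length(edges) < 2) next
    w <- diff(edges)
    for (k in seq_along(w)) {
      gaps[[length(gaps) + 1L]] <- list(chrom = cc, lo = edges[k],
                                        hi = edges[k + 1], width = w[k])
    }
  }
  if (length(gaps) == 0) return(NA_integer_)
  gaps <- gaps[order(-vapply(gaps, `[[`, numeric(1), "width"))]
  for (g in gaps) {
    inside <- rest[df$chrom[rest] == g$chrom & df$bp[rest] >= g$lo &
                     df$bp[rest] <= g$hi]
    if (length(inside)) {
      mid <- (g$lo + g$hi) / 2
      d <- abs(df$bp[inside] - mid)
      inside <- inside[order(d, df$assay_class[inside] != "II",
                             -df$score[inside], df$id[inside])]
      return(inside[1])
    }
  }
  NA_integer_
}
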