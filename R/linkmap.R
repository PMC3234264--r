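# Marker filtering and end-to-end linkage-map construction.

#' Filtering configuration for map construction
#'
#' Two stages mirror the published pipeline: the framework stage uses a GC
#' quality threshold of 0.8 and tolerates at most 35% missing data per
#' marker; the complete (placement) stage relaxes these to 0.6 and 50%.
#' Both stages require a minor-allele frequency above 0.10.
#'
#' @param stage `"framework"` or `"complete"`.
#' @param gc_min,max_missing,maf_min override the stage defaults.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(stage = c("framework", "complete"),
                          gc_min = NULL, max_missing = NULL, maf_min = 0.10) {
  stage <- match.arg(stage)
  defaults <- if (stage == "framework") c(0.8, 0.35) else c(0.6, 0.50)
  structure(list(stage = stage,
                 gc_min = if (is.null(gc_min)) defaults[1] else gc_min,
                 max_missing = if (is.null(max_missing)) defaults[2] else max_missing,
                 maf_min = maf_min),
            class = "filter_config")
}

#' Filter and recode markers for linkage mapping
#'
#' Applies the mapping filters: calls with GC score below `gc_min` become
#' missing, heterozygous calls become missing, and markers are excluded when
#' the founding parents are not both homozygous and mutually polymorphic,
#' when the missing fraction exceeds the stage limit, or when the
#' minor-allele frequency is not above `maf_min`. Retained markers are
#' recoded to parental origin (`AA` = parent-1 allele).
#'
#' @param matrix a [geno_matrix()] (GC scores used when present).
#' @param parents list with elements `p1` and `p2`: either sample names
#'   present in the matrix or call vectors of length `nrow(matrix$calls)`.
#' @param config a [filter_config()].
#' @return List with `matrix` (filtered, recoded `geno_matrix`) and
#'   `diagnostics` (data.frame `marker`, `status` in
#'   `retained`/`parents`/`missing`/`maf`).
#' @export
filter_markers <- function(matrix, parents, config = filter_config("framework")) {
  stopifnot(inherits(matrix, "geno_matrix"), inherits(config, "filter_config"))
  if (is.null(parents) || !all(c("p1", "p2") %in% names(parents))) {
    stop("founding parent genotypes are required (list(p1 = , p2 = ))",
         call. = FALSE)
  }
  resolve <- function(p) {
    if (length(p) == 1 && p %in% matrix$samples) {
      matrix$calls[, p]
    } else if (length(p) == nrow(matrix$calls)) {
      p
    } else {
      stop("parent must be a sample name or a per-marker call vector",
           call. = FALSE)
    }
  }
  p1 <- resolve(parents$p1)
  p2 <- resolve(parents$p2)
  calls <- matrix$calls
  if (!is.null(matrix$gc)) {
    calls[!is.na(matrix$gc) & matrix$gc < config$gc_min] <- "FAILED"
  }
  calls[calls == "AB"] <- "FAILED"
  parent_ok <- p1 %in% c("AA", "BB") & p2 %in% c("AA", "BB") & p1 != p2
  # recode to parental origin: AA = parent-1 allele
  flip <- parent_ok & p1 == "BB"
  if (any(flip)) {
    fl <- calls[flip, , drop = FALSE]
    fl[fl == "AA"] <- "xx"
    fl[fl == "BB"] <- "AA"
    fl[fl == "xx"] <- "BB"
    calls[flip, ] <- fl
  }
  missing_frac <- rowMeans(calls == "FAILED")
  n_aa <- rowSums(calls == "AA")
  n_bb <- rowSums(calls == "BB")
  maf <- ifelse(n_aa + n_bb > 0, pmin(n_aa, n_bb) / (n_aa + n_bb), 0)
  status <- rep("retained", nrow(calls))
  status[maf <= config$maf_min] <- "maf"
  status[missing_frac > config$max_missing] <- "missing"
  status[!parent_ok] <- "parents"
  keep <- status == "retained"
  diagnostics <- data.frame(marker = matrix$markers$marker, status = status,
                            missing = missing_frac, maf = maf)
  filtered <- geno_matrix(calls[keep, , drop = FALSE],
                          markers = matrix$markers[keep, , drop = FALSE],
                          samples = matrix$samples,
                          gc = if (is.null(matrix$gc)) NULL else
                            matrix$gc[keep, , drop = FALSE])
  list(matrix = filtered, diagnostics = diagnostics)
}

#' Build linkage maps for all chromosomes
#'
#' The full de-novo pipeline: framework- and complete-stage filtering,
#' all-pairs two-point estimation, linkage grouping, per-group scaffold
#' construction, framework extension, multipoint distance estimation
#' (corrected cM and pseudo-cM), and bin placement of the remaining
#' complete-stage markers.
#'
#' @param matrix a [geno_matrix()] with GC scores (or without, in which case
#'   no GC filtering happens).
#' @param parents as in [filter_markers()].
#' @param t intermating generations of the population design.
#' @param lod_threshold,r_threshold linkage-grouping thresholds
#'   (see [group_markers()]).
#' @param min_spacing_cM,score_threshold,n_replicates scaffold parameters
#'   (see [build_scaffold()]).
#' @param robustness_threshold framework insertion margin
#'   (see [extend_framework()]).
#' @param placement_threshold bin-placement margin (see [place_bins()]).
#' @param min_group_size groups smaller than this stay unmapped (default 6).
#' @return An object of class `linkage_map`: per linkage group a data.frame
#'   (`marker`, `tier`, `cM`, `pseudo_cM`), plus `assignment` (marker ->
#'   group id for every grouped marker), `t`, and filtering `diagnostics`.
#' @export
build_maps <- function(matrix, parents, t,
                       lod_threshold = 10, r_threshold = 0.25,
                       min_spacing_cM = 10, score_threshold = 3,
                       n_replicates = 10, robustness_threshold = 3,
                       placement_threshold = 3, min_group_size = 6) {
  fw <- filter_markers(matrix, parents, filter_config("framework"))
  cm <- filter_markers(matrix, parents, filter_config("complete"))
  if (nrow(cm$matrix$calls) < 2) stop("too few markers after filtering",
                                      call. = FALSE)
  tp <- twopoint_matrix(cm$matrix$calls)
  grouping <- group_markers(tp, lod_threshold, r_threshold)
  chromosomes <- list()
  for (gi in seq_along(grouping$groups)) {
    members <- grouping$groups[[gi]]
    if (length(members) < min_group_size) next
    fw_ids <- intersect(rownames(fw$matrix$calls), members)
    if (length(fw_ids) < 3) next
    fcalls <- fw$matrix$calls[fw_ids, , drop = FALSE]
    sc <- build_scaffold(fcalls, t, min_spacing_cM, score_threshold,
                         n_replicates)
    if (length(sc$order) < 2) next
    framework <- extend_framework(sc$order, fcalls, t, robustness_threshold)
    ord <- framework$order
    dist <- multipoint_distances(fw$matrix$calls[ord, , drop = FALSE], t)
    rest <- setdiff(members, ord)
    rows <- data.frame(marker = ord,
                       tier = unname(framework$tier[ord]),
                       cM = dist$pos_cM, pseudo_cM = dist$pos_pseudo_cM)
    if (length(rest) > 0) {
      bins <- place_bins(ord, fw$matrix$calls[ord, , drop = FALSE],
                         cm$matrix$calls[rest, , drop = FALSE], t,
                         dist = dist, threshold = placement_threshold)
      placed <- bins[bins$placed, , drop = FALSE]
      if (nrow(placed) > 0) {
        rows <- rbind(rows, data.frame(marker = placed$marker, tier = "placed",
                                       cM = placed$cM,
                                       pseudo_cM = placed$pseudo_cM))
      }
    }
    rows <- rows[order(rows$cM, rows$marker), , drop = FALSE]
    rownames(rows) <- NULL
    chromosomes[[paste0("LG", length(chromosomes) + 1L)]] <- rows
  }
  structure(list(chromosomes = chromosomes, assignment = grouping$assignment,
                 groups = grouping$groups, t = t,
                 diagnostics = list(framework = fw$diagnostics,
                                    complete = cm$diagnostics)),
            class = "linkage_map")
}

#' @export
print.linkage_map <- function(x, ...) {
  cat(sprintf("<linkage_map> %d linkage groups, t = %d\n",
              length(x$chromosomes), x$t))
  for (nm in names(x$chromosomes)) {
    ch <- x$chromosomes[[nm]]
    cat(sprintf("  %s: %d markers (%d framework), %.1f cM (%.1f pseudo-cM)\n",
                nm, nrow(ch), sum(ch$tier != "placed"),
                max(ch$cM), max(ch$pseudo_cM)))
  }
  invisible(x)
}

#' Total corrected and pseudo map lengths
#'
#' @param map a `linkage_map`.
#' @return Named vector with `cM` and `pseudo_cM` totals over linkage groups.
#' @export
map_lengths <- function(map) {
  stopifnot(inherits(map, "linkage_map"))
  c(cM = sum(vapply(map$chromosomes, function(ch) max(ch$cM), numeric(1))),
    pseudo_cM = sum(vapply(map$chromosomes, function(ch) max(ch$pseudo_cM),
                           numeric(1))))
}

#' Flatten a linkage map to the map-table dialect
#'
#' @param map a `linkage_map`.
#' @param placement optional physical placement data.frame (`marker`,
#'   `chrom`, `bp`) merged into the physical columns.
#' @param all_markers optional character vector of every assayed marker;
#'   markers absent from the map are emitted with status `-`.
#' @return data.frame in the [write_map_table()] dialect, with an extra
#'   `genetic_chrom` column naming the linkage group.
#' @export
as_map_table <- function(map, placement = NULL, all_markers = NULL) {
  stopifnot(inherits(map, "linkage_map"))
  rows <- do.call(rbind, lapply(names(map$chromosomes), function(nm) {
    ch <- map$chromosomes[[nm]]
    data.frame(marker = ch$marker,
               status = ifelse(ch$tier == "placed", "placed", "frame"),
               chrom = nm, cM = ch$cM, pseudo_cM = ch$pseudo_cM)
  }))
  if (!is.null(all_markers)) {
    missing <- setdiff(all_markers, rows$marker)
    if (length(missing)) {
      rows <- rbind(rows, data.frame(marker = missing, status = "-",
                                     chrom = NA_character_, cM = NA_real_,
                                     pseudo_cM = NA_real_))
    }
  }
  if (!is.null(placement)) {
    idx <- match(rows$marker, placement$marker)
    rows$phys_chrom <- placement$chrom[idx]
    rows$phys_bp <- placement$bp[idx]
  } else {
    rows$phys_chrom <- NA_character_
    rows$phys_bp <- NA_real_
  }
  rownames(rows) <- NULL
  rows
}
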