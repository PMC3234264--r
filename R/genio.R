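# Readers and writers for the study's tabular dialects.
#
# Genotype tables are comma-separated UTF-8 text: three annotation columns
# (marker name, marker source, dbSNP id) followed by one column per sample.
# Sample cells hold a single IUPAC base call — the plain base for a
# homozygote, the two-allele ambiguity letter for a heterozygote — or the
# literal token "Failed" for no data.

IUPAC_HET <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

.het_code <- function(a, b) {
  ab <- paste0(pmin(a, b), pmax(a, b))
  code <- names(IUPAC_HET)[match(ab, IUPAC_HET)]
  if (anyNA(code)) stop("no IUPAC code for allele pair ", ab[is.na(code)][1],
                        call. = FALSE)
  code
}

#' Write a genotype matrix in the IUPAC CSV dialect
#'
#' @param matrix a [geno_matrix()] whose marker table carries `allele_a` and
#'   `allele_b` base letters.
#' @param path output CSV path.
#' @param gc_path optional path for a companion CSV of per-call GC scores
#'   (same layout; written only when the matrix has scores).
#' @return Invisibly, `path`.
#' @export
write_genotypes <- function(matrix, path, gc_path = NULL) {
  stopifnot(inherits(matrix, "geno_matrix"))
  mk <- matrix$markers
  a <- mk$allele_a
  b <- mk$allele_b
  if (any(matrix$calls == "BB" & is.na(b))) {
    stop("BB calls present for markers with unknown allele_b", call. = FALSE)
  }
  cells <- matrix$calls
  n <- nrow(cells)
  out <- matrix("Failed", n, ncol(cells))
  for (j in seq_len(ncol(cells))) {
    cj <- cells[, j]
    out[cj == "AA", j] <- a[cj == "AA"]
    out[cj == "BB", j] <- b[cj == "BB"]
    het <- cj == "AB"
    if (any(het)) out[het, j] <- .het_code(a[het], b[het])
  }
  df <- data.frame(marker = mk$marker,
                   source = if ("source" %in% names(mk)) mk$source else "synthetic",
                   dbsnp = if ("dbsnp" %in% names(mk)) mk$dbsnp else NA_character_,
                   out, check.names = FALSE)
  names(df)[-(1:3)] <- matrix$samples
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(gc_path) && !is.null(matrix$gc)) {
    gdf <- data.frame(marker = mk$marker, matrix$gc, check.names = FALSE)
    names(gdf)[-1] <- matrix$samples
    utils::write.csv(gdf, gc_path, row.names = FALSE, quote = FALSE, na = "")
  }
  invisible(path)
}

#' Read a genotype matrix from the IUPAC CSV dialect
#'
#' Homozygote base letters are mapped to `AA`/`BB` with `allele_a` taken as
#' the alphabetically first allele observed at the marker; heterozygous IUPAC
#' ambiguity letters map to `AB`; the token `Failed` maps to `FAILED`.
#' Ragged rows and unknown cell tokens are rejected with the offending
#' row/column named. Note the format does not record the allele pair
#' explicitly, so a marker monomorphic across the written samples decodes as
#' all-`AA`: round trips are exact only up to allele labelling for such
#' markers.
#'
#' @param path CSV path in the dialect written by [write_genotypes()].
#' @param gc_path optional companion GC-score CSV.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, gc_path = NULL) {
  fields <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(fields)) > 1) {
    stop("ragged CSV: rows with differing field counts (first at line ",
         which(fields != fields[1])[1], ")", call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 4) stop("genotype table needs marker, source, dbsnp and at ",
                         "least one sample column", call. = FALSE)
  samples <- names(df)[-(1:3)]
  raw <- as.matrix(df[, -(1:3), drop = FALSE])
  valid <- c("A", "C", "G", "T", names(IUPAC_HET), "Failed")
  bad <- which(matrix(!(raw %in% valid), nrow(raw)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("unknown genotype token '%s' at marker %s, sample %s",
                 raw[bad[1, 1], bad[1, 2]], df[[1]][bad[1, 1]],
                 samples[bad[1, 2]]), call. = FALSE)
  }
  n <- nrow(raw)
  calls <- matrix("FAILED", n, ncol(raw))
  allele_a <- rep(NA_character_, n)
  allele_b <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    row <- raw[i, ]
    hets <- row[row %in% names(IUPAC_HET)]
    homs <- unique(row[row %in% c("A", "C", "G", "T")])
    alleles <- sort(unique(c(homs, unlist(strsplit(IUPAC_HET[unique(hets)], "")))))
    if (length(alleles) > 2) {
      stop("more than two alleles at marker ", df[[1]][i], call. = FALSE)
    }
    if (length(alleles) >= 1) allele_a[i] <- alleles[1]
    if (length(alleles) == 2) allele_b[i] <- alleles[2]
    calls[i, row == allele_a[i]] <- "AA"
    if (!is.na(allele_b[i])) {
      calls[i, row == allele_b[i]] <- "BB"
      calls[i, row == .het_code(allele_a[i], allele_b[i])] <- "AB"
    }
  }
  gc <- NULL
  if (!is.null(gc_path)) {
    gdf <- utils::read.csv(gc_path, check.names = FALSE)
    stopifnot(identical(gdf[[1]], df[[1]]))
    gc <- as.matrix(gdf[, -1, drop = FALSE])
    storage.mode(gc) <- "double"
  }
  geno_matrix(calls,
              markers = data.frame(marker = df[[1]], source = df[[2]],
                                   dbsnp = df[[3]], allele_a = allele_a,
                                   allele_b = allele_b),
              samples = samples, gc = gc)
}

MAP_STATUS <- c("frame", "placed", "-")

#' Read / write genetic map tables
#'
#' The map-table dialect has one row per marker with its mapping status
#' (`frame` for framework markers, `placed` for bin-placed markers, `-` for
#' unmapped; the typographic minus of the published tables is also accepted
#' on read), the genetic chromosome, intermating-corrected cM, uncorrected
#' pseudo-cM, and the physical chromosome/coordinate when known.
#'
#' @param map data.frame with columns `marker`, `status`, `chrom`, `cM`,
#'   `pseudo_cM`, `phys_chrom`, `phys_bp`.
#' @param path file path.
#' @return `read_map_table` returns the validated data.frame;
#'   `write_map_table` returns `path` invisibly.
#' @export
write_map_table <- function(map, path) {
  req <- c("marker", "status", "chrom", "cM", "pseudo_cM", "phys_chrom", "phys_bp")
  stopifnot(all(req %in% names(map)))
  .validate_map_table(map)
  utils::write.csv(map[, req], path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_map_table
#' @export
read_map_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(marker = "character",
                                       status = "character",
                                       chrom = "character",
                                       phys_chrom = "character"))
  df$status[df$status == "−"] <- "-"
  df$chrom[df$chrom == ""] <- NA_character_
  df$phys_chrom[df$phys_chrom == ""] <- NA_character_
  .validate_map_table(df)
  df
}

.validate_map_table <- function(df) {
  bad <- !(df$status %in% MAP_STATUS)
  if (any(bad)) {
    stop("unknown map status token '", df$status[bad][1], "' at marker ",
         df$marker[bad][1], call. = FALSE)
  }
  unmapped <- df$status == "-"
  if (any(unmapped & !is.na(df$cM))) {
    stop("unmapped marker ", df$marker[unmapped & !is.na(df$cM)][1],
         " carries a cM coordinate", call. = FALSE)
  }
  if (any(!is.na(df$cM) & df$cM < 0)) {
    stop("negative cM coordinate at marker ",
         df$marker[!is.na(df$cM) & df$cM < 0][1], call. = FALSE)
  }
  invisible(df)
}

#' Read / write physical placement tables
#'
#' One row per marker with its assembly chromosome and bp coordinate;
#' unplaced markers have an empty chromosome.
#'
#' @param placement data.frame with columns `marker`, `chrom`, `bp`.
#' @param path file path.
#' @return `read_placement` returns the validated data.frame.
#' @export
write_placement <- function(placement, path) {
  stopifnot(all(c("marker", "chrom", "bp") %in% names(placement)))
  utils::write.csv(placement[, c("marker", "chrom", "bp")], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_placement
#' @export
read_placement <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(marker = "character",
                                       chrom = "character"))
  df$chrom[df$chrom %in% c("", "unplaced")] <- NA_character_
  if (anyDuplicated(df$marker)) {
    stop("duplicated marker in placement table: ",
         df$marker[duplicated(df$marker)][1], call. = FALSE)
  }
  if (any(!is.na(df$bp) & df$bp < 1)) {
    stop("bp coordinates must be >= 1", call. = FALSE)
  }
  df
}
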