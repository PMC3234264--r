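# Genetic-map versus assembly comparison.

# A mapped "population" built directly from truth plus small coordinate
# noise: adequate for the synteny operations, which consume map tables.
truth_map_table <- function(genome, cm_noise = 0, seed = 1, frame_every = 1) {
  mk <- genome$markers
  set.seed(seed)
  cm <- mk$cM + rnorm(nrow(mk), 0, cm_noise)
  chrom_map <- setNames(paste0("LG", seq_along(unique(mk$chrom))),
                        unique(mk$chrom))
  data.frame(marker = mk$marker,
             status = ifelse(seq_len(nrow(mk)) %% frame_every == 0,
                             "frame", "placed"),
             chrom = unname(chrom_map[mk$chrom]),
             cM = pmax(cm, 0), pseudo_cM = pmax(cm, 0) * 2,
             phys_chrom = NA_character_, phys_bp = NA_real_)
}

test_that("concordance counts planted translocations exactly", {
  g <- make_genome(3, 40, seed = 91)
  placement <- data.frame(marker = g$markers$marker, chrom = g$markers$chrom,
                          bp = g$markers$bp)
  mt <- truth_map_table(g)
  conc0 <- concordance(mt, placement)
  expect_equal(conc0$n_discordant, 0)
  expect_true(all(conc0$records$concordant[!is.na(conc0$records$concordant)]))

  mk3 <- g$markers[g$markers$chrom == "chr3", ]
  pm <- plant_misassembly(placement, list(
    list(type = "translocation", chrom = "chr3", start = mk3$bp[10],
         end = mk3$bp[16], to = "chr1", at = 150e6)), seed = 1)
  conc <- concordance(mt, pm$placement)
  expect_equal(conc$n_discordant, 7)
  disc <- conc$records$marker[!is.na(conc$records$concordant) &
                                !conc$records$concordant]
  expect_setequal(disc, mk3$marker[10:16])
})

test_that("non-syntenic markers cluster by physical proximity", {
  g <- make_genome(2, 40, seed = 92)
  placement <- data.frame(marker = g$markers$marker, chrom = g$markers$chrom,
                          bp = g$markers$bp)
  mt <- truth_map_table(g)
  mk2 <- g$markers[g$markers$chrom == "chr2", ]
  pm <- plant_misassembly(placement, list(
    list(type = "translocation", chrom = "chr2", start = mk2$bp[5],
         end = mk2$bp[11], to = "chr1", at = 120e6)), seed = 1)
  cl <- cluster_nonsyntenic(concordance(mt, pm$placement))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_markers, 7)
  expect_equal(cl$kind, "cluster")

  # two distant discordant markers stay singletons
  pm2 <- placement
  far <- match(c(mk2$marker[2], mk2$marker[38]), pm2$marker)
  pm2$chrom[far] <- "chr1"
  cl2 <- cluster_nonsyntenic(concordance(mt, pm2))
  expect_equal(nrow(cl2), 2)
  expect_true(all(cl2$kind == "singleton"))
})

test_that("planted inversions become named regions; colinear maps give none", {
  g <- make_genome(2, 60, seed = 93)
  placement <- data.frame(marker = g$markers$marker, chrom = g$markers$chrom,
                          bp = g$markers$bp)
  mt <- truth_map_table(g, cm_noise = 0.3, seed = 3)
  expect_equal(nrow(call_regions(mt, placement, suffix = "I")), 0)

  mk1 <- g$markers[g$markers$chrom == "chr1", ]
  pm <- plant_misassembly(placement, list(
    list(type = "inversion", chrom = "chr1", start = mk1$bp[20],
         end = mk1$bp[29])), seed = 1)
  regI <- call_regions(mt, pm$placement, suffix = "I")
  expect_equal(nrow(regI), 1)
  expect_match(regI$name, "^1\\.1I$")
  expect_gte(regI$start, mk1$bp[19])
  expect_lte(regI$end, mk1$bp[30])

  # the other population sees the same assembly defect: cross-support
  mtL <- truth_map_table(g, cm_noise = 0.3, seed = 4)
  regL <- call_regions(mtL, pm$placement, other_regions = regI, suffix = "L")
  expect_equal(nrow(regL), 1)
  expect_match(regL$name, "L$")
  expect_equal(regL$support, "both")
})

test_that("single-marker displacements need cross-population support", {
  g <- make_genome(1, 60, seed = 94)
  placement <- data.frame(marker = g$markers$marker, chrom = g$markers$chrom,
                          bp = g$markers$bp)
  mt <- truth_map_table(g)
  # displace one marker far away physically
  pm <- placement
  pm$bp[30] <- pm$bp[30] + 60e6
  pm <- pm[order(pm$chrom, pm$bp), ]
  reg_alone <- call_regions(mt, pm, suffix = "I")
  expect_equal(nrow(reg_alone), 0)
  other <- data.frame(name = "1.1L", phys_chrom = "chr1",
                      start = pm$bp[match(g$markers$marker[30], pm$marker)] - 1e6,
                      end = pm$bp[match(g$markers$marker[30], pm$marker)] + 1e6,
                      n_markers = 3, support = "one", markers = "x")
  reg_backed <- call_regions(mt, pm, other_regions = other, suffix = "I")
  expect_equal(nrow(reg_backed), 1)
  expect_equal(reg_backed$support, "both")
})

test_that("region calling is population-symmetric and scale-invariant", {
  g <- make_genome(2, 60, seed = 95)
  placement <- data.frame(marker = g$markers$marker, chrom = g$markers$chrom,
                          bp = g$markers$bp)
  mk2 <- g$markers[g$markers$chrom == "chr2", ]
  pm <- plant_misassembly(placement, list(
    list(type = "inversion", chrom = "chr2", start = mk2$bp[10],
         end = mk2$bp[21])), seed = 1)
  mt <- truth_map_table(g, cm_noise = 0.2, seed = 6)
  base <- call_regions(mt, pm$placement, suffix = "I")
  scaled <- mt; scaled$cM <- scaled$cM * 3.7
  resc <- call_regions(scaled, pm$placement, suffix = "I")
  expect_equal(base$markers, resc$markers)
  expect_equal(base$start, resc$start)
})

test_that("landscape is monotone, calibrated and error-checked", {
  mt <- data.frame(marker = sprintf("m%03d", 1:100), status = "frame",
                   chrom = "LG1", cM = seq(0, 99, 1),
                   pseudo_cM = seq(0, 198, 2), phys_chrom = "chr1",
                   phys_bp = seq(1e6, 100e6, 1e6))
  ls <- landscape(mt, chrom = "chr1")
  expect_true(all(diff(ls$cM) >= 0))
  expect_true(all(ls$rate >= 0))
  # x cM = x Mbp: the rate is 1 everywhere
  expect_lt(max(abs(ls$rate - 1)), 0.05)
  # the rate integrates back to the genetic length within 1%
  integral <- sum(ls$rate[-1] * diff(ls$bp) / 1e6)
  expect_lt(abs(integral - attr(ls, "genetic_span_cM")) /
              attr(ls, "genetic_span_cM"), 0.01)

  # centromere-suppressed middle third stays below 0.1 cM/Mbp
  cm <- c(seq(0, 50, length.out = 34), rep(50, 33),
          seq(50, 100, length.out = 33)) + seq(0, 0.001, length.out = 100)
  mt2 <- mt; mt2$cM <- cm
  ls2 <- landscape(mt2, chrom = "chr1")
  mid <- ls2$bp > 40e6 & ls2$bp < 62e6
  expect_lt(max(ls2$rate[mid]), 0.1)

  expect_error(landscape(mt[1:10, ], chrom = "chr1"), "fewer than")
})

test_that("physical positions are predicted by anchor interpolation", {
  mt <- data.frame(marker = c("a", "mid", "b", "far"),
                   status = c("frame", "placed", "frame", "placed"),
                   chrom = "LG1",
                   cM = c(0, 5, 10, 20), pseudo_cM = c(0, 10, 20, 40),
                   phys_chrom = NA_character_, phys_bp = NA_real_)
  placement <- data.frame(marker = c("a", "b", "other"),
                          chrom = c("chr1", "chr1", "chr1"),
                          bp = c(10e6, 20e6, 60e6))
  pred <- predict_physical(c("mid", "a", "far"), mt, placement)
  expect_equal(pred$pred_bp[1], 15e6)       # genetic midpoint -> 15 Mb
  expect_equal(pred$pred_bp[2], 10e6)       # coincident with an anchor
  expect_equal(pred$pred_chrom[1], "chr1")
  # extrapolation beyond the last anchor is clamped to chromosome bounds
  expect_lte(pred$pred_bp[3], 60e6)
  expect_gt(pred$pred_bp[3], 20e6)
})

test_that("prediction error for deleted markers stays within anchor spacing", {
  g <- make_genome(1, 60, seed = 96)
  placement <- data.frame(marker = g$markers$marker, chrom = g$markers$chrom,
                          bp = g$markers$bp)
  mt <- truth_map_table(g, cm_noise = 0.2, seed = 8)
  drop_idx <- seq(5, 55, by = 10)
  dropped <- g$markers$marker[drop_idx]
  pl_del <- placement[!placement$marker %in% dropped, ]
  pred <- predict_physical(dropped, mt, pl_del)
  err <- abs(pred$pred_bp - g$markers$bp[drop_idx])
  spacing <- mean(diff(pl_del$bp))
  expect_lt(stats::median(err), spacing / 2)
})

test_that("polymorphism deserts require emptiness in one population only", {
  g <- make_genome(1, 100, seed = 97)
  placement <- data.frame(marker = g$markers$marker, chrom = g$markers$chrom,
                          bp = g$markers$bp)
  all_m <- g$markers$marker
  expect_equal(nrow(deserts(placement, all_m, all_m)), 0)
  # a 15 Mbp identical-by-descent block: markers 40..47 monomorphic in 'self'
  gap_span <- (placement$bp[48] - placement$bp[39]) / 1e6
  self_poly <- all_m[-(40:47)]
  de <- deserts(placement, self_poly, all_m, min_span_Mbp = gap_span * 0.9)
  expect_equal(nrow(de), 1)
  expect_gte(de$n_other, 5)
  expect_equal(nrow(deserts(placement, self_poly, all_m,
                            min_span_Mbp = 1e4)), 0)  # span > chromosome
})
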