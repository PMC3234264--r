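# The IRIL meiosis simulator and its corruption layers.

test_that("coincident markers never recombine and runs are deterministic", {
  g <- two_marker_genome(1e-9)
  des <- population_design(n_lines = 500, t_intermating = 4, n_selfing = 6,
                           rng_seed = 11)
  sim <- simulate_iril_population(g, des)
  expect_equal(observed_R(sim)$R, 0)
  sim2 <- simulate_iril_population(g, des)
  expect_identical(sim$genotypes$calls, sim2$genotypes$calls)
  expect_identical(sim$truth$crossovers, sim2$truth$crossovers)
})

test_that("two-locus recombinant fractions match the closed form", {
  # Monte-Carlo check at desk scale; the acceptance suite re-runs the full
  # 100,000-line grid of r and t values.
  for (case in list(c(r = 0.05, t = 0), c(r = 0.2, t = 2))) {
    r <- case[["r"]]; t <- case[["t"]]
    g <- two_marker_genome(haldane_d(r))
    des <- population_design(n_lines = 20000, t_intermating = t,
                             n_selfing = 10, rng_seed = 101 + t)
    obs <- observed_R(simulate_iril_population(g, des))
    Rexp <- iril_R(r, t)
    se <- sqrt(Rexp * (1 - Rexp) / obs$n)
    expect_lt(abs(obs$R - Rexp), 3 * se)
  }
})

test_that("residual heterozygosity decays as (1/2)^(n_selfing + 1)", {
  # The F2 (and any random-mating generation) is heterozygous at a locus
  # with probability 1/2; each selfing generation halves it.
  g <- make_genome(1, 40, seed = 3)
  des <- population_design(n_lines = 2000, t_intermating = 2, n_selfing = 5,
                           rng_seed = 17)
  sim <- simulate_iril_population(g, des)
  het <- mean(sim$genotypes$calls == "AB")
  p <- 0.5^(des$n_selfing + 1)
  se <- sqrt(p * (1 - p) / length(sim$genotypes$calls))
  # linked loci within a line are correlated; allow a generous multiple
  expect_lt(abs(het - p), 10 * se)
})

test_that("designs and genomes are validated", {
  expect_error(population_design(n_lines = 1), ">= 2")
  expect_error(population_design(t_intermating = -1), "non-negative")
  g0 <- genome_model(data.frame(chrom = "c1", len_cM = 0, len_Mbp = 1),
                     data.frame(marker = character(), chrom = character(),
                                cM = numeric(), bp = numeric()))
  expect_error(simulate_iril_population(g0, population_design(10)),
               "zero-length")
  expect_error(
    genome_model(data.frame(chrom = "c1", len_cM = 10, len_Mbp = 1),
                 data.frame(marker = c("a", "b"), chrom = "c1",
                            cM = c(5, 2), bp = c(1, 2))),
    "strictly increasing")
})

test_that("corrupt_genotypes honours its rate contract", {
  g <- make_genome(2, 50, seed = 5)
  sim <- simulate_iril_population(g, population_design(274, 0, 6, rng_seed = 7))
  clean <- sim$genotypes

  noiseless <- corrupt_genotypes(clean, noise_model(0, 0), seed = 1)
  expect_identical(noiseless$calls, clean$calls)

  all_missing <- corrupt_genotypes(clean, noise_model(0, 1), seed = 1)
  expect_true(all(all_missing$calls == "FAILED"))

  # missing fraction within 3 binomial SE (grid scaled down from the full
  # array dimensions; the SE shrinks with the cell count, not the shape)
  g2 <- make_genome(1, 5000, seed = 6)
  sim2 <- simulate_iril_population(g2, population_design(274, 0, 6, rng_seed = 8))
  noisy <- corrupt_genotypes(sim2$genotypes, noise_model(0, 0.04), seed = 2)
  ncell <- length(noisy$calls)
  se <- sqrt(0.04 * 0.96 / ncell)
  expect_lt(abs(mean(noisy$calls == "FAILED") - 0.04), 3 * se)

  # input object untouched, determinism, GC scores separate flips from
  # clean calls
  expect_false(any(clean$calls == "FAILED"))
  noisy_b <- corrupt_genotypes(sim2$genotypes, noise_model(0, 0.04), seed = 2)
  expect_identical(noisy$calls, noisy_b$calls)
  expect_error(noise_model(call_error_rate = 1.5), "probability")
})

test_that("injected call errors carry low GC scores", {
  g <- make_genome(1, 2000, seed = 9)
  sim <- simulate_iril_population(g, population_design(200, 0, 8, rng_seed = 10))
  noisy <- corrupt_genotypes(sim$genotypes, noise_model(0.05, 0), seed = 3)
  flipped <- attr(noisy, "flipped")
  expect_gt(mean(noisy$gc[!flipped & noisy$calls != "FAILED"]), 0.85)
  expect_lt(mean(noisy$gc[flipped]), 0.5)
  # the GC 0.8 framework threshold removes nearly all flips
  expect_lt(mean(noisy$gc[flipped] >= 0.8), 0.05)
})

test_that("make_triplets follows Mendelian expectations", {
  expect_equal(make_triplets("AA", "BB"), "AB")
  expect_equal(make_triplets("AA", "AA"), "AA")
  expect_equal(make_triplets("BB", "BB"), "BB")
  expect_equal(make_triplets("FAILED", "AA"), "FAILED")
  expect_error(make_triplets(c("AA", "AA"), "AA"), "equal length")
  expect_error(make_triplets("AB", "AA"), "homozygous")

  p1 <- rep(c("AA", "BB"), 5000)
  p2 <- rep(c("BB", "BB"), 5000)
  f1 <- make_triplets(p1, p2, error_rate = 0)
  expect_equal(triplet_consistency(p1, p2, f1)$n_inconsistent, 0)

  f1e <- make_triplets(p1, p2, error_rate = 0.005, seed = 21)
  rate <- triplet_consistency(p1, p2, f1e)$rate
  se <- sqrt(0.005 * 0.995 / length(p1))
  expect_lt(abs(rate - 0.005), 3 * se)
})

test_that("plant_misassembly applies and logs edits correctly", {
  g <- make_genome(2, 30, seed = 4)
  placement <- data.frame(marker = g$markers$marker, chrom = g$markers$chrom,
                          bp = g$markers$bp)
  # identity
  un <- plant_misassembly(placement, list())
  expect_identical(un$placement, placement)

  mk1 <- g$markers[g$markers$chrom == "chr1", ]
  inv <- list(type = "inversion", chrom = "chr1",
              start = mk1$bp[5], end = mk1$bp[14])
  tr <- list(type = "translocation", chrom = "chr2",
             start = g$markers$bp[g$markers$chrom == "chr2"][3],
             end = g$markers$bp[g$markers$chrom == "chr2"][9],
             to = "chr1", at = 190e6)
  del <- list(type = "deletion", chrom = "chr1",
              start = mk1$bp[25], end = mk1$bp[27])
  pm <- plant_misassembly(placement, list(inv, tr, del), seed = 2)

  # translocated markers report the target chromosome
  tr_markers <- g$markers$marker[g$markers$chrom == "chr2"][3:9]
  expect_true(all(pm$placement$chrom[pm$placement$marker %in% tr_markers] == "chr1"))
  # internal order preserved
  tr_bp <- pm$placement$bp[match(tr_markers, pm$placement$marker)]
  expect_true(all(diff(tr_bp) > 0))
  # inversion reverses bp ranks inside the span, leaves the rest alone
  inv_markers <- mk1$marker[5:14]
  new_bp <- pm$placement$bp[match(inv_markers, pm$placement$marker)]
  expect_true(all(diff(new_bp) < 0))
  # deletions remove markers
  expect_false(any(mk1$marker[25:27] %in% pm$placement$marker))
  expect_equal(nrow(pm$log), 3)

  overlapping <- list(
    list(type = "inversion", chrom = "chr1", start = 1e6, end = 9e6),
    list(type = "deletion", chrom = "chr1", start = 5e6, end = 12e6))
  expect_error(plant_misassembly(placement, overlapping), "overlapping")
})
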