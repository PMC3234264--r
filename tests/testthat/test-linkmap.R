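# Marker filtering, two-point estimation, grouping, ordering engine and
# multipoint distances.

test_that("filter_markers applies the published rules", {
  calls <- rbind(m1 = c("AA", "BB", "AA", "BB", "AA", "BB", "AA", "BB", "AA", "BB"),
                 m2 = c("AA", "BB", "AA", "BB", "AA", "BB", "AA", "BB", "AA", "BB"),
                 m3 = c("AA", "AB", "AA", "BB", "AA", "BB", "AA", "BB", "AA", "BB"),
                 m4 = c("AA", rep("FAILED", 4), "BB", "AA", "BB", "AA", "BB"),
                 m5 = c("AA", "AA", "AA", "AA", "AA", "AA", "AA", "AA", "AA", "BB"))
  gm <- geno_matrix(calls)
  parents <- list(p1 = c("AA", "AA", "AA", "AA", "AA"),
                  p2 = c("BB", "AA", "BB", "BB", "BB"))
  fw <- filter_markers(gm, parents, filter_config("framework"))
  d <- fw$diagnostics
  expect_equal(d$status[d$marker == "m2"], "parents")  # monomorphic parents
  expect_equal(d$status[d$marker == "m4"], "missing")  # 40% missing
  expect_equal(d$status[d$marker == "m5"], "maf")      # MAF 0.10, not > 0.10
  expect_equal(d$status[d$marker == "m1"], "retained")
  # heterozygous calls became missing, not genotypes
  expect_false(any(fw$matrix$calls == "AB"))
  # 40% missing passes the complete stage
  cm <- filter_markers(gm, parents, filter_config("complete"))
  expect_equal(cm$diagnostics$status[cm$diagnostics$marker == "m4"],
               "retained")
  expect_error(filter_markers(gm, NULL), "parent")
})

test_that("GC scores below the stage threshold become missing", {
  calls <- matrix(rep(c("AA", "BB"), 50), nrow = 2, byrow = TRUE)
  calls <- rbind(calls, calls)  # 4 markers x 50 lines, alternating
  gc <- matrix(1, 4, 50)
  gc[1, 1:30] <- 0.7           # below 0.8, above 0.6
  gm <- geno_matrix(calls, gc = gc)
  parents <- list(p1 = rep("AA", 4), p2 = rep("BB", 4))
  fw <- filter_markers(gm, parents, filter_config("framework"))
  expect_equal(fw$diagnostics$status[1], "missing")  # 60% of calls removed
  cm <- filter_markers(gm, parents, filter_config("complete"))
  expect_equal(cm$diagnostics$status[1], "retained")
})

test_that("parent-origin recoding flips markers where parent 1 carries BB", {
  calls <- rbind(m1 = c("AA", "BB", "AA", "BB"))
  gm <- geno_matrix(calls)
  out <- filter_markers(gm, list(p1 = "BB", p2 = "AA"),
                        filter_config("complete", maf_min = 0))
  expect_equal(unname(out$matrix$calls[1, ]), c("BB", "AA", "BB", "AA"))
})

test_that("two-point estimates match count ratios and LOD identities", {
  g1 <- rep(c("AA", "BB"), 20)
  est <- estimate_R(g1, g1)
  expect_equal(est$R, 0)
  expect_equal(est$lod, 40 * log10(2))
  g2 <- g1; g2[1:4] <- ifelse(g1[1:4] == "AA", "BB", "AA")
  expect_equal(estimate_R(g1, g2)$R, 0.1)
  expect_error(estimate_R(g1, g1[-1]), "length mismatch")
  short <- estimate_R(c("AA", "BB", "AA"), c("AA", "BB", "AA"))
  expect_false(short$reliable)
  # independent markers in a simulated population: R-hat near 0.5, LOD ~ 0
  set.seed(5)
  a <- sample(c("AA", "BB"), 239, TRUE)
  b <- sample(c("AA", "BB"), 239, TRUE)
  est2 <- estimate_R(a, b)
  expect_lt(abs(min(est2$R, 0.5) - 0.5), 3 * sqrt(0.25 / 239) + 1e-9)
  expect_lt(est2$lod, 2)
})

test_that("linkage grouping separates chromosomes and honours thresholds", {
  g <- make_genome(2, 30, len_cM = 120, seed = 41)
  sim <- simulate_iril_population(g, population_design(200, 2, 8, rng_seed = 42))
  tp <- twopoint_matrix(sim$genotypes$calls)
  gr <- group_markers(tp)
  expect_equal(length(gr$groups), 2)
  truth <- g$markers$chrom[match(names(gr$assignment), g$markers$marker)]
  expect_equal(length(unique(paste(truth, gr$assignment))), 2)

  # unlinked markers fall into singleton groups
  set.seed(7)
  rnd <- matrix(sample(c("AA", "BB"), 8 * 300, TRUE), 8,
                dimnames = list(paste0("u", 1:8), NULL))
  gr2 <- group_markers(twopoint_matrix(rnd))
  expect_equal(length(gr2$groups), 8)
  # zero thresholds collapse everything into one group
  gr3 <- group_markers(twopoint_matrix(rnd), lod_threshold = 0,
                       r_threshold = 0.5)
  expect_equal(length(gr3$groups), 1)
})

test_that("multipoint EM recovers distances and marginalizes missing data", {
  # frozen oracle: 10 discordant of 40 -> R = 0.25 -> r = R/(2(1-R)) = 1/6,
  # d = -50 log(1 - 1/3) = 20.273 cM at t = 0
  a <- rep(c("AA", "BB"), 20)
  b <- a; b[1:10] <- ifelse(a[1:10] == "AA", "BB", "AA")
  d <- multipoint_distances(rbind(a = a, b = b), t = 0)
  expect_equal(d$R[1], 0.25, tolerance = 1e-4)
  expect_equal(d$d_cM[1], -50 * log(1 - 2 / 6), tolerance = 1e-3)
  # pseudo-cM equals cM at t = 0
  expect_equal(d$d_cM, d$d_pseudo_cM)

  # zero recombination: all intervals collapse to ~0
  z <- multipoint_distances(rbind(a = a, b = a, c = a), t = 4)
  expect_lt(max(z$d_cM), 1e-3)

  # missing flanks are marginalized: inserting an all-missing middle marker
  # splits but preserves the total map length
  m_all_na <- rep("FAILED", 40)
  d3 <- multipoint_distances(rbind(a = a, x = m_all_na, b = b), t = 0)
  expect_equal(sum(d3$d_cM), d$d_cM[1], tolerance = 0.1)
})

test_that("true order outscores permuted orders in multipoint likelihood", {
  g <- make_genome(1, 12, len_cM = 110, seed = 51)
  sim <- simulate_iril_population(g, population_design(239, 4, 8, rng_seed = 52))
  calls <- sim$genotypes$calls
  ll_true <- multipoint_distances(calls, t = 4)$loglik
  swap <- c(12, 2:11, 1)  # exchange the chromosome ends
  ll_swap <- multipoint_distances(calls[swap, ], t = 4)$loglik
  expect_gt(ll_true, ll_swap + 10)
})

test_that("scaffolds are sparse, correctly ordered and spaced", {
  g <- make_genome(1, 100, len_cM = 200, len_Mbp = 200, seed = 31)
  sim <- simulate_iril_population(g, population_design(239, 4, 8, rng_seed = 13))
  calls <- sim$genotypes$calls
  sc <- build_scaffold(calls, t = 4)
  expect_gt(length(sc$order), 10)
  expect_equal(order_tau(sc$order, g), 1)
  dist <- multipoint_distances(calls[sc$order, ], t = 4)
  expect_true(all(dist$d_cM >= 9))  # 10 cM target, estimation noise allowed

  # two interchangeable co-segregating markers: at most one admitted
  calls2 <- rbind(calls, dup = calls[50, ])
  sc2 <- build_scaffold(calls2, t = 4)
  expect_lt(sum(c(rownames(calls)[50], "dup") %in% sc2$order), 2)
  expect_error(build_scaffold(calls[1:2, ], t = 4), "3 markers")
})

test_that("framework extension keeps robust insertions only", {
  g <- make_genome(1, 60, len_cM = 170, seed = 61)
  sim <- simulate_iril_population(g, population_design(239, 4, 8, rng_seed = 62))
  calls <- sim$genotypes$calls
  sc <- build_scaffold(calls, t = 4)
  fw <- extend_framework(sc$order, calls, t = 4)
  expect_true(all(sc$order %in% fw$order))          # framework contains scaffold
  expect_gte(order_tau(fw$order, g), 0.995)
  # a marker identical to a framework marker has zero margin -> rejected
  calls3 <- rbind(calls, dup = calls[fw$order[5], ])
  fw2 <- extend_framework(sc$order, calls3, t = 4)
  expect_false(all(c("dup", fw$order[5]) %in% fw2$order))
})

test_that("bin placement is self-consistent and rejects empty candidates", {
  g <- make_genome(1, 60, len_cM = 170, seed = 71)
  sim <- simulate_iril_population(g, population_design(239, 4, 8, rng_seed = 72))
  calls <- sim$genotypes$calls
  sc <- build_scaffold(calls, t = 4)
  fw <- extend_framework(sc$order, calls, t = 4)
  dist <- multipoint_distances(calls[fw$order, ], t = 4)
  # a framework marker re-submitted lands at its own position
  probe <- fw$order[10]
  res <- place_bins(fw$order, calls, calls[probe, , drop = FALSE], t = 4,
                    dist = dist)
  expect_true(res$placed)
  own_pos <- dist$pos_cM[10]
  expect_lt(abs(res$cM - own_pos), 1)
  # all-missing candidates stay unmapped
  nocall <- matrix("FAILED", 1, ncol(calls), dimnames = list("void", NULL))
  res2 <- place_bins(fw$order, calls, nocall, t = 4, dist = dist)
  expect_false(res2$placed)
})

test_that("end-to-end build_maps recovers a small two-chromosome design", {
  g <- make_genome(2, 50, len_cM = 150, seed = 81)
  sim <- simulate_iril_population(g, population_design(239, 4, 6, rng_seed = 82))
  noisy <- corrupt_genotypes(sim$genotypes, noise_model(), seed = 83)
  map <- build_maps(noisy, sim_parents(noisy), t = 4)
  expect_equal(length(map$chromosomes), 2)
  lens <- map_lengths(map)
  expect_lt(abs(lens["cM"] - 300) / 300, 0.10)
  expect_gt(lens["pseudo_cM"], lens["cM"])
  for (ch in map$chromosomes) {
    fwm <- ch$marker[ch$tier != "placed"]
    expect_gte(order_tau(fwm, g), 0.995)
    expect_true(all(diff(ch$cM) >= 0))  # coordinates non-decreasing
  }
  # map table flattening keeps tier semantics
  mt <- as_map_table(map, all_markers = rownames(noisy$calls))
  expect_true(all(mt$status %in% c("frame", "placed", "-")))
  expect_equal(sort(unique(mt$status[!is.na(mt$cM)])),
               sort(unique(c("frame", mt$status[mt$status == "placed"]))))
})
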