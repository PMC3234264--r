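# Shared fixtures, built in code (no data files).

# Two-marker genome at genetic distance d_cM.
two_marker_genome <- function(d_cM, len = max(50, d_cM + 1)) {
  genome_model(
    data.frame(chrom = "c1", len_cM = len, len_Mbp = 50),
    data.frame(marker = c("a", "b"), chrom = "c1",
               cM = c(0, d_cM), bp = c(1, 2e6))
  )
}

# IBM-like default parent vectors for a simulated matrix (AA x BB everywhere).
sim_parents <- function(gm) {
  list(p1 = rep("AA", nrow(gm$calls)), p2 = rep("BB", nrow(gm$calls)))
}

# Observed line-level recombinant fraction between the two markers of a
# simulated two-marker population (heterozygous lines excluded).
observed_R <- function(sim) {
  cl <- sim$genotypes$calls
  both <- cl[1, ] != "AB" & cl[2, ] != "AB"
  list(R = mean(cl[1, both] != cl[2, both]), n = sum(both))
}

# Kendall tau of a mapped order against true cM positions (orientation-free).
order_tau <- function(markers_in_order, genome) {
  tru <- genome$markers$cM[match(markers_in_order, genome$markers$marker)]
  abs(stats::cor(seq_along(tru), tru, method = "kendall"))
}
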