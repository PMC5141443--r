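# The Fm/Fn excess statistic, its Fisher and Monte Carlo tests, CpG
# masking, spectrum summary and Bonferroni correction.

test_that("enrichment counts equal a hand count on a printed toy", {
  # Four 8 nt windows, WRC/GYW. Mutable flags per window (hand-derived):
  #   "AATACGTT" center 4 (A): TAC at 3-5 flags pos 5 (C); GYW: ACG?
  #     expand(GYW) = {GCA,GCT,GTA,GTT}; ACG..: CGT at? scan: AATACGTT
  #     GTT at 6-8 flags pos 6 (G). flags = {5, 6}; center 4 not in motif.
  #   "AATACGTT" center 5 (C): same flags {5, 6}; center IS in motif.
  #   "AAAAACGT" center 6 (C): AAC at 4-6 flags 6; GYW hits: CGT at 5?
  #     CGT not in {GCA,GCT,GTA,GTT}; ACG no; GT. at 7-8 too short.
  #     flags = {6}; center in motif.
  #   "TTTTTTTT" center 4 (T): no WRC/GYW occurrence; flags = {}.
  wrc <- motif_catalog()$WRC
  muts <- mutations_from_windows(
    c("AATACGTT", "AATACGTT", "AAAAACGT", "TTTTTTTT"),
    c(4L, 5L, 6L, 4L))
  r <- compute_enrichment(muts, wrc, mc_reps = 0)
  expect_equal(r$n_mutations, 4L)
  expect_equal(r$k_in_motif, 2L)          # windows 2 and 3
  expect_equal(r$Fm, 0.5)
  # un-mutated motif positions: w1 {5,6}=2, w2 {6}=1, w3 {6}\{6}=0 plus
  # nothing else = w3 flags {6} minus center 6 -> 0, w4 0 => 2+1+0+0 = 3
  expect_equal(r$motif_positions, 3L)
  expect_equal(r$total_positions, 4L * 7L)
  expect_equal(r$Fn, 3 / 28)
  expect_equal(r$excess, 0.5 / (3 / 28))
})

test_that("mutations on motif-free windows give Fm = 0 and excess 0", {
  wrc <- motif_catalog()$WRC
  muts <- mutations_from_windows(rep("ATATATATATA", 5), rep(6L, 5))
  # ATA windows contain WA positions but no WRC; give WA for nonzero Fn
  r <- compute_enrichment(muts, motif_catalog()$WA, mc_reps = 0)
  expect_gt(r$Fn, 0)
  r2 <- compute_enrichment(muts, wrc, mc_reps = 0)
  expect_equal(r2$k_in_motif, 0L)
  expect_false(r2$computable)  # no WRC positions at all -> Fn = 0
  # non-motif centers with motif elsewhere in the window: excess 0
  muts3 <- mutations_from_windows(c("TTTACTTT"), 7L)  # TAC at 3-5, C at 5
  r3 <- compute_enrichment(muts3, wrc, mc_reps = 0)
  expect_equal(r3$Fm, 0)
  expect_equal(r3$excess, 0)
})

test_that("excess arithmetic reproduces published-scale fractions", {
  expect_equal(round(enrichment_excess(0.265, 0.222), 2), 1.19)
  expect_equal(round(enrichment_excess(0.05, 0.224), 2), 0.22)
  expect_error(enrichment_excess(0.5, 0), "fn")
})

test_that("CpG masking removes every CG and matches physical removal", {
  sim <- small_sim(theta = c(CG = 4), n_mut = 150L, len = 30000L,
                   seed = 21)
  masked <- mask_cpg_neighborhoods(sim$mutations)
  expect_gt(masked$n_dropped, 0L)
  for (w in masked$mutations$neighborhood[1:20]) {
    expect_false(grepl("CG", w))
  }
  # WRC enrichment on masked data equals WRC enrichment on a dataset
  # with CpG-context mutations dropped and CpG positions excised (N)
  wrc <- motif_catalog()$WRC
  r_masked <- compute_enrichment(sim$mutations, wrc, mask_cpg = TRUE,
                                 mc_reps = 0)
  r_direct <- compute_enrichment(masked$mutations, wrc, mc_reps = 0)
  expect_equal(r_masked$k_in_motif, r_direct$k_in_motif)
  expect_equal(r_masked$motif_positions, r_direct$motif_positions)
  expect_equal(r_masked$total_positions, r_direct$total_positions)
  # all-CpG-centered dataset: everything masked away -> error path
  cpg_only <- mutations_from_windows(c("AACGAA", "TTCGTT"), c(3L, 3L))
  expect_error(compute_enrichment(cpg_only, wrc, mask_cpg = TRUE),
               "all mutations masked")
  expect_error(compute_enrichment(sim$mutations[0, ], wrc), "empty")
})

test_that("Fisher p agrees with the closed-form hypergeometric oracle", {
  set.seed(33)
  for (i in 1:20) {
    a <- rpois(1, 8); b <- rpois(1, 40)
    c <- rpois(1, 60); d <- rpois(1, 400)
    p_pkg <- stats::fisher.test(matrix(c(a, b, c, d), 2))$p.value
    expect_equal(p_pkg, fisher_two_sided_oracle(a, b, c, d),
                 tolerance = 1e-8,
                 label = paste("table", a, b, c, d))
  }
  # and the enrichment path feeds the same table
  sim <- small_sim(n_mut = 100L, len = 20000L, seed = 9)
  r <- compute_enrichment(sim$mutations, motif_catalog()$WRC,
                          mc_reps = 0)
  expect_equal(r$fisher_p,
               fisher_two_sided_oracle(
                 r$k_in_motif, r$n_mutations - r$k_in_motif,
                 r$motif_positions,
                 r$total_positions - r$motif_positions),
               tolerance = 1e-8)
})

test_that("the excess is invariant under reverse-complementing the data", {
  sim <- small_sim(theta = c(WRC = 2), n_mut = 120L, len = 25000L,
                   seed = 13)
  muts <- sim$mutations
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  flip <- muts
  flip$neighborhood <- vapply(muts$neighborhood, function(w) {
    paste0(rev(comp[strsplit(w, "")[[1]]]), collapse = "")
  }, "", USE.NAMES = FALSE)
  flip$center_index <- nchar(muts$neighborhood) - muts$center_index + 1L
  flip$ref <- unname(comp[muts$ref])
  flip$alt <- unname(comp[muts$alt])
  for (nm in c("WRC", "WRCG", "CG", "TCW")) {
    r1 <- compute_enrichment(muts, motif_catalog()[[nm]], mc_reps = 0)
    r2 <- compute_enrichment(flip, motif_catalog()[[nm]], mc_reps = 0)
    expect_equal(r1$k_in_motif, r2$k_in_motif, label = nm)
    expect_equal(r1$motif_positions, r2$motif_positions, label = nm)
    expect_equal(r1$excess, r2$excess, label = nm)
  }
})

test_that("Monte Carlo p attains its floor when every center is a hit", {
  # centers all at the WRC C; the windows' other C positions are not
  # motif positions, so every reassignment loses the hit
  w <- paste0(strrep("G", 10), "TAC", strrep("C", 10))
  muts <- mutations_from_windows(rep(w, 6), rep(13L, 6))
  r <- compute_enrichment(muts, motif_catalog()$WRC, mc_reps = 999,
                          seed = 4)
  expect_equal(r$mc_p, 1 / 1000)
  # reps = 0 disables the test
  r0 <- compute_enrichment(muts, motif_catalog()$WRC, mc_reps = 0)
  expect_true(is.na(r0$mc_p))
  # a mutation with no same-base candidate keeps its position (message)
  expect_message(
    monte_carlo_test(mutations_from_windows("GACGG", 2L),
                     motif_catalog()$WRC, reps = 9, seed = 1),
    "without same-base candidate")
})

test_that("Monte Carlo and Fisher p-values are seeded and reproducible", {
  sim <- small_sim(n_mut = 80L, len = 20000L, seed = 17)
  r1 <- compute_enrichment(sim$mutations, motif_catalog()$CG,
                           mc_reps = 99, seed = 42)
  r2 <- compute_enrichment(sim$mutations, motif_catalog()$CG,
                           mc_reps = 99, seed = 42)
  expect_identical(r1$mc_p, r2$mc_p)
  expect_true(r1$mc_p >= 1 / 100 && r1$mc_p <= 1)
})

test_that("spectrum summary tallies classes, transitions and G:C pairs", {
  muts <- data.frame(
    chrom = "chr1", pos = 1:10,
    ref = c("C", "G", "A", "C", "G", "C", "G", "C", "A", "A"),
    alt = c("T", "A", "T", "T", "A", "T", "A", "G", "G", "C"),
    sample_id = "S1", stringsAsFactors = FALSE)
  s <- spectrum_summary(muts)
  expect_equal(sum(s$raw_counts), 10)
  expect_equal(s$transitions, 7L)   # 6 C>T/G>A plus A>G
  expect_equal(s$transversions, 3L)
  expect_equal(s$gc, 7L)
  expect_equal(s$at, 3L)
  expect_equal(s$gc_at_ratio, 7 / 3)
  # strand-symmetric classes: C>T == G>A pooled
  expect_equal(unname(s$class_counts["C>T"]), 6L)
  # two-record toy
  s2 <- spectrum_summary(data.frame(chrom = "c", pos = 1:2,
                                    ref = c("C", "G"), alt = c("T", "A"),
                                    sample_id = "S",
                                    stringsAsFactors = FALSE))
  expect_equal(s2$transitions, 2L)
  expect_equal(s2$gc, 2L)
})

test_that("Bonferroni flags use the family-size-adjusted threshold", {
  expect_true(bonferroni(0.01, m = 1))
  expect_false(bonferroni(0.01, m = 10))
  expect_false(bonferroni(0.005, m = 16))  # threshold 0.003125
  expect_equal(bonferroni(c(0.001, 0.04, NA)), c(TRUE, FALSE, FALSE))
})
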