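# WRCG-versus-CpG-control occurrence classification and Fisher contrast.

test_that("CpG occurrences classify by their upstream two bases", {
  win <- data.frame(chrom = "chr1", pos = 3L, ref = "C", alt = "T",
                    sample_id = "S1", neighborhood = "TACGA",
                    center_index = 3L, win_start = 1L,
                    stringsAsFactors = FALSE)
  occ <- enumerate_cpg_occurrences(win)
  fwd <- occ[occ$strand == "+", ]
  expect_equal(fwd$class, "WRCG")      # prefix TA = W,R
  expect_equal(fwd$mutable_pos, 3L)
  # reverse orientation lacks two downstream bases (CG at 3-4, needs 5-6)
  expect_equal(nrow(occ[occ$strand == "-", ]), 0L)

  win$neighborhood <- "TCCGA"          # prefix TC: C is a pyrimidine
  occ <- enumerate_cpg_occurrences(win)
  expect_equal(occ$class[occ$strand == "+"], "control")

  # reverse-strand classification: CG at 2-3 of "ACGTA";
  # reverse-strand prefix = complements of bases 5,4 = T,A = W,R -> WRCG
  win$neighborhood <- "ACGTA"
  win$pos <- 2L
  win$center_index <- 2L
  occ <- enumerate_cpg_occurrences(win)
  expect_equal(occ$class[occ$strand == "-"], "WRCG")
  expect_equal(occ$mutable_pos[occ$strand == "-"], 3L)  # the G's C strand
})

test_that("exhaustive NNCG scan finds 4 target and 12 control prefixes", {
  pre <- expand.grid(b2 = c("A", "C", "G", "T"),
                     b1 = c("A", "C", "G", "T"),
                     stringsAsFactors = FALSE)
  cls <- vapply(seq_len(nrow(pre)), function(i) {
    win <- data.frame(chrom = "chr1", pos = 3L + (i - 1L) * 100L,
                      ref = "C", alt = "T", sample_id = "S1",
                      neighborhood = paste0(pre$b2[i], pre$b1[i], "CG"),
                      center_index = 3L,
                      win_start = 1L + (i - 1L) * 100L,
                      stringsAsFactors = FALSE)
    occ <- enumerate_cpg_occurrences(win)
    occ$class[occ$strand == "+"]
  }, "")
  expect_equal(sum(cls == "WRCG"), 4L)
  expect_equal(sum(cls == "control"), 12L)
})

test_that("classification partitions and edge CpGs are excluded", {
  sim <- small_sim(n_mut = 100L, len = 30000L, seed = 19)
  occ <- enumerate_cpg_occurrences(sim$mutations)
  expect_true(all(occ$class %in% c("WRCG", "control")))
  # partition conservation: target + control = all classified occurrences
  ct <- contrast_test(occ, sim$mutations)
  expect_equal(ct$total_target + ct$total_control, nrow(occ))
  # a CpG at the very window edge cannot be classified forward
  edge <- data.frame(chrom = "chr1", pos = 1L, ref = "C", alt = "T",
                     sample_id = "S1", neighborhood = "CGTT",
                     center_index = 1L, win_start = 1L,
                     stringsAsFactors = FALSE)
  occ_edge <- enumerate_cpg_occurrences(edge)
  expect_equal(nrow(occ_edge[occ_edge$strand == "+", ]), 0L)
})

test_that("duplicated windows do not change occurrence counts", {
  sim <- small_sim(n_mut = 80L, len = 20000L, seed = 23)
  occ1 <- enumerate_cpg_occurrences(sim$mutations)
  dup <- rbind(sim$mutations, sim$mutations)
  occ2 <- enumerate_cpg_occurrences(dup)
  expect_equal(nrow(occ1), nrow(occ2))
  ct1 <- contrast_test(occ1, sim$mutations)
  ct2 <- contrast_test(occ2, dup)
  expect_equal(ct1$mutated_target, ct2$mutated_target)
  expect_equal(ct1$mutated_control, ct2$mutated_control)
})

test_that("symmetric and extreme toy tables give the exact Fisher p", {
  occ <- data.frame(
    chrom = "chr1", cpg_pos = seq_len(120) * 10L, strand = "+",
    mutable_pos = seq_len(120) * 10L,
    class = rep(c("WRCG", "control"), each = 60L),
    stringsAsFactors = FALSE)
  # 3/60 mutated in each class: identical fractions, p = 1
  muts <- data.frame(chrom = "chr1",
                     pos = c(10L, 20L, 30L, 610L, 620L, 630L))
  ct <- contrast_test(occ, muts)
  expect_equal(ct$fraction_target, ct$fraction_control)
  expect_equal(ct$fisher_p, 1)
  # 5/5 target mutated vs 0/5 control: two-sided p = 1/126
  occ2 <- occ[c(1:5, 61:65), ]
  muts2 <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L, 50L))
  ct2 <- contrast_test(occ2, muts2)
  expect_equal(ct2$mutated_target, 5L)
  expect_equal(ct2$mutated_control, 0L)
  expect_equal(ct2$fisher_p, 1 / 126, tolerance = 1e-10)
  # empty class flags non-computable
  ct3 <- contrast_test(occ2[occ2$class == "WRCG", ], muts2)
  expect_false(ct3$computable)
})

test_that("mutated occurrences are binary (many hits count once)", {
  occ <- data.frame(chrom = "chr1", cpg_pos = c(10L, 50L),
                    strand = "+", mutable_pos = c(10L, 50L),
                    class = c("WRCG", "control"),
                    stringsAsFactors = FALSE)
  muts <- data.frame(chrom = "chr1", pos = c(10L, 10L, 10L))
  ct <- contrast_test(occ, muts)
  expect_equal(ct$mutated_target, 1L)
})

test_that("region mode scans a reference without mutation windows", {
  ref <- c(chr1 = "TTTACGTTTTCCGTTTT")
  occ <- enumerate_cpg_occurrences(reference = ref,
                                   regions = data.frame(
                                     chrom = "chr1", start = 1L,
                                     end = 17L))
  fwd <- occ[occ$strand == "+", ]
  expect_equal(fwd$cpg_pos, c(5L, 12L))
  expect_equal(fwd$class, c("WRCG", "control"))  # TA.. vs TC..
})

test_that("a planted 4x hit-rate difference is detected consistently", {
  # simulation calibration: target occurrences mutated at 4x the control
  # rate; Fisher rejects at alpha = 0.05 in nearly all replicates
  set.seed(101)
  rejections <- vapply(1:60, function(i) {
    n <- 600L
    occ <- data.frame(chrom = "chr1", cpg_pos = seq_len(n) * 10L,
                      strand = "+", mutable_pos = seq_len(n) * 10L,
                      class = rep(c("WRCG", "control"), length.out = n),
                      stringsAsFactors = FALSE)
    rate <- ifelse(occ$class == "WRCG", 0.20, 0.05)
    hit <- stats::runif(n) < rate
    muts <- data.frame(chrom = "chr1", pos = occ$mutable_pos[hit])
    contrast_test(occ, muts)$fisher_p < 0.05
  }, TRUE)
  expect_gte(mean(rejections), 0.95)
})
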