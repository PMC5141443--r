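#!/usr/bin/env Rscript
# Stage 1: simulate the study dataset.
#
# A 450 kb reference (42% GC, CpG observed/expected 0.25), 10,000 somatic
# mutations with planted rate multipliers -- 3x at the mutable C of the
# hybrid AID/CpG motif WRCG/CGYW and 2x at CpG positions (multipliers
# compose multiplicatively where motifs overlap) -- and a per-CpG
# methylation table whose WRCG-context sites average 5 ratio points below
# control-CpG sites. Everything is written under results/simulated/ along
# with the ground-truth JSON so later stages (and anyone else) can rerun
# from files.

suppressMessages(library(motifexcess))

truth <- synthetic_truth(theta = c(WRCG = 3, CG = 2), seed = 20260922L)
sim <- simulate_dataset(truth, outdir = "results/simulated")

cat("reference:", nchar(sim$reference[[1]]), "bp;",
    "CpG sites:", nrow(sim$methylation), "\n")
cat("mutations:", nrow(sim$mutations), "planted with theta =",
    paste(names(truth$theta), truth$theta, sep = "=", collapse = ", "),
    "\n")
spectrum <- spectrum_summary(sim$mutations)
cat("spectrum: ", spectrum$transitions, "transitions /", spectrum$transversions,
    "transversions; G:C vs A:T ratio",
    round(spectrum$gc_at_ratio, 2), "\n")
cat("outputs in results/simulated/\n")
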