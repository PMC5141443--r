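#!/usr/bin/env Rscript
# Stage 3: is the hybrid motif more than CpG hypermutability?
#
# Classifies every CpG occurrence in the union of mutation neighborhoods
# as WRCG/CGYW (AID context upstream of the CpG) or control (YCG/CGR and
# SNCG/CGNS -- CpGs without the AID context; the two classes partition
# all classifiable CpG contexts) and compares the fractions of mutated
# occurrences with a two-sided Fisher test. Under the planted 3x WRCG
# multiplier the target fraction must exceed the control fraction even
# though both motif classes carry the 2x CpG multiplier.

suppressMessages(library(motifexcess))

muts <- read_mutations("results/simulated/mutations.tsv")
muts <- attach_neighborhoods(muts, "results/simulated/reference.fa")

occ <- enumerate_cpg_occurrences(muts)
cat("CpG occurrences in scope:", nrow(occ),
    sprintf("(%d WRCG, %d control)\n", sum(occ$class == "WRCG"),
            sum(occ$class == "control")))
ct <- contrast_test(occ, muts)
print(ct)

tab <- data.frame(
  mutated_target = ct$mutated_target, total_target = ct$total_target,
  mutated_control = ct$mutated_control,
  total_control = ct$total_control,
  fraction_target = ct$fraction_target,
  fraction_control = ct$fraction_control, fisher_p = ct$fisher_p)
write.table(tab, "results/contrast.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("table: results/contrast.tsv\n")
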