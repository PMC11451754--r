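#!/usr/bin/env Rscript
# Step 1 — simulate the study inputs: a reference with an inverted
# segmental-duplication (SD) pair plus a small diploid cohort carrying
# simple SVs and one SD-mediated complex rearrangement at controlled
# allele frequencies. Writes FASTA haplotypes and the truth table.

suppressMessages(library(complexsv))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ref <- make_reference(seed, 120000, sd_specs = list(
  sd_spec(30000, 33000, 60000, 63000, "inverted", 98)))
write_fasta(list(ref), file.path(out, "reference.fa"))
write.table(attr(ref, "sd_table"), file.path(out, "sd_pairs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

af_spec <- list(
  list(plan = list(rearrangement_op("DEL", 10000, 11200)), af = 1.0),
  list(plan = list(rearrangement_op("INS", 80000, 80000,
                                    payload_seed = seed + 1L,
                                    payload_len = 600)), af = 0.5),
  list(plan = list(rearrangement_op("TANDEM_DUP", 95000, 96500)), af = 0.25),
  # the SD-mediated composite: deletion, inversion across the SD pair,
  # deletion — the DEL-INV-DEL signature with a deceptive simple footprint
  list(plan = list(rearrangement_op("DEL", 27000, 30000),
                   rearrangement_op("INV", 30000, 63000),
                   rearrangement_op("DEL", 63000, 66000)), af = 0.4))

cohort <- simulate_cohort(ref, n_samples = 8, seed = seed + 2L,
                          af_spec = af_spec, dir = out)
cat(sprintf("simulated %d haplotypes (%d samples) with %d planted variants\n",
            cohort$n_haplotypes, 8L, length(af_spec)))
print(cohort$carriers[, c("variant", "target_af", "realised_af")])
cat("wrote", out, "\n")
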