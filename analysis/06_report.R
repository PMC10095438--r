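#!/usr/bin/env Rscript
# Stage 6: run summary.
#
# Collates the persisted stage tables into one plain-text report: cohort
# composition, DMP/DMR counts split by direction, DE counts at FDR and
# nominal thresholds, trait-associated modules, and the eQTM table.

suppressPackageStartupMessages(library(eqtmr))

ds <- read_dataset("results/cohort")
write.table(ds$samples, "results/samples.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

lines <- report_run("results")
writeLines(lines, "results/report.txt")
writeLines(lines)
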