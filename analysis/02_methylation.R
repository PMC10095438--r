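#!/usr/bin/env Rscript
# Stage 2: differential methylation.
#
# Per-CpG OLS on beta values adjusted for age, sex and five of the six
# blood cell fractions, BH FDR, then region calling at the strict (0.05)
# and relaxed (0.1) FDR cuts with the 2-CpG / 1000-nt rule. Promoter flags
# use the 5'UTR / first-exon / TSS-1500 definition.

suppressPackageStartupMessages(library(eqtmr))
ds <- read_dataset("results/cohort")
dir.create("results", showWarnings = FALSE)

dmps <- fit_dmps(ds$beta, ds$samples, design_spec())
sig <- dmps[!is.na(dmps$fdr) & dmps$fdr < 0.05, ]
message(sprintf("DMPs at FDR<0.05: %d (%d hypo, %d hyper) of %d CpGs",
                nrow(sig), sum(sig$direction == "hypo"),
                sum(sig$direction == "hyper"), nrow(dmps)))

# promoter annotation of significant DMPs
ann <- ds$cpg_annotation[match(dmps$cpg_id, ds$cpg_annotation$cpg_id), ]
gm_idx <- match(ann$gene, ds$gene_models$gene_id)
dmps$promoter <- vapply(seq_len(nrow(dmps)), function(i) {
  if (is.na(gm_idx[i])) return(FALSE)
  annotate_promoter(ann[i, ], ds$gene_models[gm_idx[i], ])
}, TRUE)
message(sprintf("promoter-associated significant DMPs: %d",
                sum(dmps$promoter & !is.na(dmps$fdr) & dmps$fdr < 0.05)))

dmrs <- call_dmrs(dmps, ds$cpg_annotation, fdr_threshold = 0.05)
dmrs_rel <- call_dmrs(dmps, ds$cpg_annotation, fdr_threshold = 0.1)
message(sprintf("DMRs: %d at FDR<0.05 (%d hypo, %d hyper); %d at FDR<0.1",
                nrow(dmrs), sum(dmrs$direction == "hypo"),
                sum(dmrs$direction == "hyper"), nrow(dmrs_rel)))

# recovery against the planted truth
recovered <- vapply(ds$truth$dmr_regions, function(r) {
  any(dmrs$chrom == r$chrom & dmrs$start <= r$end & dmrs$end >= r$start)
}, TRUE)
message(sprintf("planted regions recovered at FDR<0.05: %d/%d",
                sum(recovered), length(recovered)))

write.table(dmps, "results/dmp_table.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(dmrs, "results/dmr_table.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(dmrs_rel, "results/dmr_table_relaxed.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(dmr_to_bed(dmrs), "results/dmr_table.bed", sep = "\t",
            row.names = FALSE, col.names = FALSE, quote = FALSE)
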