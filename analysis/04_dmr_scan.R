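#!/usr/bin/env Rscript
# Step 4 -- differential methylation scans, case vs unaffected sibling.
#
# Class A/B BOPs with >= 3 probes are tested with the sliding-window MANOVA
# (Pillai's trace on 3 consecutive CpGs; lowest window p per BOP), class C/D
# probes with the site-level ANOVA, both adjusted for sex, batch and the five
# non-reference leukocyte fractions, with BH correction within each class.
# Mothers never enter the tests.  Chromosome-level beta distributions of the
# three groups are compared with pooled Kolmogorov-Smirnov tests (Bonferroni
# over chromosome x pair).

library(bopscan)

beta <- read_beta_matrix("results/qc/beta_qc.tsv")
annot <- parse_manifest("results/data/manifest.csv")
bops <- read_bop_table("results/qc/bops.tsv")
sheet <- read.delim("results/data/sheet.tsv")
props <- t(read_beta_matrix("results/deconvolution/proportions.tsv"))

design <- make_design(sheet, cell_props = props)
print(design)

scan <- scan_bops(bops, beta, design)
print(scan)
sites <- scan_sites(beta, annot, design, classes = c("C", "D"))
message("site scan: ", sum(sites$q_value < 0.05), " of ", nrow(sites),
        " class C/D probes with q < 0.05")

groups <- split(sheet$sample_id, sheet$group)
ks <- chromosome_distribution_test(beta, annot, groups)
message("chromosome distribution tests with Bonferroni p < 0.05: ",
        sum(ks$bonferroni_p < 0.05), " of ", nrow(ks))

dir.create("results/dmr", showWarnings = FALSE, recursive = TRUE)
write.table(scan$results, "results/dmr/bop_results.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(scan$probe_deltas, "results/dmr/probe_deltas.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sites, "results/dmr/site_results.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ks, "results/dmr/chromosome_ks.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# BED track of significant regions
sig <- scan$results[scan$results$q_value < 0.05, ]
if (nrow(sig)) {
  bed <- data.frame(chrom = paste0("chr", sig$chromosome),
                    start = sig$start - 1L, end = sig$end,
                    name = sig$bop_id,
                    score = round(-10 * log10(pmax(sig$min_p, 1e-30))))
  write.table(bed[order(bed$chrom, bed$start), ], "results/dmr/dmrs.bed",
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}
message("wrote results/dmr/")
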