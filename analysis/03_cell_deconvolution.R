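#!/usr/bin/env Rscript
# Step 3 -- leukocyte composition from methylation.
#
# Whole-blood methylation mixes cell-type-specific methylomes, and the case
# group carries a genuine composition shift (fewer B and CD4+ T cells, more
# CD8+ T cells), so composition must be estimated and adjusted for.  The 500
# most cell-type-informative CpGs (one-way F across sorted-cell types) feed a
# non-negative least-squares projection per sample; fractions are normalized
# to sum to one.  Estimates are validated against the simulated ground truth
# (standing in for flow-cytometry counts) and the group contrasts reported.

library(bopscan)

beta <- read_beta_matrix("results/qc/beta_qc.tsv")
ref <- read_beta_matrix("results/data/reference.tsv")
ref_sheet <- read.delim("results/data/reference_sheet.tsv")
sheet <- read.delim("results/data/sheet.tsv")
truth <- read_truth("results/data/truth.json")

sites <- select_informative_cpgs(ref, ref_sheet$cell_type, n = 500)
est <- estimate_cell_proportions(beta, ref, ref_sheet$cell_type, sites)
message("used ", est$n_sites_used, " of 500 informative sites (",
        est$n_sites_missing, " lost to QC)")

cmp <- compare_proportions(est$proportions, truth$proportions)
message("agreement with true proportions:")
print(cmp, digits = 3)

# group contrasts of the estimated fractions (descriptive Welch tests)
grp <- sheet$group[match(rownames(est$proportions), sheet$sample_id)]
contrast <- do.call(rbind, lapply(colnames(est$proportions), function(ty) {
  tt <- t.test(est$proportions[grp == "DSP", ty],
               est$proportions[grp == "DSS", ty])
  data.frame(cell_type = ty,
             mean_DSP = mean(est$proportions[grp == "DSP", ty]),
             mean_DSS = mean(est$proportions[grp == "DSS", ty]),
             p_value = tt$p.value)
}))
message("DSP vs DSS composition contrasts:")
print(contrast, digits = 3)

dir.create("results/deconvolution", showWarnings = FALSE, recursive = TRUE)
write_beta_matrix(t(est$proportions), "results/deconvolution/proportions.tsv",
                  id_name = "cell_type")
write.table(cmp, "results/deconvolution/agreement.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(contrast, "results/deconvolution/group_contrasts.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(sites, "results/deconvolution/informative_sites.txt")
message("wrote results/deconvolution/")
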