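#!/usr/bin/env Rscript
# Step 2 -- probe annotation and quality control.
#
# Classifies every probe (A: CpG-island context + genic, B: island context
# only, C: genic open sea, D: open sea), groups class A/B probes into BOPs,
# then applies the detection filters: samples failing detection at p > 1e-5
# on more than 75% of probes are dropped (none should be), and probes are
# removed when they fail detection at p > 0.05 in more than 75% of samples,
# contain missing values, or lie on a sex chromosome.

library(bopscan)

annot <- parse_manifest("results/data/manifest.csv")
beta <- read_beta_matrix("results/data/beta.tsv")
detp <- read_beta_matrix("results/data/detp.tsv")

cls <- classify_probes(annot)
bops <- build_bops(annot)
message("probe classes:")
print(table(cls))
message("BOP sizes (region scan tests only >= 3):")
print(bop_size_summary(bops))

sqc <- sample_qc(beta, detp)
message(length(sqc$retained), " of ", ncol(beta), " samples pass sample QC")
beta <- beta[, sqc$retained]
detp <- detp[, sqc$retained]

pqc <- probe_qc(beta, detp, annot)
message("probe QC: ", pqc$report$removed_detection, " failed detection, ",
        pqc$report$removed_missing, " had missing values, ",
        pqc$report$removed_sex, " on sex chromosomes; ",
        pqc$report$n_retained, " of ", pqc$report$n_input, " retained")

dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)
write_probe_classes(annot, "results/qc/probe_classes.tsv")
write_bop_table(bops, "results/qc/bops.tsv")
write_bop_bed(bops, "results/qc/bops.bed")
write_beta_matrix(pqc$beta, "results/qc/beta_qc.tsv")
jsonlite::write_json(
  c(pqc$report[c("n_input", "removed_detection", "removed_missing",
                 "removed_sex", "n_retained")],
    list(samples_retained = sqc$retained)),
  "results/qc/qc_report.json", auto_unbox = TRUE, digits = NA)
message("wrote results/qc/")
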