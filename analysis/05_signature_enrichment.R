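#!/usr/bin/env Rscript
# Step 5 -- epigenetic signature, enrichment and cohort geometry.
#
# From the significant class-A BOPs, keeps those with >= 2 genomically
# adjacent probes whose case-sibling difference exceeds 0.15 in the same
# direction (the stringent signature rule), summarizes each by its most
# significant probe, and checks: chromosomal enrichment of DMRs (Fisher),
# gene-set enrichment against synthetic collections, cancellation of shared
# family effects in per-trio differences, and whether the signature separates
# cases in MDS and hierarchical clustering.

library(bopscan)

beta <- read_beta_matrix("results/qc/beta_qc.tsv")
annot <- parse_manifest("results/data/manifest.csv")
bops <- read_bop_table("results/qc/bops.tsv")
sheet <- read.delim("results/data/sheet.tsv")
props <- t(read_beta_matrix("results/deconvolution/proportions.tsv"))
truth <- read_truth("results/data/truth.json")

design <- make_design(sheet, cell_props = props)
scan <- scan_bops(bops, beta, design)

## signature selection ----------------------------------------------------
sig <- select_signature(scan, delta_thresh = 0.15, min_adjacent = 2)
split <- attr(sig, "direction_split")
message(nrow(sig), " signature BOPs (", split["hyper"], " hyper / ",
        split["hypo"], " hypo in cases); ",
        sum(sig$bop_id %in% truth$planted$bop_id), " are planted regions")

site_p <- setNames(site_anova(beta, design)$p_value, rownames(beta))
reps <- representative_probes(scan, site_p, sig$bop_id)

## chromosomal enrichment over class-A BOPs -------------------------------
a <- scan$results[scan$results$class == "A", ]
enr <- chromosome_enrichment(data.frame(chromosome = a$chromosome,
                                        significant = a$q_value < 0.05))
message("chromosome enrichment (q < 0.05): ",
        paste(enr$unit[enr$significant], collapse = " "))

## gene-set enrichment -----------------------------------------------------
cls <- classify_probes(annot)
universe <- sort(unique(unlist(annot$genes[cls == "A"])))
dmr_genes <- sort(unique(bops$gene[bops$bop_id %in%
                                     a$bop_id[a$q_value < 0.05]]))
set.seed(2029)
collections <- c(
  list(signature_like = unique(c(dmr_genes,
                                 sample(universe, 5)))),
  lapply(setNames(1:4, paste0("random_set_", 1:4)),
         function(i) sample(universe, 30)))
write_gmt(collections, "results/dmr/collections.gmt")
gse <- geneset_fisher(dmr_genes, universe,
                      read_gmt("results/dmr/collections.gmt"))
message("gene-set enrichment:")
print(gse[, c("unit", "a", "odds_ratio", "p_value", "q_value")], digits = 3)

## trio differences and geometry ------------------------------------------
fd <- family_pair_differences(beta, sheet, reps$probe_id)
sig_mat <- t(beta[reps$probe_id, sheet$sample_id])
emb <- mds_embedding(sig_mat)
hc <- hierarchical_cluster(sig_mat, "rows")
k2 <- cutree(hc, 2)
grp <- sheet$group[match(names(k2), sheet$sample_id)]
message("2-cluster cut vs groups:")
print(table(cluster = k2, group = grp))

dir.create("results/signature", showWarnings = FALSE, recursive = TRUE)
write.table(sig, "results/signature/signature.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(reps, "results/signature/representative_probes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(enr, "results/signature/chromosome_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(gse, "results/signature/geneset_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_beta_matrix(fd$differences, "results/signature/family_differences.tsv",
                  id_name = "family")
write_beta_matrix(cbind(emb), "results/signature/mds_coordinates.tsv",
                  id_name = "sample_id")
writeLines(as_newick(hc), "results/signature/sample_dendrogram.nwk")
if (!is.null(fd$clustering)) {
  writeLines(as_newick(fd$clustering),
             "results/signature/family_dendrogram.nwk")
}

dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
png("results/figures/mds_signature.png", 700, 600)
plot(emb, col = c(DSP = "firebrick", DSS = "steelblue",
                  DSM = "darkgreen")[grp],
     pch = 19, xlab = "dimension 1", ylab = "dimension 2",
     main = "MDS on signature representative probes")
legend("topright", legend = c("DSP", "DSS", "DSM"), pch = 19,
       col = c("firebrick", "steelblue", "darkgreen"))
dev.off()
png("results/figures/sample_dendrogram.png", 900, 500)
plot(hc, labels = grp, cex = 0.6, main = "Signature clustering of samples")
dev.off()
message("wrote results/signature/ and results/figures/")
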