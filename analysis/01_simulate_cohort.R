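#!/usr/bin/env Rscript
# Step 1 -- simulate the study inputs.
#
# Builds the desk-scale trio cohort the rest of the workflow analyzes:
# 29 families (case / unaffected sibling / mother), a manifest with CpG-island
# loci plus open-sea probes (class mix ~50/13/24/12%), a sorted-leukocyte
# reference methylome coupled to the manifest, planted case-group effects in
# 12 class-A BOPs, a case-specific leukocyte composition shift, and a few
# engineered QC failures so the filters have work to do.

library(bopscan)

spec <- cohort_spec(planted_n = 12, planted_delta = 0.2, planted_probes = 3,
                    n_failing_probes = 5, n_missing_probes = 8,
                    seed = 2026)

manifest <- generate_manifest(spec)
annot <- as_probe_annotation(manifest)
message(nrow(manifest), " probes on the synthetic array")
print(table(classify_probes(annot)))

# reference methylome on a subset of array probes, as for a real
# sorted-cell panel assayed on the same platform
set.seed(2027)
ref_ids <- sort(sample(annot$probe_id, 800))
reference <- generate_reference_profiles(cpg_ids = ref_ids,
                                         n_discriminative = 500,
                                         seed = 2028)

cohort <- generate_cohort(spec, manifest, reference = reference)
message(ncol(cohort$beta), " samples x ", nrow(cohort$beta), " probes; ",
        nrow(cohort$truth$planted), " planted DMR BOPs")

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
write_cohort(cohort, manifest, "results/data")
write_beta_matrix(reference$beta, "results/data/reference.tsv",
                  id_name = "cpg_id")
write.table(data.frame(sample_id = colnames(reference$beta),
                       cell_type = reference$cell_type),
            "results/data/reference_sheet.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote results/data/{manifest.csv,beta.tsv,detp.tsv,sheet.tsv,",
        "truth.json,reference.tsv,reference_sheet.tsv}")
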