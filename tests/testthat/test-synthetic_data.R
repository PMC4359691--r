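test_that("the manifest generator is deterministic and class-balanced", {
  spec <- cohort_spec(seed = 9)
  m1 <- generate_manifest(spec)
  m2 <- generate_manifest(spec)
  expect_identical(m1, m2)

  cls <- classify_probes(as_probe_annotation(m1))
  prop <- table(cls) / length(cls)
  # roughly 50/13/24/12 with generous bands
  expect_gt(prop["A"], 0.35)
  expect_lt(prop["A"], 0.65)
  expect_gt(prop["C"], 0.12)
  expect_gt(prop["B"], 0.05)
  expect_gt(prop["D"], 0.05)
})

test_that("shores and shelves flank their island on both sides", {
  spec <- cohort_spec(n_loci_genic = 40, n_loci_cgi_nongenic = 0,
                      n_probes_c = 0, n_probes_d = 0, n_probes_sex = 0,
                      flank_prob = 1, seed = 10)
  annot <- as_probe_annotation(generate_manifest(spec))
  span <- do.call(rbind, regmatches(annot$island_id,
                                    regexec("chr[^:]+:(\\d+)-(\\d+)",
                                            annot$island_id)))
  start <- as.integer(span[, 2])
  end <- as.integer(span[, 3])
  rel <- annot$island_relation
  expect_true(all(annot$position[rel == "Island"] >= start[rel == "Island"]))
  expect_true(all(annot$position[rel == "Island"] <= end[rel == "Island"]))
  expect_true(all(annot$position[rel == "N_Shore"] < start[rel == "N_Shore"]))
  expect_true(all(annot$position[rel == "S_Shore"] > end[rel == "S_Shore"]))
  expect_true(all(annot$position[rel == "N_Shelf"] <
                    start[rel == "N_Shelf"] - 2000))
  expect_true(all(annot$position[rel == "S_Shelf"] >
                    end[rel == "S_Shelf"] + 2000))
})

test_that("a genic-loci-only spec yields pure class A probes in BOPs", {
  spec <- cohort_spec(n_loci_genic = 10, n_loci_cgi_nongenic = 0,
                      n_probes_c = 0, n_probes_d = 0, n_probes_sex = 0,
                      bop_size = 3, flank_prob = 0, multi_gene_frac = 0,
                      seed = 12)
  annot <- as_probe_annotation(generate_manifest(spec))
  expect_equal(nrow(annot), 30)
  expect_true(all(classify_probes(annot) == "A"))
  bops <- build_bops(annot)
  expect_equal(length(unique(bops$bop_id)), 10)
  expect_true(all(table(bops$bop_id) == 3))
})

test_that("the reference generator plants recoverable signal deterministically", {
  r1 <- generate_reference_profiles(n_cpgs = 300, n_discriminative = 40,
                                    seed = 13)
  r2 <- generate_reference_profiles(n_cpgs = 300, n_discriminative = 40,
                                    seed = 13)
  expect_identical(r1$beta, r2$beta)
  expect_length(r1$discriminative, 40)
  expect_true(all(r1$beta >= 0 & r1$beta <= 1))

  # with no planted sites the ranking has nothing to recover
  r0 <- generate_reference_profiles(n_cpgs = 100, n_discriminative = 0,
                                    seed = 14)
  expect_length(r0$discriminative, 0)
  expect_length(select_informative_cpgs(r0$beta, r0$cell_type, n = 10), 10)
})

test_that("a zero-effect noiseless cohort has identical group means", {
  spec <- cohort_spec(n_loci_genic = 15, n_loci_cgi_nongenic = 5,
                      n_probes_c = 20, n_probes_d = 10, n_probes_sex = 0,
                      planted_n = 0, frac_celltype = 0,
                      family_sd = 0, sex_sd = 0, batch_sd = 0,
                      noise_precision = Inf, seed = 15)
  man <- generate_manifest(spec)
  coh <- generate_cohort(spec, man)
  dsp <- coh$sheet$sample_id[coh$sheet$group == "DSP"]
  dss <- coh$sheet$sample_id[coh$sheet$group == "DSS"]
  expect_equal(rowMeans(coh$beta[, dsp]), rowMeans(coh$beta[, dss]))
})

test_that("planted deltas are realized within the sampling error bound", {
  spec <- cohort_spec(n_loci_genic = 80, n_loci_cgi_nongenic = 0,
                      n_probes_c = 0, n_probes_d = 0, n_probes_sex = 0,
                      bop_size = 3, flank_prob = 0, multi_gene_frac = 0,
                      planted_n = 5, planted_delta = 0.2, planted_probes = 3,
                      frac_celltype = 0, seed = 16)
  man <- generate_manifest(spec)
  coh <- generate_cohort(spec, man)
  dsp <- coh$sheet$sample_id[coh$sheet$group == "DSP"]
  dss <- coh$sheet$sample_id[coh$sheet$group == "DSS"]
  planted_probes <- unlist(strsplit(coh$truth$planted$probes, ";"))
  emp <- rowMeans(coh$beta[planted_probes, dsp]) -
    rowMeans(coh$beta[planted_probes, dss])
  expect_true(all(abs(emp - 0.2) < 0.03))
})

test_that("engineered QC failures are caught by the probe filters", {
  spec <- cohort_spec(n_loci_genic = 20, n_loci_cgi_nongenic = 0,
                      n_probes_c = 30, n_probes_d = 10, n_probes_sex = 6,
                      n_failing_probes = 4, n_missing_probes = 3,
                      frac_celltype = 0, detp_fail_rate = 0, seed = 17)
  man <- generate_manifest(spec)
  annot <- as_probe_annotation(man)
  coh <- generate_cohort(spec, man)
  qc <- sample_qc(coh$beta, coh$detp)
  expect_length(qc$retained, ncol(coh$beta))
  pqc <- probe_qc(coh$beta, coh$detp, annot)
  expect_equal(pqc$report$removed_detection, 4)
  expect_equal(pqc$report$removed_missing, 3)
  expect_equal(pqc$report$removed_sex, 6)
  expect_false(anyNA(pqc$beta))
})

test_that("cohorts are deterministic and the ground truth round-trips", {
  spec <- cohort_spec(n_loci_genic = 10, n_loci_cgi_nongenic = 3,
                      n_probes_c = 10, n_probes_d = 5, n_probes_sex = 2,
                      planted_n = 2, planted_probes = 3, seed = 18)
  man <- generate_manifest(spec)
  c1 <- generate_cohort(spec, man)
  c2 <- generate_cohort(spec, man)
  expect_identical(c1$beta, c2$beta)
  expect_identical(c1$detp, c2$detp)
  expect_identical(c1$sheet, c2$sheet)

  f <- tempfile(fileext = ".json")
  write_truth(c1$truth, f)
  back <- read_truth(f)
  expect_equal(back$planted$bop_id, c1$truth$planted$bop_id)
  expect_equal(back$proportions, c1$truth$proportions, tolerance = 1e-12)
  expect_equal(back$probe_effect, c1$truth$probe_effect, tolerance = 1e-12)
  expect_equal(back$sheet$sample_id, c1$truth$sheet$sample_id)

  # full cohort persistence
  d <- tempfile()
  write_cohort(c1, man, d)
  expect_equal(read_beta_matrix(file.path(d, "beta.tsv")), c1$beta)
  expect_equal(nrow(read.delim(file.path(d, "sheet.tsv"))),
               nrow(c1$sheet))
})

test_that("the sample sheet mirrors the trio design conditions", {
  spec <- cohort_spec(n_loci_genic = 5, n_loci_cgi_nongenic = 0,
                      n_probes_c = 5, n_probes_d = 0, n_probes_sex = 0,
                      frac_celltype = 0, seed = 19)
  coh <- generate_cohort(spec, generate_manifest(spec))
  s <- coh$sheet
  expect_equal(nrow(s), 3 * 29)
  expect_equal(unname(table(s$group)[c("DSP", "DSS", "DSM")]),
               rep(29L, 3), ignore_attr = TRUE)
  expect_equal(sum(s$sex == "M" & s$group == "DSP"), 18)
  expect_equal(sum(s$sex == "M" & s$group == "DSS"), 7)
  expect_true(all(s$sex[s$group == "DSM"] == "F"))
  # every family contributes one sample per group
  expect_true(all(table(s$family, s$group) == 1))
  # true proportions sum to one
  expect_true(all(abs(rowSums(coh$truth$proportions) - 1) < 1e-9))
})
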