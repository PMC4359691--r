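test_that("window MANOVA matches the type-II multivariate tests in car", {
  for (seed in 1:3) {
    set.seed(seed)
    sheet <- toy_sheet(20, seed = seed)
    des <- make_design(sheet)
    Y <- matrix(rnorm(3 * nrow(sheet), 0.5, 0.05), 3, nrow(sheet),
                dimnames = list(paste0("p", 1:3), sheet$sample_id))
    df <- data.frame(group = factor(sheet$group, c("DSP", "DSS")),
                     sex = factor(sheet$sex), batch = factor(sheet$batch))
    fit <- lm(t(Y) ~ group + sex + batch, data = df)

    sm <- summary(car::Manova(fit, type = 2))$multivariate.tests$group
    H <- sm$SSPH
    E <- sm$SSPE
    # car's own Pillai F approximation for this hypothesis
    V <- sum(diag(H %*% solve(H + E)))
    ve <- sm$df.residual
    f <- (ve - 3 + 1) / 3 * V / (1 - V)
    p_car <- pf(f, 3, ve - 2, lower.tail = FALSE)

    p_pkg <- window_manova_p(Y, des)
    expect_equal(as.numeric(p_pkg), p_car, tolerance = 1e-10)

    # Wilks' lambda route agrees with anova.mlm when group is the only term
    des0 <- make_design(sheet, covariates = character(0))
    fit0 <- lm(t(Y) ~ group, data = df)
    aw <- anova(fit0, test = "Wilks")
    expect_equal(as.numeric(window_manova_p(Y, des0, statistic = "wilks")),
                 aw["group", "Pr(>F)"], tolerance = 1e-10)
    ap <- anova(fit0, test = "Pillai")
    expect_equal(as.numeric(window_manova_p(Y, des0)),
                 ap["group", "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("window MANOVA agrees with its permutation null on a toy window", {
  set.seed(99)
  n <- 20
  sheet <- data.frame(sample_id = sprintf("t%02d", 1:n),
                      group = rep(c("DSP", "DSS"), each = n / 2),
                      stringsAsFactors = FALSE)
  des <- make_design(sheet, covariates = character(0))
  Y <- matrix(rnorm(3 * n, 0.5, 0.08), 3, n,
              dimnames = list(paste0("p", 1:3), sheet$sample_id))
  p_analytic <- as.numeric(window_manova_p(Y, des))

  v_obs <- oracle_pillai(t(Y), sheet$group)
  set.seed(123)
  n_perm <- 10000
  count <- 0
  for (i in seq_len(n_perm)) {
    v <- oracle_pillai(t(Y), sample(sheet$group))
    if (v >= v_obs) count <- count + 1
  }
  p_perm <- (count + 1) / (n_perm + 1)
  expect_lt(abs(p_analytic - p_perm), 0.02)
})

test_that("site ANOVA reduces to the pooled t-test and matches car type II", {
  sheet <- toy_sheet(15, seed = 11)
  des0 <- make_design(sheet, covariates = character(0))
  set.seed(12)
  b <- matrix(rnorm(nrow(sheet), 0.5, 0.05), 1, nrow(sheet),
              dimnames = list("probe", sheet$sample_id))
  res <- site_anova(b, des0)
  tt <- t.test(b[1, sheet$group == "DSP"], b[1, sheet$group == "DSS"],
               var.equal = TRUE)
  expect_lt(abs(res$p_value - tt$p.value), 1e-10)
  expect_equal(res$delta,
               mean(b[1, sheet$group == "DSP"]) -
                 mean(b[1, sheet$group == "DSS"]))

  # with covariates: type-II F for the group term, as in car::Anova
  des <- make_design(sheet)
  res2 <- site_anova(b, des)
  df <- data.frame(y = b[1, ], group = factor(sheet$group, c("DSP", "DSS")),
                   sex = factor(sheet$sex), batch = factor(sheet$batch))
  a2 <- car::Anova(lm(y ~ group + sex + batch, data = df), type = 2)
  expect_equal(res2$p_value, a2["group", "Pr(>F)"], tolerance = 1e-10)
})

test_that("degenerate probes yield p = 1 with a flag instead of failing", {
  sheet <- toy_sheet(10, seed = 21)
  des <- make_design(sheet)
  b <- matrix(0.5, 3, nrow(sheet),
              dimnames = list(paste0("p", 1:3), sheet$sample_id))
  p <- window_manova_p(b, des)
  expect_equal(as.numeric(p), 1)
  expect_true(attr(p, "degenerate"))
  res <- site_anova(b, des)
  expect_equal(res$p_value, rep(1, 3))
  expect_true(all(res$degenerate))
})

test_that("the BOP scan slides width-3 windows and keeps the lowest p", {
  spec <- cohort_spec(n_loci_genic = 60, n_loci_cgi_nongenic = 0,
                      n_probes_c = 0, n_probes_d = 0, n_probes_sex = 0,
                      flank_prob = 0, multi_gene_frac = 0,
                      frac_celltype = 0, seed = 31)
  man <- generate_manifest(spec)
  annot <- as_probe_annotation(man)
  coh <- generate_cohort(spec, man)
  bops <- build_bops(annot)
  des <- make_design(coh$sheet)
  sc <- scan_bops(bops, coh$beta, des, keep_windows = TRUE)

  # n_windows = n_probes - 2 for every tested BOP
  expect_equal(sc$results$n_windows, sc$results$n_probes - 2L)
  expect_true(all(sc$results$n_probes >= 3))
  # excluded BOPs are exactly those with < 3 probes
  sizes <- table(bops$bop_id)
  expect_setequal(sc$excluded$bop_id, names(sizes)[sizes < 3])
  # the reported minimum never exceeds any individual window p
  mins <- tapply(sc$windows$p_value, sc$windows$bop_id, min)
  expect_equal(as.numeric(mins[sc$results$bop_id]), sc$results$min_p)
  # q-values dominate p-values
  expect_true(all(sc$results$q_value >= sc$results$min_p - 1e-12))
})

test_that("a planted BOP attains the smallest scan p-value among nulls", {
  spec <- cohort_spec(n_loci_genic = 200, n_loci_cgi_nongenic = 0,
                      n_probes_c = 0, n_probes_d = 0, n_probes_sex = 0,
                      bop_size = 3, flank_prob = 0, multi_gene_frac = 0,
                      planted_n = 1, planted_delta = 0.2, planted_probes = 3,
                      frac_celltype = 0, seed = 32)
  man <- generate_manifest(spec)
  coh <- generate_cohort(spec, man)
  bops <- build_bops(as_probe_annotation(man))
  des <- make_design(coh$sheet)
  sc <- scan_bops(bops, coh$beta, des)
  expect_equal(sc$results$bop_id[which.min(sc$results$min_p)],
               coh$truth$planted$bop_id)
})

test_that("BH adjustment reproduces the step-up values and dominates p", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  set.seed(41)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  # monotone: a larger p never gets a smaller q
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("a full-null site scan makes no discoveries across seeds", {
  zero <- 0
  for (seed in 1:10) {
    spec <- cohort_spec(n_loci_genic = 0, n_loci_cgi_nongenic = 0,
                        n_probes_c = 300, n_probes_d = 0, n_probes_sex = 0,
                        planted_n = 0, frac_celltype = 0,
                        family_sd = 0, sex_sd = 0, batch_sd = 0,
                        seed = 500 + seed)
    man <- generate_manifest(spec)
    coh <- generate_cohort(spec, man)
    des <- make_design(coh$sheet)
    sites <- scan_sites(coh$beta, as_probe_annotation(man), des,
                        classes = "C")
    if (sum(sites$q_value < 0.05) == 0) zero <- zero + 1
  }
  expect_gte(zero, 9)
})

test_that("adjusting for cell proportions removes composition confounding", {
  # probe whose group difference is entirely mediated by one cell fraction
  set.seed(51)
  n <- 40
  frac <- c(runif(n / 2, 0.5, 0.9), runif(n / 2, 0.1, 0.5))
  sheet <- data.frame(sample_id = sprintf("c%02d", 1:n),
                      group = rep(c("DSP", "DSS"), each = n / 2),
                      stringsAsFactors = FALSE)
  props <- cbind(CT1 = frac, Gran = 1 - frac)
  rownames(props) <- sheet$sample_id
  b <- matrix(0.2 + 0.4 * frac + rnorm(n, sd = 0.02), 1, n,
              dimnames = list("probe", sheet$sample_id))

  un <- site_anova(b, make_design(sheet, covariates = character(0)))
  ad <- site_anova(b, make_design(sheet, covariates = character(0),
                                  cell_props = props))
  expect_lt(un$p_value, 0.01)
  expect_gt(ad$p_value, 0.05)
})

test_that("renaming batch labels leaves the scan unchanged", {
  sheet <- toy_sheet(15, seed = 61)
  set.seed(62)
  b <- matrix(rnorm(4 * nrow(sheet), 0.5, 0.05), 4, nrow(sheet),
              dimnames = list(paste0("p", 1:4), sheet$sample_id))
  des1 <- make_design(sheet)
  sheet2 <- sheet
  sheet2$batch <- c(B1 = "Bx", B2 = "By")[sheet$batch]
  des2 <- make_design(sheet2)
  expect_equal(site_anova(b, des1)$p_value, site_anova(b, des2)$p_value,
               tolerance = 1e-12)
  expect_equal(as.numeric(window_manova_p(b[1:3, ], des1)),
               as.numeric(window_manova_p(b[1:3, ], des2)),
               tolerance = 1e-12)
})

test_that("chromosome distribution tests match the ECDF oracle and Bonferroni scaling", {
  set.seed(71)
  probes <- sprintf("p%03d", 1:100)
  annot <- data.frame(probe_id = probes,
                      chromosome = rep(c("1", "2"), each = 50),
                      position = 1:100, island_relation = "OpenSea",
                      island_id = "", stringsAsFactors = FALSE)
  annot$genes <- replicate(100, character(0), simplify = FALSE)

  ids <- sprintf("s%02d", 1:20)
  g <- list(DSP = ids[1:10], DSS = ids[11:20])
  b <- matrix(runif(100 * 20, 0.2, 0.6), 100, 20,
              dimnames = list(probes, ids))
  # identical distributions -> D = 0, p = 1 (duplicate the group columns)
  b_id <- b
  b_id[, g$DSS] <- b[, g$DSP]
  r0 <- chromosome_distribution_test(b_id, annot, g)
  expect_true(all(r0$ks_statistic == 0))
  expect_true(all(r0$bonferroni_p == 1))

  # group 2 shifted by +0.2: D >= 0.2, and D equals a brute-force ECDF sweep
  b_sh <- b
  b_sh[, g$DSS] <- pmin(b[, g$DSS] + 0.2, 1)
  r1 <- chromosome_distribution_test(b_sh, annot, g)
  expect_true(all(r1$ks_statistic >= 0.2))
  for (ch in c("1", "2")) {
    x <- as.vector(b_sh[annot$chromosome == ch, g$DSP])
    y <- as.vector(b_sh[annot$chromosome == ch, g$DSS])
    expect_equal(r1$ks_statistic[r1$chromosome == ch], oracle_ks_stat(x, y))
  }
  # Bonferroni multiplies by (chromosomes x pairs), capped at 1
  expect_equal(r1$bonferroni_p, pmin(1, r1$p_raw * attr(r1, "n_tests")))
  expect_equal(attr(r1, "n_tests"), 2)

  # histograms are densities over [0,1]
  h <- attr(r1, "histograms")
  expect_true(all(vapply(h, function(d) abs(sum(d) / 100 - 1) < 1e-9,
                         TRUE)))
  expect_error(chromosome_distribution_test(b, annot, list(DSP = ids[1:10],
                                                           DSS = character(0))),
               "empty group")
})
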