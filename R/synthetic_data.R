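#' @name synthetic_data
#' @title Synthetic trio-cohort generator
#' @description
#' Generates every input the pipeline consumes — a manifest-dialect probe
#' annotation table, a sorted-cell reference methylome, and a trio-structured
#' beta / detection-p matrix pair with sample sheet — with controllable
#' planted effects: BOP-level methylation differences in the case group,
#' group-dependent leukocyte composition, family / sex / batch nuisance
#' shifts, and beta-distributed measurement noise.  Ground truth (planted
#' regions, true cell proportions, assignments) is returned alongside and
#' serializes to JSON.
NULL

#' Cohort specification
#'
#' Holds the study conditions for [generate_manifest()] and
#' [generate_cohort()].  Defaults mirror a 29-trio whole-blood study: one
#' affected case (DSP), one unaffected sibling (DSS) and the mother (DSM)
#' per family, case sex ratio 18M/11F and sibling 7M/22F, four processing
#' batches, and a case-specific leukocyte shift (fewer B and CD4+ T cells,
#' more CD8+ T cells).
#'
#' @param n_families number of trios.
#' @param n_loci_genic,n_loci_cgi_nongenic CpG-island loci with / without a
#'   gene annotation (yielding class A / class B BOPs).
#' @param n_probes_c,n_probes_d open-sea probes with / without genes.
#' @param n_probes_sex probes placed on chromosomes X/Y (exercise QC rule 3).
#' @param bop_size fixed probes-per-region count, or `NULL` to sample sizes
#'   1-8 with a small-skewed distribution (mean ~2.7).
#' @param flank_prob probability that each shore/shelf of a locus carries
#'   probes.
#' @param multi_gene_frac fraction of genic loci annotated to two genes.
#' @param planted_n,planted_delta,planted_probes number of class-A BOPs with
#'   a planted case-group effect, the beta shift, and how many consecutive
#'   probes of each BOP are shifted (`Inf` = all).
#' @param comp_control,comp_case named mean leukocyte fractions per group
#'   (DSS and DSM use `comp_control`).
#' @param comp_concentration Dirichlet concentration of per-sample
#'   composition around the group mean.
#' @param frac_celltype fraction of (non-reference) probes given
#'   cell-type-specific methylation, i.e. probes confounded by composition.
#' @param family_sd,sex_sd,batch_sd standard deviations of the per-probe
#'   nuisance shifts shared within a family, added to males, and shared
#'   within a batch.
#' @param n_batches number of processing batches.
#' @param noise_precision precision of the beta-distributed observation
#'   noise (`Inf` = noiseless).
#' @param detp_fail_rate fraction of random detection failures.
#' @param n_failing_probes probes engineered to fail detection in every
#'   sample (removed by probe QC rule 1).
#' @param n_missing_probes probes given one missing beta value (removed by
#'   probe QC rule 2).
#' @param dsp_male,dss_male number of male cases / siblings (scaled
#'   proportionally if `n_families` differs from 29).
#' @param seed integer seed; the generator is fully deterministic given the
#'   spec.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_families = 29,
                        n_loci_genic = 180, n_loci_cgi_nongenic = 45,
                        n_probes_c = 480, n_probes_d = 240,
                        n_probes_sex = 20,
                        bop_size = NULL, flank_prob = 0.3,
                        multi_gene_frac = 0.05,
                        planted_n = 0, planted_delta = 0.2,
                        planted_probes = 3,
                        comp_control = c(Bcell = 0.08, CD4T = 0.20,
                                         CD8T = 0.10, Gran = 0.55,
                                         Mono = 0.03, NK = 0.04),
                        comp_case = c(Bcell = 0.03, CD4T = 0.13,
                                      CD8T = 0.18, Gran = 0.57,
                                      Mono = 0.04, NK = 0.05),
                        comp_concentration = 200,
                        frac_celltype = 0.3,
                        family_sd = 0.02, sex_sd = 0.01, batch_sd = 0.01,
                        n_batches = 4,
                        noise_precision = 100,
                        detp_fail_rate = 0.002,
                        n_failing_probes = 0, n_missing_probes = 0,
                        dsp_male = 18, dss_male = 7,
                        seed = 1) {
  stopifnot(abs(planted_delta) < 1, family_sd >= 0, sex_sd >= 0,
            batch_sd >= 0, noise_precision > 0,
            abs(sum(comp_control) - 1) < 1e-9,
            abs(sum(comp_case) - 1) < 1e-9)
  structure(as.list(environment()), class = "cohort_spec")
}

.bop_size_probs <- c(0.35, 0.18, 0.16, 0.12, 0.08, 0.05, 0.04, 0.02)

#' Generate a synthetic manifest
#'
#' Lays CpG-island loci on synthetic coordinates (1 kb island, 2 kb shores
#' and shelves flanking it on both sides, each present with probability
#' `flank_prob`), assigns genes to genic loci, and appends open-sea probes
#' with and without genes plus a few sex-chromosome probes.  The class A-D
#' proportions under the defaults are roughly 50/13/24/12%.
#'
#' @param spec a [cohort_spec()].
#' @return `data.frame` in the manifest dialect (columns `IlmnID`, `CHR`,
#'   `MAPINFO`, `RELATION_TO_UCSC_CPG_ISLAND`, `UCSC_REFGENE_NAME`,
#'   `UCSC_CPG_ISLANDS_NAME`); parse with [as_probe_annotation()].
#' @export
generate_manifest <- function(spec) {
  set.seed(spec$seed)
  n_loci <- spec$n_loci_genic + spec$n_loci_cgi_nongenic
  genic <- rep(c(TRUE, FALSE), c(spec$n_loci_genic, spec$n_loci_cgi_nongenic))

  draw_size <- function(k) {
    if (!is.null(spec$bop_size)) rep(spec$bop_size, k)
    else sample(1:8, k, replace = TRUE, prob = .bop_size_probs)
  }

  rows <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    chrom <- as.character(sample(1:22, 1))
    base <- 1e6 + i * 20000
    island_id <- sprintf("chr%s:%d-%d", chrom, base, base + 999)
    gene <- if (genic[i]) {
      g <- sprintf("GENE%04d", i)
      if (runif(1) < spec$multi_gene_frac) {
        paste(g, sprintf("GENEB%04d", i), sep = ";")
      } else g
    } else ""
    spans <- list(Island = c(base, base + 999),
                  N_Shore = c(base - 2000, base - 1),
                  S_Shore = c(base + 1000, base + 2999),
                  N_Shelf = c(base - 4000, base - 2001),
                  S_Shelf = c(base + 3000, base + 4999))
    use <- c(TRUE, runif(4) < spec$flank_prob)
    reg <- lapply(which(use), function(k) {
      rel <- names(spans)[k]
      np <- draw_size(1)
      pos <- sort(sample(spans[[k]][1]:spans[[k]][2], np))
      data.frame(CHR = chrom, MAPINFO = pos,
                 RELATION_TO_UCSC_CPG_ISLAND = rel,
                 UCSC_REFGENE_NAME = gene,
                 UCSC_CPG_ISLANDS_NAME = island_id,
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, reg)
  }
  cgi <- do.call(rbind, rows)

  open_sea <- function(n, genes) {
    if (n == 0) return(NULL)
    data.frame(CHR = as.character(sample(1:22, n, replace = TRUE)),
               MAPINFO = 5e7 + seq_len(n) * 1000 +
                 sample(0:999, n, replace = TRUE),
               RELATION_TO_UCSC_CPG_ISLAND = "",
               UCSC_REFGENE_NAME = genes,
               UCSC_CPG_ISLANDS_NAME = "",
               stringsAsFactors = FALSE)
  }
  cc <- open_sea(spec$n_probes_c,
                 sprintf("GENEC%04d", (seq_len(spec$n_probes_c) - 1) %/% 3))
  dd <- open_sea(spec$n_probes_d, "")
  dd$MAPINFO <- dd$MAPINFO + 1e7
  sex <- if (spec$n_probes_sex == 0) NULL else data.frame(
    CHR = rep(c("X", "Y"), length.out = spec$n_probes_sex),
    MAPINFO = 1e6 + seq_len(spec$n_probes_sex) * 1000,
    RELATION_TO_UCSC_CPG_ISLAND = "",
    UCSC_REFGENE_NAME = "",
    UCSC_CPG_ISLANDS_NAME = "",
    stringsAsFactors = FALSE)

  manifest <- rbind(cgi, cc, dd, sex)
  manifest <- cbind(IlmnID = sprintf("cg%08d", seq_len(nrow(manifest))),
                    manifest, stringsAsFactors = FALSE)
  rownames(manifest) <- NULL
  manifest
}

#' Generate sorted-cell reference methylation profiles
#'
#' Discriminative CpGs receive independent per-cell-type mean methylation
#' levels spread over `[0.1, 0.9]`; the remaining CpGs share one common mean
#' across types.  Reference samples add within-type beta-distributed noise
#' around the type mean.
#'
#' @param cpg_ids CpG identifiers; default synthetic ids of length
#'   `n_cpgs`.  Pass manifest probe ids to couple the reference to a cohort.
#' @param n_cpgs number of CpGs when `cpg_ids` is `NULL`.
#' @param n_discriminative number of cell-type-discriminative CpGs.
#' @param n_per_type reference samples per cell type.
#' @param cell_types cell-type labels.
#' @param precision beta-noise precision of reference samples (`Inf` =
#'   noiseless).
#' @param seed integer seed.
#' @return List with `beta` (CpGs x reference samples), `cell_type` (label
#'   per sample), `mu` (true CpGs x types means), `discriminative` (planted
#'   CpG ids) and `cell_types`.
#' @export
generate_reference_profiles <- function(cpg_ids = NULL, n_cpgs = 2000,
                                        n_discriminative = 200,
                                        n_per_type = 3,
                                        cell_types = leukocyte_types(),
                                        precision = 200, seed = 1) {
  set.seed(seed)
  if (is.null(cpg_ids)) cpg_ids <- sprintf("ref%05d", seq_len(n_cpgs))
  n <- length(cpg_ids)
  if (n_discriminative > n) {
    stop("n_discriminative exceeds the number of CpGs")
  }
  k <- length(cell_types)
  disc <- sort(sample(cpg_ids, n_discriminative))
  common <- runif(n, 0.2, 0.8)
  mu <- matrix(common, n, k, dimnames = list(cpg_ids, cell_types))
  mu[disc, ] <- runif(n_discriminative * k, 0.1, 0.9)

  labels <- rep(cell_types, each = n_per_type)
  beta <- vapply(seq_along(labels), function(j) {
    m <- mu[, labels[j]]
    if (is.finite(precision)) rbeta(n, m * precision, (1 - m) * precision)
    else m
  }, numeric(n))
  dimnames(beta) <- list(cpg_ids,
                         paste(labels, sequence(rep(n_per_type, k)),
                               sep = "_"))
  list(beta = beta, cell_type = labels, mu = mu, discriminative = disc,
       cell_types = cell_types)
}

#' Generate mixed-cell target profiles from a reference
#'
#' Draws mixing weights from a flat Dirichlet prior over the reference cell
#' types, mixes the true type means accordingly and adds Gaussian
#' measurement noise (clipped to `[0, 1]`).  Used to benchmark
#' [estimate_cell_proportions()] against known weights.
#'
#' @param reference output of [generate_reference_profiles()].
#' @param n number of target samples.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return List with `beta` (CpGs x targets) and the true `weights`
#'   (targets x cell types).
#' @export
generate_mixture_targets <- function(reference, n = 50, noise_sd = 0.02,
                                     seed = 1) {
  set.seed(seed)
  k <- length(reference$cell_types)
  g <- matrix(rgamma(n * k, 1), n, k)
  w <- g / rowSums(g)
  colnames(w) <- reference$cell_types
  rownames(w) <- sprintf("mix%03d", seq_len(n))
  beta <- reference$mu %*% t(w)
  if (noise_sd > 0) {
    beta <- beta + rnorm(length(beta), sd = noise_sd)
  }
  beta <- pmin(pmax(beta, 0), 1)
  colnames(beta) <- rownames(w)
  list(beta = beta, weights = w)
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), alpha), n, length(alpha),
              byrow = TRUE)
  g / rowSums(g)
}

# Base mean methylation by island relation: islands low, open sea high,
# flanks intermediate, clipped away from the boundaries.
.draw_base_means <- function(relation) {
  n <- length(relation)
  a <- c(Island = 3, N_Shore = 4, S_Shore = 4, N_Shelf = 5, S_Shelf = 5,
         OpenSea = 8)[relation]
  b <- c(Island = 12, N_Shore = 6, S_Shore = 6, N_Shelf = 5, S_Shelf = 5,
         OpenSea = 3)[relation]
  pmin(pmax(rbeta(n, a, b), 0.05), 0.95)
}

#' Generate a trio cohort
#'
#' Builds, per sample, `beta = clip(base + family + sex + batch + planted
#' group effect + composition mixture, eps, 1-eps)` followed by
#' beta-distributed observation noise, together with detection p-values and
#' a sample sheet.  Case samples (DSP) receive the planted deltas and the
#' shifted leukocyte composition.  When a `reference` built on manifest
#' probe ids is supplied, the overlapping probes carry the reference's
#' cell-type profiles so that deconvolution of the cohort is consistent with
#' the reference; an additional `frac_celltype` of probes get independent
#' cell-type-specific profiles.
#'
#' @param spec a [cohort_spec()].
#' @param manifest manifest `data.frame` from [generate_manifest()].
#' @param reference optional output of [generate_reference_profiles()]
#'   (built on manifest probe ids).
#' @return List with `beta`, `detp` (probes x samples), `sheet`
#'   (`sample_id`, `family`, `group`, `sex`, `batch`) and `truth` (planted
#'   table, true proportions, per-probe true case-control effect).
#' @export
generate_cohort <- function(spec, manifest, reference = NULL) {
  annot <- as_probe_annotation(manifest)
  probes <- annot$probe_id
  n_probes <- length(probes)
  set.seed(spec$seed + 1L)

  ## --- samples -------------------------------------------------------
  nf <- spec$n_families
  fams <- sprintf("F%02d", seq_len(nf))
  scale_m <- function(m) round(nf * m / 29)
  sex_dsp <- sample(rep(c("M", "F"),
                        c(scale_m(spec$dsp_male),
                          nf - scale_m(spec$dsp_male))))
  sex_dss <- sample(rep(c("M", "F"),
                        c(scale_m(spec$dss_male),
                          nf - scale_m(spec$dss_male))))
  sheet <- data.frame(
    sample_id = c(paste0(fams, "_DSP"), paste0(fams, "_DSS"),
                  paste0(fams, "_DSM")),
    family = rep(fams, 3),
    group = rep(c("DSP", "DSS", "DSM"), each = nf),
    sex = c(sex_dsp, sex_dss, rep("F", nf)),
    batch = sample(sprintf("B%d", seq_len(spec$n_batches)), 3 * nf,
                   replace = TRUE),
    stringsAsFactors = FALSE)
  n_samples <- nrow(sheet)

  ## --- true cell proportions ----------------------------------------
  types <- names(spec$comp_control)
  props <- matrix(NA_real_, n_samples, length(types),
                  dimnames = list(sheet$sample_id, types))
  is_case <- sheet$group == "DSP"
  props[is_case, ] <- .rdirichlet(sum(is_case),
                                  spec$comp_case * spec$comp_concentration)
  props[!is_case, ] <- .rdirichlet(sum(!is_case),
                                   spec$comp_control *
                                     spec$comp_concentration)

  ## --- probe-level structure ----------------------------------------
  base <- .draw_base_means(annot$island_relation)
  names(base) <- probes

  ct_mu <- NULL
  if (!is.null(reference)) {
    overlap <- intersect(rownames(reference$mu), probes)
    if (length(overlap)) ct_mu <- reference$mu[overlap, types, drop = FALSE]
  }
  pool <- setdiff(probes, rownames(ct_mu))
  n_extra <- round(spec$frac_celltype * length(pool))
  if (n_extra > 0) {
    extra <- sample(pool, n_extra)
    extra_mu <- matrix(runif(n_extra * length(types), 0.1, 0.9),
                       n_extra, length(types),
                       dimnames = list(extra, types))
    ct_mu <- rbind(ct_mu, extra_mu)
  }

  ## --- planted BOP effects ------------------------------------------
  planted <- data.frame(bop_id = character(), delta = numeric(),
                        probes = character(), stringsAsFactors = FALSE)
  effect <- setNames(numeric(n_probes), probes)
  if (spec$planted_n > 0) {
    bops <- build_bops(annot)
    a <- bops[bops$class == "A", , drop = FALSE]
    sizes <- table(a$bop_id)
    min_np <- if (is.finite(spec$planted_probes)) spec$planted_probes else 3
    eligible <- names(sizes)[sizes >= min_np]
    eligible <- eligible[!duplicated(vapply(eligible, function(b) {
      paste(sort(a$probe_id[a$bop_id == b]), collapse = ";")
    }, ""))]
    if (length(eligible) < spec$planted_n) {
      stop("only ", length(eligible), " eligible class-A BOPs for ",
           spec$planted_n, " planted effects")
    }
    chosen <- sample(eligible, spec$planted_n)
    for (b in chosen) {
      pid <- a$probe_id[a$bop_id == b]
      pid <- pid[order(a$position[a$bop_id == b])]
      np <- if (is.finite(spec$planted_probes)) {
        min(spec$planted_probes, length(pid))
      } else length(pid)
      pid <- pid[seq_len(np)]
      effect[pid] <- spec$planted_delta
      # keep the planted shift inside the beta range
      base[pid] <- runif(length(pid), 0.25, 0.55)
      planted <- rbind(planted, data.frame(
        bop_id = b, delta = spec$planted_delta,
        probes = paste(pid, collapse = ";"), stringsAsFactors = FALSE))
    }
  }

  ## --- nuisance effects ---------------------------------------------
  fam_eff <- matrix(rnorm(n_probes * nf, sd = spec$family_sd), n_probes, nf,
                    dimnames = list(probes, fams))
  sex_eff <- rnorm(n_probes, sd = spec$sex_sd)
  batch_eff <- matrix(rnorm(n_probes * spec$n_batches, sd = spec$batch_sd),
                      n_probes, spec$n_batches,
                      dimnames = list(probes,
                                      sprintf("B%d",
                                              seq_len(spec$n_batches))))

  ## --- expected beta per (probe, sample) ----------------------------
  M <- matrix(base, n_probes, n_samples,
              dimnames = list(probes, sheet$sample_id))
  if (!is.null(ct_mu)) {
    M[rownames(ct_mu), ] <- ct_mu %*% t(props)
  }
  M <- M + fam_eff[, sheet$family]
  M <- M + outer(sex_eff, as.numeric(sheet$sex == "M"))
  M <- M + batch_eff[, sheet$batch]
  M <- M + outer(effect, as.numeric(is_case))
  eps <- 1e-6
  M <- pmin(pmax(M, eps), 1 - eps)

  ## --- observation noise and detection p, one substream per sample --
  beta <- matrix(NA_real_, n_probes, n_samples,
                 dimnames = dimnames(M))
  detp <- beta
  seed_base <- (spec$seed %% 100000L) * 10000L
  for (j in seq_len(n_samples)) {
    set.seed(seed_base + j)
    beta[, j] <- if (is.finite(spec$noise_precision)) {
      rbeta(n_probes, M[, j] * spec$noise_precision,
            (1 - M[, j]) * spec$noise_precision)
    } else M[, j]
    dp <- runif(n_probes) * 1e-6
    fail <- runif(n_probes) < spec$detp_fail_rate
    dp[fail] <- runif(sum(fail), 0.06, 1)
    detp[, j] <- dp
  }

  ## --- engineered QC failures ---------------------------------------
  set.seed(spec$seed + 2L)
  fp <- character()
  if (spec$n_failing_probes > 0) {
    fp <- sample(probes, spec$n_failing_probes)
    detp[fp, ] <- runif(length(fp) * n_samples, 0.06, 0.5)
  }
  if (spec$n_missing_probes > 0) {
    mp <- sample(setdiff(probes, fp), spec$n_missing_probes)
    beta[cbind(mp, sample(sheet$sample_id, length(mp), replace = TRUE))] <-
      NA_real_
  }

  truth <- list(planted = planted, proportions = props,
                probe_effect = effect[effect != 0],
                sheet = sheet, seed = spec$seed)
  list(beta = beta, detp = detp, sheet = sheet, truth = truth)
}

#' Serialize / restore cohort ground truth
#'
#' @param truth the `truth` element of [generate_cohort()] output.
#' @param path JSON file path.
#' @return `read_truth` returns the truth list (matrices restored).
#' @export
write_truth <- function(truth, path) {
  obj <- list(planted = truth$planted,
              proportions = as.data.frame(truth$proportions),
              proportion_samples = rownames(truth$proportions),
              probe_effect = as.list(truth$probe_effect),
              sheet = truth$sheet, seed = truth$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  props <- as.matrix(obj$proportions)
  rownames(props) <- obj$proportion_samples
  list(planted = as.data.frame(obj$planted),
       proportions = props,
       probe_effect = unlist(obj$probe_effect),
       sheet = as.data.frame(obj$sheet), seed = obj$seed)
}

#' Write a generated cohort to disk
#'
#' Writes `manifest.csv`, `beta.tsv`, `detp.tsv`, `sheet.tsv` and
#' `truth.json` under `dir`.
#'
#' @param cohort output of [generate_cohort()].
#' @param manifest manifest `data.frame`.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, manifest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE,
            quote = FALSE)
  write_beta_matrix(cohort$beta, file.path(dir, "beta.tsv"))
  write_beta_matrix(cohort$detp, file.path(dir, "detp.tsv"))
  write.table(cohort$sheet, file.path(dir, "sheet.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_truth(cohort$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
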