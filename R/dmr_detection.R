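#' @name dmr_detection
#' @title Covariate-adjusted differential methylation scans
#' @description
#' Region-level testing slides a window of 3 consecutive CpGs along each BOP
#' and fits a multivariate linear model of the 3 beta responses on the group
#' factor plus nuisance covariates (sex, batch, cell proportions); the group
#' effect is tested with Pillai's trace (Wilks' lambda optionally) via the
#' standard F approximation, and the lowest window p-value represents the
#' BOP.  CpG-poor probes (classes C and D) are tested one at a time with the
#' analogous univariate F test.  Both tests use type-II sums of squares for
#' the group term (the model with and without the group factor, all
#' covariates retained), so covariate order is irrelevant.  Benjamini-
#' Hochberg correction is applied separately within each probe class.
NULL

#' Build the design for a two-group covariate-adjusted scan
#'
#' Restricts the sample sheet to the two tested groups (mothers or any other
#' group are excluded from testing), encodes the group factor and the
#' requested nuisance covariates, and appends cell-proportion covariates.
#' To avoid the sum-to-one collinearity of compositional covariates, one
#' cell type (by default the granulocyte compartment, the largest) is
#' dropped.
#'
#' @param sheet sample sheet `data.frame` with columns `sample_id`, `group`
#'   and any covariate columns named in `covariates`.
#' @param cell_props optional matrix of estimated cell proportions
#'   (samples x cell types) from [estimate_cell_proportions()].
#' @param groups the two group labels to contrast; the first is the case
#'   group (deltas are first minus second).
#' @param covariates sample-sheet columns treated as factors in the model.
#' @param drop_celltype cell-proportion column excluded as reference
#'   compartment.
#' @return A `dmr_design` list holding the sample ids, group factor, full and
#'   reduced model matrices and their QR decompositions.
#' @export
make_design <- function(sheet, cell_props = NULL,
                        groups = c("DSP", "DSS"),
                        covariates = c("sex", "batch"),
                        drop_celltype = "Gran") {
  keep <- sheet$group %in% groups
  s <- sheet[keep, , drop = FALSE]
  if (!nrow(s)) stop("no samples in groups ", paste(groups, collapse = "/"))
  df <- data.frame(group = factor(s$group, levels = groups))
  for (cv in covariates) {
    if (!cv %in% names(s)) stop("covariate column '", cv, "' not in sheet")
    v <- s[[cv]]
    df[[cv]] <- if (is.numeric(v)) v else factor(v)
  }
  if (!is.null(cell_props)) {
    missing <- setdiff(s$sample_id, rownames(cell_props))
    if (length(missing)) {
      stop("cell proportions missing for sample(s): ",
           paste(head(missing, 5), collapse = ", "))
    }
    P <- cell_props[s$sample_id,
                    setdiff(colnames(cell_props), drop_celltype),
                    drop = FALSE]
    for (ty in colnames(P)) df[[paste0("prop_", ty)]] <- P[, ty]
  }
  X_full <- model.matrix(~ ., df)
  X_red <- model.matrix(~ . - group, df)
  if (qr(X_full)$rank < ncol(X_full)) {
    stop("design matrix is rank-deficient; drop collinear covariates")
  }
  qr_full <- qr(X_full)
  qr_red <- qr(X_red)
  structure(list(samples = s$sample_id, group = df$group, groups = groups,
                 X_full = X_full, X_red = X_red,
                 qr_full = qr_full, qr_red = qr_red,
                 df_group = qr_full$rank - qr_red$rank,
                 ve = nrow(X_full) - qr_full$rank),
            class = "dmr_design")
}

#' @export
print.dmr_design <- function(x, ...) {
  cat("dmr_design:", length(x$samples), "samples;",
      paste(x$groups, collapse = " vs "), "\n")
  cat("  columns:", paste(colnames(x$X_full), collapse = ", "), "\n")
  cat("  residual df:", x$ve, "\n")
  invisible(x)
}

# Multivariate test of the group effect from SSCP matrices.
# E: residual SSCP of the full model; H: extra SSCP explained by group
# (type II); q: hypothesis df; ve: residual df.
.manova_p <- function(E, H, q, ve, statistic = "pillai") {
  p <- nrow(E)
  HE <- H + E
  out <- list(p_value = 1, statistic = NA_real_, degenerate = TRUE)
  if (statistic == "pillai") {
    V <- tryCatch(sum(diag(H %*% solve(HE))), error = function(e) NA_real_)
    if (is.na(V) || !is.finite(V)) return(out)
    s <- min(p, q)
    m <- (abs(p - q) - 1) / 2
    nn <- (ve - p - 1) / 2
    df1 <- s * (2 * m + s + 1)
    df2 <- s * (2 * nn + s + 1)
    if (df2 <= 0) return(out)
    V <- min(max(V, 0), s)
    f <- if (V >= s - 1e-12) Inf else
      (2 * nn + s + 1) / (2 * m + s + 1) * V / (s - V)
    list(p_value = pf(f, df1, df2, lower.tail = FALSE), statistic = V,
         degenerate = FALSE)
  } else if (statistic == "wilks") {
    detE <- det(E)
    detHE <- det(HE)
    if (!is.finite(detE) || !is.finite(detHE) || detHE <= 0) return(out)
    lambda <- max(min(detE / detHE, 1), 0)
    r <- ve - (p - q + 1) / 2
    st <- if (p^2 + q^2 - 5 > 0) {
      sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5))
    } else 1
    df1 <- p * q
    df2 <- r * st - p * q / 2 + 1
    if (df2 <= 0) return(out)
    ls <- lambda^(1 / st)
    f <- if (ls <= 0) Inf else (1 - ls) / ls * df2 / df1
    list(p_value = pf(f, df1, df2, lower.tail = FALSE), statistic = lambda,
         degenerate = FALSE)
  } else {
    stop("unknown statistic: ", statistic)
  }
}

#' MANOVA p-value for one 3-CpG window
#'
#' Fits a multivariate linear model of the window's beta responses on the
#' design and returns the p-value for the group effect.  A degenerate window
#' (e.g. a constant probe making the residual covariance singular) returns
#' p = 1 with the `"degenerate"` attribute set, rather than failing.
#'
#' @param window_beta matrix of the window's probes (rows) by samples
#'   (columns); columns must cover the design's samples.
#' @param design a `dmr_design` from [make_design()].
#' @param statistic `"pillai"` (default) or `"wilks"`.
#' @return The p-value, with attributes `statistic` and `degenerate`.
#' @export
window_manova_p <- function(window_beta, design,
                            statistic = c("pillai", "wilks")) {
  statistic <- match.arg(statistic)
  Yt <- t(window_beta[, design$samples, drop = FALSE])
  rf <- qr.resid(design$qr_full, Yt)
  rr <- qr.resid(design$qr_red, Yt)
  E <- crossprod(rf)
  H <- crossprod(rr) - E
  res <- .manova_p(E, H, design$df_group, design$ve, statistic)
  structure(res$p_value, statistic = res$statistic,
            degenerate = res$degenerate)
}

#' Per-probe group-mean differences
#'
#' Delta is mean beta in the case group minus mean beta in the control group
#' (the first and second entries of the design's `groups`).
#'
#' @param beta beta matrix.
#' @param design a `dmr_design`.
#' @return Named numeric vector of deltas, one per probe in `beta`.
#' @export
probe_deltas <- function(beta, design) {
  case <- design$samples[design$group == design$groups[1]]
  ctrl <- design$samples[design$group == design$groups[2]]
  rowMeans(beta[, case, drop = FALSE]) - rowMeans(beta[, ctrl, drop = FALSE])
}

#' Region-level sliding-window MANOVA scan over BOPs
#'
#' For every BOP with at least 3 probes present in the beta matrix, slides a
#' width-3, step-1 window in genomic order, computes [window_manova_p()] per
#' window, and keeps the lowest p-value (and the window attaining it).  BOPs
#' with fewer than 3 probes are listed as excluded.  BH q-values are computed
#' separately within each class.
#'
#' @param bops BOP membership table from [build_bops()].
#' @param beta QC'd beta matrix.
#' @param design a `dmr_design`.
#' @param statistic `"pillai"` or `"wilks"`.
#' @param keep_windows also return every individual window p-value (used
#'   e.g. for calibration diagnostics).
#' @return A `bop_scan` list: `results` (one row per tested BOP: `bop_id`,
#'   `class`, `chromosome`, `start`, `end`, `n_probes`, `n_windows`,
#'   `min_p`, `best_window`, `q_value`, `delta`, `direction`, `degenerate`),
#'   `probe_deltas` (per BOP-probe delta in genomic order), `excluded`
#'   (BOPs with < 3 usable probes) and, if requested, `windows`.
#' @export
scan_bops <- function(bops, beta, design, statistic = c("pillai", "wilks"),
                      keep_windows = FALSE) {
  statistic <- match.arg(statistic)
  present <- bops$probe_id %in% rownames(beta)
  n_dropped <- sum(!present)
  memb <- bops[present, , drop = FALSE]

  sizes <- table(memb$bop_id)
  tested_ids <- names(sizes)[sizes >= 3]
  small_ids <- names(sizes)[sizes < 3]

  probes <- unique(memb$probe_id)
  B <- beta[probes, design$samples, drop = FALSE]
  RF <- qr.resid(design$qr_full, t(B))
  RR <- qr.resid(design$qr_red, t(B))
  colnames(RF) <- colnames(RR) <- probes
  deltas <- probe_deltas(B, design)

  memb_tested <- memb[memb$bop_id %in% tested_ids, , drop = FALSE]
  groups_idx <- split(seq_len(nrow(memb_tested)), memb_tested$bop_id)

  window_log <- if (keep_windows) vector("list", length(groups_idx))
  res <- lapply(seq_along(groups_idx), function(gi) {
    bid <- names(groups_idx)[gi]
    rows <- groups_idx[[bid]]
    pid <- memb_tested$probe_id[rows]
    np <- length(pid)
    best_p <- Inf
    best_w <- NA_character_
    degen <- FALSE
    wp <- numeric(np - 2)
    for (w in seq_len(np - 2)) {
      idx <- pid[w:(w + 2)]
      E <- crossprod(RF[, idx, drop = FALSE])
      H <- crossprod(RR[, idx, drop = FALSE]) - E
      m <- .manova_p(E, H, design$df_group, design$ve, statistic)
      if (m$degenerate) degen <- TRUE
      wp[w] <- m$p_value
      if (m$p_value < best_p) {
        best_p <- m$p_value
        best_w <- paste(idx, collapse = ";")
      }
    }
    if (keep_windows) {
      window_log[[gi]] <<- data.frame(bop_id = bid,
                                      window = seq_len(np - 2),
                                      p_value = wp,
                                      stringsAsFactors = FALSE)
    }
    if (!is.finite(best_p)) best_p <- 1
    d <- mean(deltas[pid])
    data.frame(
      bop_id = bid, class = memb_tested$class[rows[1]],
      chromosome = memb_tested$chromosome[rows[1]],
      start = min(memb_tested$position[rows]),
      end = max(memb_tested$position[rows]),
      n_probes = np, n_windows = np - 2L, min_p = best_p,
      best_window = best_w, delta = d,
      direction = ifelse(d >= 0, "hyper", "hypo"),
      degenerate = degen, stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, res)
  if (is.null(results)) {
    results <- data.frame(bop_id = character(), class = character(),
                          chromosome = character(), start = integer(),
                          end = integer(), n_probes = integer(),
                          n_windows = integer(), min_p = numeric(),
                          best_window = character(), delta = numeric(),
                          direction = character(), degenerate = logical())
  }
  results$q_value <- NA_real_
  for (cl in unique(results$class)) {
    i <- results$class == cl
    results$q_value[i] <- bh_adjust(results$min_p[i])
  }
  results <- results[, c("bop_id", "class", "chromosome", "start", "end",
                         "n_probes", "n_windows", "min_p", "q_value",
                         "best_window", "delta", "direction", "degenerate")]
  rownames(results) <- NULL

  pd <- memb[, c("bop_id", "class", "probe_id", "position")]
  pd <- pd[order(pd$bop_id, pd$position), ]
  pd$delta <- deltas[pd$probe_id]
  rownames(pd) <- NULL

  excluded <- data.frame(bop_id = small_ids,
                         n_probes = as.integer(sizes[small_ids]),
                         reason = rep("fewer than 3 probes",
                                      length(small_ids)))
  out <- list(results = results, probe_deltas = pd, excluded = excluded,
              n_probes_dropped = n_dropped, statistic = statistic)
  if (keep_windows) out$windows <- do.call(rbind, window_log)
  structure(out, class = "bop_scan")
}

#' @export
print.bop_scan <- function(x, ...) {
  cat("bop_scan (", x$statistic, "): ", nrow(x$results), " BOPs tested, ",
      nrow(x$excluded), " excluded (<3 probes)\n", sep = "")
  for (cl in sort(unique(x$results$class))) {
    i <- x$results$class == cl
    cat("  class ", cl, ": ", sum(i), " tested, ",
        sum(x$results$q_value[i] < 0.05), " with q < 0.05\n", sep = "")
  }
  invisible(x)
}

#' Site-level ANOVA scan
#'
#' Tests each probe with the univariate analogue of the window test: the
#' type-II F test of the group factor in a linear model of beta on group plus
#' covariates.  Constant (degenerate) probes return p = 1 with a flag.
#'
#' @param beta beta matrix restricted to the probes to test (e.g. one
#'   class).
#' @param design a `dmr_design`.
#' @return `data.frame` with `probe_id`, `p_value`, `delta`, `direction`,
#'   `degenerate`.  Add class-wise q-values with [bh_adjust()] or use
#'   [scan_sites()].
#' @export
site_anova <- function(beta, design) {
  B <- beta[, design$samples, drop = FALSE]
  RF <- qr.resid(design$qr_full, t(B))
  RR <- qr.resid(design$qr_red, t(B))
  rss_f <- colSums(RF^2)
  rss_r <- colSums(RR^2)
  q <- design$df_group
  f <- ((rss_r - rss_f) / q) / (rss_f / design$ve)
  p <- pf(f, q, design$ve, lower.tail = FALSE)
  degenerate <- rss_f < 1e-12
  p[degenerate] <- 1
  d <- probe_deltas(B, design)
  data.frame(probe_id = rownames(beta), p_value = unname(p),
             delta = unname(d),
             direction = ifelse(d >= 0, "hyper", "hypo"),
             degenerate = unname(degenerate), stringsAsFactors = FALSE)
}

#' Site-level scan with per-class BH correction
#'
#' Runs [site_anova()] on the probes of the requested classes (typically C
#' and D) and attaches BH q-values computed within each class.
#'
#' @param beta QC'd beta matrix.
#' @param annot probe annotation table.
#' @param design a `dmr_design`.
#' @param classes probe classes to test.
#' @return `data.frame` of site results with `class` and `q_value` columns.
#' @export
scan_sites <- function(beta, annot, design, classes = c("C", "D")) {
  cls <- classify_probes(annot)
  names(cls) <- annot$probe_id
  probe_cls <- cls[rownames(beta)]
  out <- lapply(classes, function(cl) {
    probes <- rownames(beta)[probe_cls == cl & !is.na(probe_cls)]
    if (!length(probes)) return(NULL)
    r <- site_anova(beta[probes, , drop = FALSE], design)
    r$class <- cl
    r$q_value <- bh_adjust(r$p_value)
    r
  })
  res <- do.call(rbind, out)
  ann_idx <- match(res$probe_id, annot$probe_id)
  res$chromosome <- annot$chromosome[ann_idx]
  res$position <- annot$position[ann_idx]
  res[, c("probe_id", "class", "chromosome", "position", "p_value",
          "q_value", "delta", "direction", "degenerate")]
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up false discovery rate adjustment with enforced
#' monotonicity.  The paper-facing convention is to apply it separately
#' within each probe class, which [scan_bops()] and [scan_sites()] do.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return Vector of q-values in input order (empty input gives an empty
#'   vector).
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  p.adjust(p, method = "BH")
}

#' Chromosome-wise beta distribution comparison
#'
#' For every chromosome and every pair of groups, pools all (probe, sample)
#' beta values of the chromosome within each group and compares the two
#' pooled samples with a two-sample Kolmogorov-Smirnov test.  P-values are
#' Bonferroni-corrected by the number of chromosome-by-pair tests.  For
#' reporting, each group's pooled values are summarized as a 100-bin
#' density histogram on `[0, 1]` (attached as the `"histograms"` attribute).
#'
#' @param beta QC'd beta matrix.
#' @param annot probe annotation table.
#' @param groups named list of sample-id vectors (e.g. DSP / DSS / DSM).
#' @param bins number of equal-width histogram bins on `[0, 1]`.
#' @return `data.frame` with `chromosome`, `pair`, `ks_statistic`, `p_raw`
#'   and `bonferroni_p`.
#' @export
chromosome_distribution_test <- function(beta, annot, groups, bins = 100) {
  if (any(!lengths(groups))) stop("empty group(s): ",
                                  paste(names(groups)[!lengths(groups)],
                                        collapse = ", "))
  chrom <- annot$chromosome[match(rownames(beta), annot$probe_id)]
  chroms <- unique(chrom[!is.na(chrom)])
  chroms <- chroms[order(suppressWarnings(as.numeric(chroms)), chroms)]
  pairs <- combn(names(groups), 2, simplify = FALSE)
  n_tests <- length(chroms) * length(pairs)
  breaks <- seq(0, 1, length.out = bins + 1)

  hists <- list()
  rows <- list()
  k <- 0
  for (ch in chroms) {
    probes <- which(chrom == ch)
    pooled <- lapply(groups, function(ids) {
      as.vector(beta[probes, ids, drop = FALSE])
    })
    for (g in names(groups)) {
      hists[[paste(ch, g, sep = "|")]] <-
        hist(pooled[[g]], breaks = breaks, plot = FALSE)$density
    }
    for (pr in pairs) {
      kt <- suppressWarnings(ks.test(pooled[[pr[1]]], pooled[[pr[2]]]))
      k <- k + 1
      rows[[k]] <- data.frame(
        chromosome = ch, pair = paste(pr, collapse = " vs "),
        ks_statistic = unname(kt$statistic), p_raw = kt$p.value,
        bonferroni_p = min(1, kt$p.value * n_tests))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "histograms") <- hists
  attr(out, "n_tests") <- n_tests
  out
}
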