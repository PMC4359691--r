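#' @name cell_deconvolution
#' @title Reference-based leukocyte deconvolution
#' @description
#' Whole-blood methylation is a mixture of cell-type-specific methylomes, so
#' differences in leukocyte composition between groups masquerade as
#' differential methylation.  Following the constrained-projection approach,
#' the most cell-type-informative CpGs are selected from a sorted-cell
#' reference by a one-way F statistic across cell types, and each target
#' sample's composition is estimated by non-negative least squares against
#' the per-cell-type mean reference profiles, normalized to sum to one.  The
#' estimated fractions are then used as covariates in the differential
#' methylation scans.
NULL

#' Default leukocyte cell-type labels
#'
#' Short labels for the six whole-blood compartments modelled throughout the
#' package: CD19+ B cells, CD3+CD4+ T cells, CD3+CD8+ T cells, granulocytes,
#' CD14+ monocytes and CD56+ NK cells.
#'
#' @return Character vector of length six.
#' @export
leukocyte_types <- function() {
  c("Bcell", "CD4T", "CD8T", "Gran", "Mono", "NK")
}

#' Rank reference CpGs by cell-type informativeness
#'
#' Informativeness is the one-way analysis-of-variance F statistic of the CpG
#' across cell types (between-type over within-type mean square).  CpGs with
#' zero within-type variance but distinct type means rank first (infinite F);
#' ties are broken by CpG id.
#'
#' @param ref reference beta matrix, CpGs x reference samples.
#' @param cell_type cell-type label per reference sample.
#' @param n number of CpGs to return.
#' @return Character vector of the `n` top-ranked CpG ids, most informative
#'   first.
#' @export
select_informative_cpgs <- function(ref, cell_type, n = 500) {
  if (length(cell_type) != ncol(ref)) {
    stop("cell_type must have one label per reference sample")
  }
  types <- unique(cell_type)
  if (length(types) < 2) stop("reference must contain >= 2 cell types")
  if (n < length(types)) {
    stop("n (", n, ") must be at least the number of cell types (",
         length(types), ")")
  }
  if (n > nrow(ref)) {
    stop("requested ", n, " CpGs but reference has only ", nrow(ref))
  }

  grand <- rowMeans(ref)
  ssb <- 0
  ssw <- 0
  for (ty in types) {
    cols <- which(cell_type == ty)
    m <- rowMeans(ref[, cols, drop = FALSE])
    ssb <- ssb + length(cols) * (m - grand)^2
    ssw <- ssw + rowSums((ref[, cols, drop = FALSE] - m)^2)
  }
  df_b <- length(types) - 1
  df_w <- ncol(ref) - length(types)
  f <- (ssb / df_b) / (ssw / max(df_w, 1))
  f[ssw == 0 & ssb > 0] <- Inf
  f[ssb == 0] <- 0
  ids <- rownames(ref)
  ids[order(-f, ids)][seq_len(n)]
}

#' Estimate leukocyte proportions by constrained projection
#'
#' For each target sample, solves `min || y - S x ||^2` subject to `x >= 0`,
#' where `y` is the sample's beta vector over the selected sites and `S` the
#' per-cell-type mean reference matrix, then normalizes `x` to sum to one.
#' Sites missing from either matrix are dropped with a warning (their count
#' is reported).
#'
#' @param beta target beta matrix (probes x samples).
#' @param ref reference beta matrix (CpGs x reference samples).
#' @param cell_type cell-type label per reference sample.
#' @param sites CpG ids to project on (e.g. from
#'   [select_informative_cpgs()]).
#' @return List with `proportions` (samples x cell types, rows sum to 1),
#'   `raw` (the unnormalized non-negative solutions), `n_sites_used` and
#'   `n_sites_missing`.
#' @export
estimate_cell_proportions <- function(beta, ref, cell_type, sites) {
  present <- sites[sites %in% rownames(beta) & sites %in% rownames(ref)]
  n_missing <- length(sites) - length(present)
  if (n_missing > 0) {
    warning(n_missing, " of ", length(sites),
            " sites missing from target or reference; using ",
            length(present))
  }
  types <- sort(unique(cell_type))
  if (length(present) < length(types)) {
    stop("too few usable sites (", length(present), ") for ",
         length(types), " cell types")
  }
  S <- vapply(types, function(ty) {
    rowMeans(ref[present, cell_type == ty, drop = FALSE])
  }, numeric(length(present)))
  if (qr(S)$rank < ncol(S)) {
    stop("reference matrix is rank-deficient over the chosen sites; ",
         "use more informative sites")
  }
  raw <- t(apply(beta[present, , drop = FALSE], 2, function(y) {
    pracma::lsqnonneg(S, y)$x
  }))
  dimnames(raw) <- list(colnames(beta), types)
  tot <- rowSums(raw)
  if (any(tot == 0)) stop("all-zero projection for sample(s): ",
                          paste(rownames(raw)[tot == 0], collapse = ", "))
  list(proportions = raw / tot, raw = raw,
       n_sites_used = length(present), n_sites_missing = n_missing)
}

#' Compare estimated with measured cell proportions
#'
#' @param est estimated proportions matrix (samples x cell types).
#' @param measured measured fractions matrix with matching dimnames (a
#'   superset or subset of samples is allowed; >= 3 overlapping samples are
#'   required).
#' @return Per-cell-type `data.frame` with `bias` (mean estimated minus
#'   measured), `rmse` and Spearman `rank_correlation`.
#' @export
compare_proportions <- function(est, measured) {
  samples <- intersect(rownames(est), rownames(measured))
  if (length(samples) < 3) {
    stop("need >= 3 overlapping samples, found ", length(samples))
  }
  types <- intersect(colnames(est), colnames(measured))
  if (!length(types)) stop("no overlapping cell types")
  e <- est[samples, types, drop = FALSE]
  m <- measured[samples, types, drop = FALSE]
  data.frame(
    cell_type = types,
    bias = unname(colMeans(e - m)),
    rmse = unname(sqrt(colMeans((e - m)^2))),
    rank_correlation = unname(vapply(types, function(ty) {
      suppressWarnings(cor(e[, ty], m[, ty], method = "spearman"))
    }, 0)),
    row.names = NULL)
}
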