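#' @name preprocessing
#' @title Beta-matrix quality control
#' @description
#' Sample- and probe-level detection-p filters for a beta-value / detection-p
#' matrix pair.  A sample is dropped when strictly more than a fraction of its
#' probes fail detection at a stringent threshold; probes are then removed, in
#' order, when (1) they fail detection in strictly more than a fraction of the
#' surviving samples, (2) they contain any missing beta value, or (3) they map
#' to a sex chromosome.  The rules are applied sequentially so removal counts
#' are disjoint.
NULL

#' Read / write a beta or detection-p matrix
#'
#' Tab-separated, probes in rows, first column the probe id, header row of
#' sample ids.  Gzip-compressed files are accepted.
#'
#' @param path file path.
#' @return `read_beta_matrix` returns a numeric matrix with probe-id rownames
#'   and sample-id colnames.
#' @export
read_beta_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_beta_matrix
#' @param m matrix to write.
#' @param id_name header for the first (probe id) column.
#' @export
write_beta_matrix <- function(m, path, id_name = "probe_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_name
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.check_aligned <- function(beta, detp) {
  if (!identical(dim(beta), dim(detp)) ||
      !identical(rownames(beta), rownames(detp)) ||
      !identical(colnames(beta), colnames(detp))) {
    stop("beta and detection-p matrices are not label-aligned")
  }
}

#' Sample-level quality control
#'
#' Drops a sample iff strictly more than `frac` of its probes have detection
#' p-value > `p_thresh`.
#'
#' @param beta beta matrix (probes x samples).
#' @param detp detection-p matrix, label-aligned with `beta`.
#' @param frac failing-probe fraction above which a sample is dropped.
#' @param p_thresh detection p-value threshold defining a failed probe.
#' @return List with `retained` (sample ids) and `report` (per-sample failing
#'   fraction and retention flag).
#' @export
sample_qc <- function(beta, detp, frac = 0.75, p_thresh = 1e-5) {
  .check_aligned(beta, detp)
  failing <- colMeans(detp > p_thresh)
  retained <- failing <= frac
  list(retained = colnames(beta)[retained],
       report = data.frame(sample_id = colnames(beta),
                           failing_fraction = unname(failing),
                           retained = unname(retained)))
}

#' Probe-level quality control
#'
#' Applies, in order: (1) removal of probes with detection p > `p_thresh` in
#' strictly more than `frac` of samples; (2) removal of probes with any
#' missing beta value; (3) removal of probes on chromosomes X or Y.  Each
#' probe is attributed to the first rule that removes it, so the per-rule
#' counts plus the retained count equal the input probe count.
#'
#' @inheritParams sample_qc
#' @param annot probe annotation table covering every probe in `beta`.
#' @param p_thresh detection p-value threshold (probe-level default 0.05).
#' @return List with the filtered `beta` and `detp` matrices and a `report`
#'   list: `n_input`, `removed_detection`, `removed_missing`, `removed_sex`,
#'   `n_retained` and the dropped probe ids per rule.
#' @export
probe_qc <- function(beta, detp, annot, frac = 0.75, p_thresh = 0.05) {
  .check_aligned(beta, detp)
  missing_annot <- setdiff(rownames(beta), annot$probe_id)
  if (length(missing_annot)) {
    stop("probe(s) in matrix but absent from annotations: ",
         paste(head(missing_annot, 5), collapse = ", "))
  }
  chrom <- annot$chromosome[match(rownames(beta), annot$probe_id)]

  rule1 <- rowMeans(detp > p_thresh) > frac
  rule2 <- !rule1 & !complete.cases(beta)
  rule3 <- !rule1 & !rule2 & chrom %in% c("X", "Y")
  keep <- !(rule1 | rule2 | rule3)

  list(beta = beta[keep, , drop = FALSE],
       detp = detp[keep, , drop = FALSE],
       report = list(
         n_input = nrow(beta),
         removed_detection = sum(rule1),
         removed_missing = sum(rule2),
         removed_sex = sum(rule3),
         n_retained = sum(keep),
         dropped_detection = rownames(beta)[rule1],
         dropped_missing = rownames(beta)[rule2],
         dropped_sex = rownames(beta)[rule3]))
}
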