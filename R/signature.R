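#' @name signature_enrichment
#' @title Signature selection, enrichment tests and cohort geometry
#' @description
#' Post-processing of the differential methylation scans: a stringent
#' delta-beta rule extracts an epigenetic signature from the significant
#' BOPs (at least `min_adjacent` genomically consecutive probes each moving
#' by more than `delta_thresh` in the same direction), chromosomes and
#' user-supplied gene sets are tested for DMR enrichment with two-tailed
#' Fisher exact tests, and the signature is summarized by representative
#' probes, per-family case-control differences, classical multidimensional
#' scaling and average-linkage hierarchical clustering.
NULL

# Longest run of TRUE values; returns c(start, length) of the first longest
# run, or c(NA, 0) when none.
.longest_run <- function(x) {
  if (!length(x) || !any(x)) return(c(NA_integer_, 0L))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values)
  best <- ok[which.max(r$lengths[ok])]
  c(starts[best], r$lengths[best])
}

#' Select the epigenetic signature from a BOP scan
#'
#' Keeps the BOPs that are significant at `q_thresh` and contain at least one
#' run of `min_adjacent` genomically consecutive probes, each with
#' `|delta| > delta_thresh`, moving in a consistent direction (set
#' `same_sign = FALSE` to drop the direction requirement and apply the
#' threshold to absolute deltas regardless of sign).
#'
#' @param scan a `bop_scan` from [scan_bops()].
#' @param delta_thresh minimum absolute group-mean difference per probe.
#' @param min_adjacent minimum number of consecutive qualifying probes.
#' @param q_thresh BOP-level significance cutoff.
#' @param same_sign require the qualifying run to share one direction.
#' @return `data.frame` with one row per selected BOP: `bop_id`, `class`,
#'   `q_value`, `run_probes` (the qualifying probes, `;`-separated),
#'   `run_length`, `direction` and `max_abs_delta`.  The hyper/hypo split is
#'   attached as the `"direction_split"` attribute.
#' @export
select_signature <- function(scan, delta_thresh = 0.15, min_adjacent = 2,
                             q_thresh = 0.05, same_sign = TRUE) {
  sig <- scan$results[!is.na(scan$results$q_value) &
                        scan$results$q_value < q_thresh, , drop = FALSE]
  pd <- scan$probe_deltas
  rows <- lapply(seq_len(nrow(sig)), function(i) {
    bid <- sig$bop_id[i]
    d <- pd[pd$bop_id == bid, , drop = FALSE]
    d <- d[order(d$position), , drop = FALSE]
    qual <- if (same_sign) {
      pos <- .longest_run(d$delta > delta_thresh)
      neg <- .longest_run(d$delta < -delta_thresh)
      if (pos[2] >= neg[2]) list(run = pos, dir = "hyper") else
        list(run = neg, dir = "hypo")
    } else {
      run <- .longest_run(abs(d$delta) > delta_thresh)
      list(run = run, dir = if (run[2] > 0 &&
                                mean(d$delta[run[1]:(run[1] + run[2] - 1)])
                                >= 0) "hyper" else "hypo")
    }
    if (qual$run[2] < min_adjacent) return(NULL)
    idx <- qual$run[1]:(qual$run[1] + qual$run[2] - 1)
    data.frame(bop_id = bid, class = sig$class[i], q_value = sig$q_value[i],
               run_probes = paste(d$probe_id[idx], collapse = ";"),
               run_length = qual$run[2], direction = qual$dir,
               max_abs_delta = max(abs(d$delta[idx])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(bop_id = character(), class = character(),
                      q_value = numeric(), run_probes = character(),
                      run_length = integer(), direction = character(),
                      max_abs_delta = numeric())
  }
  rownames(out) <- NULL
  attr(out, "direction_split") <- c(hyper = sum(out$direction == "hyper"),
                                    hypo = sum(out$direction == "hypo"))
  out
}

#' Most significant probe of a BOP
#'
#' Returns the probe with the smallest site-level p-value; ties are broken by
#' the smaller genomic position.
#'
#' @param probe_ids probes of the BOP.
#' @param p site-level p-values aligned with `probe_ids`.
#' @param positions genomic positions aligned with `probe_ids`.
#' @return A single probe id.
#' @export
representative_probe <- function(probe_ids, p, positions) {
  keep <- !is.na(p)
  if (!any(keep)) stop("no tested probes in BOP")
  probe_ids <- probe_ids[keep]
  p <- p[keep]
  positions <- positions[keep]
  probe_ids[order(p, positions)][1]
}

#' Representative probes for a set of BOPs
#'
#' Applies [representative_probe()] to each BOP of a scan, using site-level
#' p-values from an ANOVA run over the BOP probes.
#'
#' @param scan a `bop_scan`.
#' @param site_p named vector of site-level p-values (names are probe ids).
#' @param bop_ids BOPs to summarize (default: all tested BOPs).
#' @return `data.frame` with `bop_id` and `probe_id`.
#' @export
representative_probes <- function(scan, site_p, bop_ids = NULL) {
  pd <- scan$probe_deltas
  if (is.null(bop_ids)) bop_ids <- unique(scan$results$bop_id)
  rows <- lapply(bop_ids, function(bid) {
    d <- pd[pd$bop_id == bid, , drop = FALSE]
    data.frame(bop_id = bid,
               probe_id = representative_probe(d$probe_id,
                                               site_p[d$probe_id],
                                               d$position))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.fisher_row <- function(a, b, c, d, unit) {
  or <- if (b * c > 0) (a * d) / (b * c) else
    if (a * d > 0) Inf else NA_real_
  p <- fisher.test(matrix(c(a, c, b, d), 2), alternative = "two.sided")$p.value
  data.frame(unit = unit, a = a, b = b, c = c, d = d, odds_ratio = or,
             p_value = p, stringsAsFactors = FALSE)
}

#' Chromosomal enrichment of DMRs
#'
#' For each chromosome, builds the 2x2 table of (significant vs not) by (on
#' vs off the chromosome) over the tested units (BOPs for classes A/B,
#' probes for C/D), and applies a two-tailed Fisher exact test.  The odds
#' ratio is the closed form `(a d)/(b c)`; q-values are BH across
#' chromosomes.
#'
#' @param units `data.frame` with columns `chromosome` and `significant`
#'   (logical), one row per tested unit.
#' @return `data.frame` with `unit` (chromosome), counts `a` (significant,
#'   on-chromosome), `b` (significant, off), `c` (not significant, on),
#'   `d` (not significant, off), `odds_ratio`, `p_value`, `q_value`,
#'   `direction` and `significant` flag at q < 0.05.
#' @export
chromosome_enrichment <- function(units) {
  chroms <- unique(units$chromosome)
  chroms <- chroms[order(suppressWarnings(as.numeric(chroms)), chroms)]
  rows <- lapply(chroms, function(ch) {
    on <- units$chromosome == ch
    .fisher_row(a = sum(on & units$significant),
                b = sum(!on & units$significant),
                c = sum(on & !units$significant),
                d = sum(!on & !units$significant),
                unit = ch)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out$direction <- ifelse(is.na(out$odds_ratio), NA_character_,
                          ifelse(out$odds_ratio > 1, "enriched", "depleted"))
  out$significant <- out$q_value < 0.05
  rownames(out) <- NULL
  out
}

#' Gene-set enrichment by Fisher exact test
#'
#' Two-tailed Fisher exact test of each collection against the DMR gene list,
#' with the universe restricted to the tested genes; collection members
#' outside the universe are ignored and duplicated symbols count once.
#'
#' @param dmr_genes character vector of genes hit by DMRs.
#' @param universe character vector of all tested genes.
#' @param collections named list of gene sets (e.g. from [read_gmt()]).
#' @return `data.frame` as in [chromosome_enrichment()], one row per
#'   collection.
#' @export
geneset_fisher <- function(dmr_genes, universe, collections) {
  universe <- unique(toupper(universe))
  if (!length(universe)) stop("empty gene universe")
  dmr <- intersect(unique(toupper(dmr_genes)), universe)
  rows <- lapply(names(collections), function(nm) {
    set <- intersect(unique(toupper(collections[[nm]])), universe)
    .fisher_row(a = length(intersect(set, dmr)),
                b = length(setdiff(dmr, set)),
                c = length(setdiff(set, dmr)),
                d = length(universe) - length(union(set, dmr)),
                unit = nm)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out$direction <- ifelse(is.na(out$odds_ratio), NA_character_,
                          ifelse(out$odds_ratio > 1, "enriched", "depleted"))
  out$significant <- out$q_value < 0.05
  rownames(out) <- NULL
  out
}

#' Read / write gene-set collections in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path file path.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, "", 1)
  sets
}

#' @rdname read_gmt
#' @param sets named list of gene sets.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Per-family case-control differences over the signature probes
#'
#' For each family contributing exactly one case and one control sample,
#' computes the difference of methylation (case minus control) at every
#' signature probe.  Additive shifts shared by both members of a family
#' (genetic background, shared environment, a family-confounded batch)
#' cancel in this matrix, which is the rationale of the trio design.
#'
#' @param beta beta matrix.
#' @param sheet sample sheet with `sample_id`, `family` and `group` columns.
#' @param probes representative signature probe ids.
#' @param groups the case and control group labels.
#' @return List with `differences` (families x probes matrix) and
#'   `clustering` (average-linkage `hclust` of the family rows; `NULL` for
#'   fewer than 2 families).  Incomplete families are excluded with a
#'   warning.
#' @export
family_pair_differences <- function(beta, sheet, probes,
                                    groups = c("DSP", "DSS")) {
  fams <- unique(sheet$family)
  rows <- list()
  skipped <- character()
  for (fam in fams) {
    case <- sheet$sample_id[sheet$family == fam & sheet$group == groups[1]]
    ctrl <- sheet$sample_id[sheet$family == fam & sheet$group == groups[2]]
    if (length(case) != 1 || length(ctrl) != 1 ||
        !all(c(case, ctrl) %in% colnames(beta))) {
      skipped <- c(skipped, fam)
      next
    }
    rows[[fam]] <- beta[probes, case] - beta[probes, ctrl]
  }
  if (length(skipped)) {
    warning("excluded incomplete family(ies): ",
            paste(skipped, collapse = ", "))
  }
  if (!length(rows)) stop("no complete families")
  m <- do.call(rbind, rows)
  colnames(m) <- probes
  clustering <- if (nrow(m) >= 2) hierarchical_cluster(m, "rows") else NULL
  list(differences = m, clustering = clustering)
}

#' Classical multidimensional scaling of samples
#'
#' Classical (metric) MDS on Euclidean distances between the rows of the
#' input matrix.  The orientation is fixed by a sign convention: on each
#' axis, the first sample with a non-zero coordinate is made non-negative.
#' A configuration of rank < 2 gets a zero second axis and the
#' `"rank_deficient"` attribute.
#'
#' @param m samples x features matrix (e.g. samples by representative
#'   signature probes), no missing values.
#' @return samples x 2 coordinate matrix.
#' @export
mds_embedding <- function(m) {
  if (nrow(m) < 3) stop("need >= 3 samples")
  if (anyNA(m)) stop("missing values in input")
  fit <- suppressWarnings(cmdscale(dist(m), k = 2, eig = TRUE))
  xy <- fit$points
  eig <- fit$eig
  rank_def <- ncol(xy) < 2 ||
    sum(eig > max(eig, 0) * 1e-8) < 2
  if (ncol(xy) < 2) xy <- cbind(xy, 0)
  if (rank_def) xy[, 2] <- 0
  for (j in 1:2) {
    nz <- which(abs(xy[, j]) > 1e-12)
    if (length(nz) && xy[nz[1], j] < 0) xy[, j] <- -xy[, j]
  }
  rownames(xy) <- rownames(m)
  colnames(xy) <- c("dim1", "dim2")
  attr(xy, "rank_deficient") <- rank_def
  xy
}

#' Average-linkage hierarchical clustering
#'
#' Euclidean distance, average linkage.  Items are ordered by label before
#' clustering so the leaf order is deterministic under distance ties.
#'
#' @param m data matrix.
#' @param axis cluster the `"rows"` or the `"cols"` of `m`.
#' @return An `hclust` object.
#' @export
hierarchical_cluster <- function(m, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  if (axis == "cols") m <- t(m)
  if (nrow(m) < 2) stop("need >= 2 items to cluster")
  if (anyNA(m)) stop("missing values in input")
  m <- m[order(rownames(m)), , drop = FALSE]
  hclust(dist(m), method = "average")
}

#' Dendrogram as a Newick string
#'
#' @param hc an `hclust` object.
#' @return Newick string (requires the `ape` package).
#' @export
as_newick <- function(hc) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("the 'ape' package is required for newick export")
  }
  ape::write.tree(ape::as.phylo(hc))
}
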