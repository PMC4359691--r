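#' @name array_annotation
#' @title Probe annotation, classification and BOP construction
#' @description
#' Probes on CpG-dense arrays are described by their relation to a CpG island
#' (the island itself, its 0-2 kb shores, its 2-4 kb shelves, or none of these,
#' the "open sea") and by the genes they are annotated to.  Crossing the two
#' yields four probe classes: A (CpG-island context, genic), B (CpG-island
#' context, non-genic), C (open sea, genic) and D (open sea, non-genic).
#' Class A and B probes falling in the same island, the same shore or the same
#' shelf (and, for class A, annotated to the same gene) form a block of probes
#' (BOP), the unit of the region-level differential methylation scan.
NULL

.island_relations <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf",
                       "OpenSea")

#' Manifest column mapping
#'
#' Names the manifest columns holding each annotation field.  Defaults follow
#' the Illumina 450k manifest dialect.
#'
#' @param probe_id,chromosome,position,island_relation,genes,island_id column
#'   names in the manifest file.
#' @return Named list of column names.
#' @export
manifest_columns <- function(probe_id = "IlmnID",
                             chromosome = "CHR",
                             position = "MAPINFO",
                             island_relation = "RELATION_TO_UCSC_CPG_ISLAND",
                             genes = "UCSC_REFGENE_NAME",
                             island_id = "UCSC_CPG_ISLANDS_NAME") {
  list(probe_id = probe_id, chromosome = chromosome, position = position,
       island_relation = island_relation, genes = genes,
       island_id = island_id)
}

#' Parse a manifest-dialect probe annotation table
#'
#' Reads a CSV manifest and returns one annotation row per probe.  An empty
#' island-relation cell means open sea (the manifest convention of leaving the
#' cell blank).  Multi-gene cells are split on `gene_delim`, trimmed,
#' uppercased and deduplicated.  Chromosome labels are normalized by stripping
#' any `"chr"` prefix.
#'
#' @param path path to a CSV file in the manifest dialect.
#' @param columns column mapping, see [manifest_columns()].
#' @param gene_delim delimiter separating gene symbols within one cell.
#' @return A `data.frame` with columns `probe_id`, `chromosome`, `position`
#'   (1-based bp), `island_relation`, `island_id` (`""` for open-sea probes)
#'   and the list-column `genes` (character vector per probe, possibly empty).
#' @export
parse_manifest <- function(path, columns = manifest_columns(),
                           gene_delim = ";") {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
  as_probe_annotation(raw, columns = columns, gene_delim = gene_delim)
}

#' Coerce a raw manifest table to probe annotations
#'
#' In-memory counterpart of [parse_manifest()], used both by the parser and by
#' the synthetic manifest generator.
#'
#' @param manifest a `data.frame` in the manifest dialect.
#' @inheritParams parse_manifest
#' @return See [parse_manifest()].
#' @export
as_probe_annotation <- function(manifest, columns = manifest_columns(),
                                gene_delim = ";") {
  for (field in c("probe_id", "chromosome", "position", "island_relation",
                  "genes")) {
    if (!columns[[field]] %in% names(manifest)) {
      stop("manifest is missing required column '", columns[[field]],
           "' (", field, ")")
    }
  }
  has_island_col <- columns$island_id %in% names(manifest)

  pos_chr <- trimws(as.character(manifest[[columns$position]]))
  position <- suppressWarnings(as.numeric(pos_chr))
  bad <- which(is.na(position))
  if (length(bad)) {
    stop("unparseable position '", pos_chr[bad[1]], "' at manifest row ",
         bad[1])
  }

  relation <- trimws(as.character(manifest[[columns$island_relation]]))
  relation[relation == "" | is.na(relation)] <- "OpenSea"
  unknown <- setdiff(unique(relation), .island_relations)
  if (length(unknown)) {
    stop("unknown island relation value(s): ",
         paste(unknown, collapse = ", "))
  }

  genes_raw <- as.character(manifest[[columns$genes]])
  genes_raw[is.na(genes_raw)] <- ""
  genes <- lapply(strsplit(genes_raw, gene_delim, fixed = TRUE), function(g) {
    g <- unique(toupper(trimws(g)))
    g[nzchar(g)]
  })

  island_id <- if (has_island_col) {
    trimws(as.character(manifest[[columns$island_id]]))
  } else {
    rep("", nrow(manifest))
  }
  island_id[is.na(island_id)] <- ""
  island_id[relation == "OpenSea"] <- ""

  annot <- data.frame(
    probe_id = trimws(as.character(manifest[[columns$probe_id]])),
    chromosome = sub("^chr", "", trimws(as.character(
      manifest[[columns$chromosome]]))),
    position = as.integer(position),
    island_relation = relation,
    island_id = island_id,
    stringsAsFactors = FALSE
  )
  annot$genes <- genes
  if (anyDuplicated(annot$probe_id)) {
    stop("duplicated probe ids in manifest")
  }
  annot
}

#' Classify probes into classes A-D
#'
#' Class A: CpG-island context (island/shore/shelf) and genic; B: CpG-island
#' context, non-genic; C: open sea, genic; D: open sea, non-genic.  Every
#' probe receives exactly one label.
#'
#' @param annot probe annotation table from [parse_manifest()].
#' @return Character vector of labels `"A"`, `"B"`, `"C"`, `"D"`, one per
#'   probe.
#' @export
classify_probes <- function(annot) {
  genic <- lengths(annot$genes) > 0
  cgi <- annot$island_relation != "OpenSea"
  ifelse(cgi, ifelse(genic, "A", "B"), ifelse(genic, "C", "D"))
}

#' Group class A/B probes into blocks of probes (BOPs)
#'
#' A BOP collects the probes lying in the same island, the same shore or the
#' same shelf; shores and shelves on opposite sides of an island are distinct
#' BOPs.  Class A BOPs are additionally keyed by gene, so a probe annotated to
#' k genes contributes to k class A BOPs (set `multi_gene = "first"` to key by
#' the first gene only).  Within a BOP, probes are ordered by genomic
#' position.
#'
#' @param annot probe annotation table.
#' @param multi_gene `"per_gene"` (default) or `"first"`.
#' @return A membership `data.frame` with one row per (BOP, probe) pair:
#'   `bop_id`, `class`, `gene` (`NA` for class B), `island_id`,
#'   `island_relation`, `chromosome`, `probe_id`, `position`.
#' @export
build_bops <- function(annot, multi_gene = c("per_gene", "first")) {
  multi_gene <- match.arg(multi_gene)
  cls <- classify_probes(annot)
  keep <- cls %in% c("A", "B")
  ab <- annot[keep, , drop = FALSE]
  cls <- cls[keep]
  if (any(ab$island_id == "")) {
    stop("probe(s) with island relation but no island id: ",
         paste(head(ab$probe_id[ab$island_id == ""], 5), collapse = ", "))
  }

  rows <- vector("list", 2L)
  is_b <- cls == "B"
  if (any(is_b)) {
    b <- ab[is_b, , drop = FALSE]
    rows[[1]] <- data.frame(
      class = "B", gene = NA_character_, island_id = b$island_id,
      island_relation = b$island_relation, chromosome = b$chromosome,
      probe_id = b$probe_id, position = b$position, stringsAsFactors = FALSE)
  }
  if (any(!is_b)) {
    a <- ab[!is_b, , drop = FALSE]
    glist <- a$genes
    if (multi_gene == "first") glist <- lapply(glist, `[`, 1L)
    n_rep <- lengths(glist)
    idx <- rep(seq_len(nrow(a)), n_rep)
    rows[[2]] <- data.frame(
      class = "A", gene = unlist(glist), island_id = a$island_id[idx],
      island_relation = a$island_relation[idx], chromosome = a$chromosome[idx],
      probe_id = a$probe_id[idx], position = a$position[idx],
      stringsAsFactors = FALSE)
  }
  memb <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  memb$bop_id <- ifelse(
    memb$class == "A",
    paste("A", memb$gene, memb$island_id, memb$island_relation, sep = "|"),
    paste("B", memb$island_id, memb$island_relation, sep = "|"))
  memb <- memb[order(memb$bop_id, memb$position),
               c("bop_id", "class", "gene", "island_id", "island_relation",
                 "chromosome", "probe_id", "position")]
  rownames(memb) <- NULL
  memb
}

#' Summarize BOP sizes
#'
#' @param bops BOP membership table from [build_bops()].
#' @return A `data.frame` with counts of BOPs containing 1, 2 and >= 3
#'   probes (the region scan only tests BOPs with >= 3 probes).
#' @export
bop_size_summary <- function(bops) {
  sizes <- table(bops$bop_id)
  data.frame(
    size = c("1", "2", ">=3"),
    n_bops = c(sum(sizes == 1), sum(sizes == 2), sum(sizes >= 3)),
    n_probes = c(sum(sizes[sizes == 1]), sum(sizes[sizes == 2]),
                 sum(sizes[sizes >= 3])))
}

#' Write / read a BOP membership table
#'
#' Tab-separated persistence of [build_bops()] output; reading back
#' reproduces identical region keys.
#'
#' @param bops BOP membership table.
#' @param path file path.
#' @return `read_bop_table` returns the membership `data.frame`.
#' @export
write_bop_table <- function(bops, path) {
  write.table(bops, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bop_table
#' @export
read_bop_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(position = "integer"))
}

#' Write probe class assignments
#'
#' @param annot probe annotation table.
#' @param path file path for the tab-separated probe -> class table.
#' @export
write_probe_classes <- function(annot, path) {
  out <- data.frame(probe_id = annot$probe_id,
                    chromosome = annot$chromosome,
                    position = annot$position,
                    island_relation = annot$island_relation,
                    class = classify_probes(annot),
                    genes = vapply(annot$genes, paste, "", collapse = ";"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export BOP intervals as BED
#'
#' Converts the 1-based inclusive manifest coordinates of each BOP's probes to
#' a 0-based half-open interval spanning the block.
#'
#' @param bops BOP membership table.
#' @param path output BED path.
#' @export
write_bop_bed <- function(bops, path) {
  sp <- split(bops, bops$bop_id)
  bed <- data.frame(
    chrom = vapply(sp, function(b) paste0("chr", b$chromosome[1]), ""),
    start = vapply(sp, function(b) min(b$position) - 1L, 0L),
    end = vapply(sp, function(b) max(b$position), 0L),
    name = names(sp))
  bed <- bed[order(bed$chrom, bed$start), ]
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
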