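# Shared fixture builders (everything is generated in code; nothing on disk).

# A small raw manifest data.frame in the Illumina dialect.
toy_manifest <- function() {
  data.frame(
    IlmnID = sprintf("cg%03d", 1:8),
    CHR = c("21", "chr21", "21", "1", "1", "X", "2", "Y"),
    MAPINFO = c(100, 200, 2500, 300, 400, 500, 600, 700),
    RELATION_TO_UCSC_CPG_ISLAND = c("Island", "Island", "N_Shore", "",
                                    "", "", "S_Shelf", ""),
    UCSC_REFGENE_NAME = c("RUNX1;RUNX1", "RUNX1", "RUNX1", "GENE1;GENE2",
                          "", "", "", ""),
    UCSC_CPG_ISLANDS_NAME = c("chr21:3000-4000", "chr21:3000-4000",
                              "chr21:3000-4000", "", "", "",
                              "chr2:100-200", ""),
    stringsAsFactors = FALSE)
}

# Sample sheet for a plain two-group design (no families).
toy_sheet <- function(n_per_group = 20, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    group = rep(c("DSP", "DSS"), each = n_per_group),
    sex = sample(c("M", "F"), n, replace = TRUE),
    batch = sample(c("B1", "B2"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# A hand-built bop_scan-shaped object: per-BOP q-values and per-probe
# deltas, as produced by scan_bops().  deltas is a named list of numeric
# vectors; BOPs with < 3 probes go to the excluded table (never tested).
fake_scan <- function(deltas, q = 0.01) {
  tested <- names(deltas)[lengths(deltas) >= 3]
  small <- setdiff(names(deltas), tested)
  pd <- do.call(rbind, lapply(names(deltas), function(b) {
    d <- deltas[[b]]
    data.frame(bop_id = b, class = "A",
               probe_id = sprintf("%s_p%d", b, seq_along(d)),
               position = seq_along(d) * 100L, delta = d,
               stringsAsFactors = FALSE)
  }))
  results <- data.frame(
    bop_id = tested, class = "A", chromosome = "1",
    start = 1L, end = 1000L,
    n_probes = lengths(deltas)[tested],
    n_windows = lengths(deltas)[tested] - 2L,
    min_p = q / 10, q_value = q,
    best_window = NA_character_,
    delta = vapply(deltas[tested], mean, 0),
    direction = "hyper", degenerate = FALSE,
    stringsAsFactors = FALSE)
  structure(list(results = results,
                 probe_deltas = pd[pd$bop_id %in% tested, ],
                 excluded = data.frame(bop_id = small,
                                       n_probes = lengths(deltas)[small],
                                       reason = rep("fewer than 3 probes",
                                                    length(small))),
                 statistic = "pillai"),
            class = "bop_scan")
}
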