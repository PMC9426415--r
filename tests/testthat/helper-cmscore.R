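# Builders for hand-crafted Ct tables and calibrations used across tests.

cm_cfg <- assay_config()
cm_genes <- cm_cfg$panel$target_genes
cm_layout <- cm_cfg$layout$cartridges

# Cartridge of a target gene under the default layout
gene_cartridge <- function(gene) {
  for (cid in names(cm_layout)) {
    if (gene %in% cm_layout[[cid]]) return(cid)
  }
  stop("not a panel gene: ", gene)
}

# One sample run as Ct-table rows. `cts` is a named vector over target
# genes (45 = no signal); unlisted genes default to no signal. `actb`
# gives the per-cartridge reference Ct.
run_from_cts <- function(sample_id, cts = numeric(0),
                         actb = c(A = 25, B = 25),
                         group_label = "unknown", matrix = "plasma",
                         draw_day = NA_integer_, subject_id = sample_id) {
  full <- structure(rep(45, length(cm_genes)), names = cm_genes)
  full[names(cts)] <- cts
  rows <- lapply(names(cm_layout), function(cid) {
    g <- cm_layout[[cid]]
    data.frame(sample_id = sample_id, subject_id = subject_id,
               group_label = group_label, matrix = matrix,
               draw_day = draw_day, cartridge_id = cid,
               gene = c(g, "ACTB"), ct = c(full[g], actb[[cid]]),
               no_signal = c(full[g], actb[[cid]]) == 45,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Calibration with one shared median for all nine genes
flat_calibration <- function(median = 3) {
  calibration_table(structure(rep(median, length(cm_genes)),
                              names = cm_genes))
}

# Brute-force AUC oracle: concordant-pair fraction with ties worth 1/2
auc_pair_count <- function(scores, labels) {
  cases <- scores[labels]
  ctrls <- scores[!labels]
  tot <- 0
  for (x in cases) for (y in ctrls) {
    tot <- tot + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  tot / (length(cases) * length(ctrls))
}
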