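#' Ct table column schema
#'
#' The native data currency of the pipeline is a long-format cycle-threshold
#' (Ct) table with one row per (sample, cartridge, gene) reaction:
#'
#' * `sample_id`, `subject_id` — identifiers (character).
#' * `group_label` — one of `cancer`, `benign`, `normal`, `unknown`.
#' * `matrix` — `plasma` or `serum`.
#' * `draw_day` — integer days from baseline (`NA` for single draws).
#' * `cartridge_id` — detection cartridge identifier (e.g. `A`/`B`).
#' * `gene` — target or reference gene name.
#' * `ct` — cycle threshold in cycles; equals the no-signal sentinel (45)
#'   when `no_signal` is true, otherwise strictly inside (0, 45).
#' * `no_signal` — logical; true when the reaction never amplified.
#'
#' @return Character vector of the nine schema column names, in order.
#' @export
ct_table_columns <- function() {
  c("sample_id", "subject_id", "group_label", "matrix", "draw_day",
    "cartridge_id", "gene", "ct", "no_signal")
}

group_levels <- function() c("cancer", "benign", "normal", "unknown")
matrix_levels <- function() c("plasma", "serum")

#' Validate one sample run against the cartridge layout
#'
#' A complete sample run covers every (cartridge, gene) cell of the layout
#' exactly once, including one reference (ACTB) measurement per cartridge.
#' Gene names are resolved against the panel case-insensitively; the
#' returned rows carry canonical upper-case names.
#'
#' @param run Data frame of Ct-table rows (see [ct_table_columns()]) for a
#'   single sample.
#' @param config An [assay_config()].
#' @return The validated run, with canonical gene and cartridge names.
#' @examples
#' sim <- simulate_spike_replicates(spike_design(copies = 300,
#'                                               replicates = 3), seed = 1)
#' run <- sim$ct[sim$ct$sample_id == sim$ct$sample_id[1], ]
#' nrow(validate_sample_run(run))
#' @export
validate_sample_run <- function(run, config = assay_config()) {
  stopifnot(is.data.frame(run))
  missing_cols <- setdiff(ct_table_columns(), names(run))
  if (length(missing_cols)) {
    stop("Ct table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (length(unique(run$sample_id)) != 1L) {
    stop("validate_sample_run() expects rows for exactly one sample",
         call. = FALSE)
  }
  sid <- run$sample_id[1]
  run$gene <- canonical_gene(run$gene)
  run$cartridge_id <- trimws(as.character(run$cartridge_id))

  layout <- config$layout
  panel <- config$panel
  known <- c(panel$target_genes, panel$reference_gene)
  unknown <- setdiff(unique(run$gene), known)
  if (length(unknown)) {
    stop("sample ", sid, ": unknown gene(s) not in panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  unknown_cart <- setdiff(unique(run$cartridge_id), names(layout$cartridges))
  if (length(unknown_cart)) {
    stop("sample ", sid, ": unknown cartridge id(s): ",
         paste(unknown_cart, collapse = ", "), call. = FALSE)
  }

  cells <- paste(run$cartridge_id, run$gene, sep = ":")
  expected <- unlist(lapply(names(layout$cartridges), function(id) {
    paste(id, c(layout$cartridges[[id]], layout$reference_gene), sep = ":")
  }), use.names = FALSE)
  dup <- unique(cells[duplicated(cells)])
  if (length(dup)) {
    stop("sample ", sid, ": duplicate (cartridge, gene) cell(s): ",
         paste0("(", sub(":", ", ", dup), ")", collapse = ", "),
         call. = FALSE)
  }
  miss <- setdiff(expected, cells)
  if (length(miss)) {
    stop("sample ", sid, ": missing (cartridge, gene) cell(s): ",
         paste0("(", sub(":", ", ", miss), ")", collapse = ", "),
         call. = FALSE)
  }
  stray <- setdiff(cells, expected)
  if (length(stray)) {
    stop("sample ", sid, ": gene measured in the wrong cartridge: ",
         paste0("(", sub(":", ", ", stray), ")", collapse = ", "),
         call. = FALSE)
  }

  ns <- as.logical(run$no_signal)
  if (anyNA(ns)) {
    stop("sample ", sid, ": no_signal must be TRUE/FALSE", call. = FALSE)
  }
  nsct <- config$constants$no_signal_ct
  bad_sentinel <- ns & run$ct != nsct
  if (any(bad_sentinel)) {
    stop("sample ", sid, ": no-signal rows must carry ct = ", nsct,
         " (gene ", paste(run$gene[bad_sentinel], collapse = ", "), ")",
         call. = FALSE)
  }
  bad_ct <- !ns & (!is.finite(run$ct) | run$ct <= 0 | run$ct >= nsct)
  if (any(bad_ct)) {
    stop("sample ", sid, ": ct must lie strictly in (0, ", nsct,
         ") unless flagged no-signal (gene ",
         paste(run$gene[bad_ct], collapse = ", "), ")", call. = FALSE)
  }
  run$no_signal <- ns

  if (!all(run$group_label %in% group_levels())) {
    stop("sample ", sid, ": group_label must be one of ",
         paste(group_levels(), collapse = "/"), call. = FALSE)
  }
  if (!all(run$matrix %in% matrix_levels())) {
    stop("sample ", sid, ": matrix must be one of ",
         paste(matrix_levels(), collapse = "/"), call. = FALSE)
  }
  run
}

#' Validate a full Ct table
#'
#' Applies [validate_sample_run()] to every sample in the table and returns
#' the canonicalized table, samples in first-appearance order.
#'
#' @param ct_table Long-format Ct table (see [ct_table_columns()]).
#' @param config An [assay_config()].
#' @return The validated, canonicalized table.
#' @export
validate_ct_table <- function(ct_table, config = assay_config()) {
  stopifnot(is.data.frame(ct_table))
  if (nrow(ct_table) == 0L) {
    stop("Ct table has no rows", call. = FALSE)
  }
  ids <- unique(ct_table$sample_id)
  out <- lapply(ids, function(sid) {
    validate_sample_run(ct_table[ct_table$sample_id == sid, , drop = FALSE],
                        config = config)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
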