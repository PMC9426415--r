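#' Read a Ct table CSV
#'
#' Parses the fixed-schema Ct table (see [ct_table_columns()]), checks the
#' header exactly, parses `ct` as a positive decimal (an empty `ct` cell
#' is allowed only with `no_signal` true, and is filled with the sentinel),
#' and validates every sample run against the layout. Parse and structure
#' errors name the offending file line.
#'
#' @param path CSV path.
#' @param config An [assay_config()].
#' @return A validated Ct table data frame.
#' @export
read_ct_table <- function(path, config = assay_config()) {
  if (!file.exists(path)) stop("Ct table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE)
  if (!identical(names(df), ct_table_columns())) {
    stop("Ct table header must be exactly: ",
         paste(ct_table_columns(), collapse = ","), call. = FALSE)
  }
  line <- seq_len(nrow(df)) + 1L  # header is line 1

  no_signal <- toupper(trimws(df$no_signal)) %in% c("TRUE", "T", "1")
  ct_chr <- trimws(df$ct)
  ct <- suppressWarnings(as.numeric(ct_chr))
  empty <- !nzchar(ct_chr)
  bad <- (!empty & (is.na(ct) | ct <= 0)) | (empty & !no_signal)
  if (any(bad)) {
    stop("line ", line[which(bad)[1]],
         ": ct must be a positive decimal (or empty with no_signal=true), got '",
         ct_chr[which(bad)[1]], "'", call. = FALSE)
  }
  ct[empty] <- config$constants$no_signal_ct

  out <- data.frame(sample_id = df$sample_id, subject_id = df$subject_id,
                    group_label = trimws(df$group_label),
                    matrix = trimws(df$matrix),
                    draw_day = suppressWarnings(as.integer(df$draw_day)),
                    cartridge_id = df$cartridge_id, gene = df$gene,
                    ct = ct, no_signal = no_signal,
                    stringsAsFactors = FALSE)

  key <- paste(out$sample_id, trimws(out$cartridge_id),
               canonical_gene(out$gene))
  dup <- duplicated(key)
  if (any(dup)) {
    stop("line ", line[which(dup)[1]], ": duplicate (sample, cartridge, ",
         "gene) row for ", key[which(dup)[1]], call. = FALSE)
  }
  validate_ct_table(out, config = config)
}

#' Write a Ct table CSV
#'
#' Deterministic output: fixed column order, rows in input order, Ct
#' serialized to 4 decimals (more precision than the 1-decimal instrument
#' convention, so that write/read round-trips are lossless for scoring).
#'
#' @param ct_table A Ct table data frame.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct_table, path) {
  df <- ct_table[, ct_table_columns()]
  df$ct <- formatC(df$ct, format = "f", digits = 4)
  df$no_signal <- ifelse(ct_table$no_signal, "true", "false")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Write a score report
#'
#' One row per sample, sorted by `sample_id`: metadata, the per-gene
#' post-shift/post-censor delta-Ct and methylation M (columns
#' `delta_ct.<GENE>` and `m.<GENE>` in panel order), the CM, and the
#' validity flag/reason. CSV and JSON mirrors carry identical content;
#' CM and delta-Ct are serialized at 4 decimals.
#'
#' @param scores A `cm_scores` object from [score_batch()].
#' @param path Output path; `.csv` or `.json`.
#' @param config An [assay_config()] (panel column order).
#' @return `path`, invisibly.
#' @export
write_score_report <- function(scores, path, config = assay_config()) {
  stopifnot(inherits(scores, "cm_scores"))
  wide <- score_report_frame(scores, config)
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "csv") {
    num <- vapply(wide, is.numeric, logical(1)) & names(wide) != "draw_day"
    wide[num] <- lapply(wide[num], function(v)
      ifelse(is.na(v), "", formatC(v, format = "f", digits = 4)))
    utils::write.csv(wide, path, row.names = FALSE, quote = FALSE, na = "")
  } else if (ext == "json") {
    jsonlite::write_json(wide, path, auto_unbox = TRUE, digits = 4,
                         na = "null", pretty = TRUE)
  } else {
    stop("unsupported score report format: .", ext, call. = FALSE)
  }
  invisible(path)
}

score_report_frame <- function(scores, config = assay_config()) {
  genes <- config$panel$target_genes
  samples <- scores$samples[order(scores$samples$sample_id), , drop = FALSE]
  g <- scores$genes
  wide <- samples[, c("sample_id", "subject_id", "group_label", "matrix",
                      "draw_day")]
  for (gn in genes) {
    sub <- g[g$gene == gn, ]
    wide[[paste0("delta_ct.", gn)]] <-
      sub$delta_ct[match(wide$sample_id, sub$sample_id)]
  }
  for (gn in genes) {
    sub <- g[g$gene == gn, ]
    wide[[paste0("m.", gn)]] <- sub$m[match(wide$sample_id, sub$sample_id)]
  }
  wide$cm <- samples$cm
  wide$valid <- samples$valid
  wide$invalid_reason <- samples$invalid_reason
  rownames(wide) <- NULL
  wide
}

#' Read a score report CSV back into a samples frame
#'
#' @param path Score-report CSV written by [write_score_report()].
#' @return Data frame with at least `sample_id`, `subject_id`,
#'   `group_label`, `matrix`, `draw_day`, `cm`, `valid`.
#' @export
read_score_report <- function(path) {
  if (!file.exists(path)) {
    stop("score report not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group_label", "cm", "valid")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("score report is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$valid <- as.logical(df$valid)
  df$cm <- suppressWarnings(as.numeric(df$cm))
  df
}

#' Write an evaluation report
#'
#' JSON (machine-readable, full precision within the stated rounding:
#' probabilities and AUC at 3 decimals, CM quantities at 1) plus an
#' optional human-readable TSV of the per-class descriptive statistics.
#'
#' @param evaluation A `cm_evaluation` from [evaluate_cohort()].
#' @param path Output `.json` path.
#' @param tsv_path Optional `.tsv` path for the descriptives table.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(evaluation, path, tsv_path = NULL) {
  stopifnot(inherits(evaluation, "cm_evaluation"))
  r1 <- function(x) round(x, 1)
  r3 <- function(x) round(x, 3)
  conf <- evaluation$confusion
  doc <- list(
    descriptives = lapply(seq_len(nrow(evaluation$descriptives)),
                          function(i) {
      row <- evaluation$descriptives[i, ]
      list(class = row$class, n = row$n, min = r1(row$min),
           q25 = r1(row$q25), median = r1(row$median), q75 = r1(row$q75),
           max = r1(row$max), mean = r1(row$mean),
           mean_ci = c(r1(row$mean_ci_lower), r1(row$mean_ci_upper)))
    }),
    mann_whitney = list(u = evaluation$mann_whitney$statistic,
                        p_value = evaluation$mann_whitney$p_value,
                        method = evaluation$mann_whitney$method),
    roc = list(auc = r3(evaluation$roc$auc),
               auc_ci = r3(evaluation$roc$auc_ci),
               best_threshold = r1(evaluation$roc$best_threshold)),
    threshold = r1(evaluation$threshold),
    threshold_derived = evaluation$threshold_derived,
    confusion = list(tp = conf$tp, fn = conf$fn, tn = conf$tn,
                     fp = conf$fp,
                     sensitivity = r3(conf$sensitivity),
                     specificity = r3(conf$specificity),
                     accuracy = r3(conf$accuracy),
                     lr_positive = if (conf$lr_defined)
                       r3(conf$lr_positive) else NULL,
                     lr_defined = conf$lr_defined)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  if (!is.null(tsv_path)) {
    utils::write.table(evaluation$descriptives, tsv_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write a run manifest
#'
#' Provenance record written into every CLI output directory: the
#' configuration and input paths, seed, stage, tool version and
#' timestamp. Sufficient (with the same package version) to re-run the
#' stage and reproduce its outputs byte-identically.
#'
#' @param dir Output directory.
#' @param stage Stage name (e.g. `"score"`).
#' @param inputs Named character vector/list of input paths.
#' @param seed Seed used (or `NA`).
#' @param extra Optional named list of extra fields.
#' @return The manifest path, invisibly.
#' @export
write_run_manifest <- function(dir, stage, inputs = list(), seed = NA,
                               extra = list()) {
  manifest <- c(list(
    tool = "cmscore",
    version = as.character(utils::packageVersion("cmscore")),
    stage = stage,
    inputs = as.list(inputs),
    output_dir = normalizePath(dir, mustWork = FALSE),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
  path <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
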