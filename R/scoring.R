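#' Reference-normalized delta-Ct
#'
#' Step one of the CM algorithm: normalize a target gene's cycle threshold
#' to the ACTB reference measured in the same cartridge,
#' `delta_ct = ct_gene - ct_reference`. A no-signal target (Ct at the
#' sentinel, 45) propagates as a large delta-Ct and is removed later by
#' censoring; a no-signal *reference* means the cartridge produced no
#' quantifiable cfDNA signal at all and invalidates the run.
#'
#' @param ct_gene Target gene Ct (cycles); may equal the no-signal sentinel.
#' @param ct_reference Reference (ACTB) Ct from the same cartridge.
#' @param constants [algorithm_constants()].
#' @return `ct_gene - ct_reference` (delta-Ct units; may be negative).
#' @examples
#' delta_ct(30, 25)
#' delta_ct(45, 25)  # no-signal target, censored downstream
#' @export
delta_ct <- function(ct_gene, ct_reference, constants = algorithm_constants()) {
  if (any(!is.finite(ct_gene)) || any(!is.finite(ct_reference))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  if (any(ct_reference >= constants$no_signal_ct)) {
    stop("reference gene has no signal (Ct = ", constants$no_signal_ct,
         "); the cartridge run is invalid", call. = FALSE)
  }
  ct_gene - ct_reference
}

#' Per-gene shift constants for a batch
#'
#' If any sample in the analysis batch has delta-Ct below one for a gene,
#' every sample's delta-Ct for that gene is raised by the smallest
#' nonnegative integer `k` such that `min(delta_ct) + k >= 1`. The same
#' `k` is added to that gene's historical calibration median before the
#' censoring comparison, so the censoring decision is identical on the raw
#' and shifted scales. Targeting a minimum of 1 (not merely positive)
#' bounds the gene methylation transform at `m_scale` per gene.
#'
#' @param delta_ct_by_gene Named list (or data frame) mapping each gene to
#'   the numeric vector of raw delta-Ct values observed across the batch.
#' @return Named integer vector of shift constants, one per gene.
#' @examples
#' compute_gene_shifts(list(HOXB4 = c(-2.4, 3.0), RASSF1 = c(5.0, 9.1)))
#' @export
compute_gene_shifts <- function(delta_ct_by_gene) {
  if (is.data.frame(delta_ct_by_gene)) {
    delta_ct_by_gene <- as.list(delta_ct_by_gene)
  }
  if (!length(delta_ct_by_gene) || is.null(names(delta_ct_by_gene))) {
    stop("delta_ct_by_gene must be a named list of numeric vectors",
         call. = FALSE)
  }
  vapply(delta_ct_by_gene, function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(0L)
    lo <- min(v)
    # smallest nonnegative integer k with lo + k >= 1 (tolerate fp dust)
    as.integer(max(0, ceiling(1 - lo - 1e-9)))
  }, integer(1))
}

#' Censor signals too low to quantitate
#'
#' Step two: a shifted delta-Ct higher than the gene's censoring bound --
#' the (equally shifted) historical replicate median at 300 spiked copies
#' plus the censor offset (13 delta-Ct units, i.e. below 300 * 2^-13,
#' just under 0.04 copies) -- is set to 0, removing it from the analysis.
#' The comparison is strict: a value exactly at the bound is retained.
#'
#' @param shifted_delta_ct Numeric vector of shifted delta-Ct values.
#' @param gene Single gene name (canonicalized against the calibration).
#' @param calibration A [build_calibration()] table whose shift constants
#'   have already been aligned with the batch.
#' @param constants [algorithm_constants()].
#' @return The input with censored entries replaced by 0.
#' @examples
#' cal <- calibration_table(c(HOXB4 = 10))
#' censor_low_signal(c(24, 23, 5), "HOXB4", cal)
#' @export
censor_low_signal <- function(shifted_delta_ct, gene, calibration,
                              constants = algorithm_constants()) {
  stopifnot(inherits(calibration, "cm_calibration"))
  gene <- canonical_gene(gene)
  i <- match(gene, calibration$gene)
  if (length(gene) != 1L || is.na(i)) {
    stop("no calibration entry for gene ", gene, call. = FALSE)
  }
  bound <- calibration$median_delta_ct_300[i] +
    calibration$shift_constant[i] + constants$censor_offset
  ifelse(shifted_delta_ct > bound, 0, shifted_delta_ct)
}

#' Gene methylation transform
#'
#' Step three: `M = m_scale / delta_ct` (default scale 1200), raising
#' methylation values from baseline and widening the dynamic range. A
#' censored delta-Ct of 0 is the "removed from analysis" sentinel and maps
#' to `M = 0`, not to a division by zero.
#'
#' @param delta_ct Nonnegative shifted, censored delta-Ct values.
#' @param constants [algorithm_constants()].
#' @return Gene methylation M (same length as input), `M >= 0`.
#' @examples
#' gene_methylation(c(12, 0, 24))
#' @export
gene_methylation <- function(delta_ct, constants = algorithm_constants()) {
  if (any(is.na(delta_ct)) || any(delta_ct < 0)) {
    stop("delta_ct must be nonnegative after shifting and censoring",
         call. = FALSE)
  }
  ifelse(delta_ct > 0, constants$m_scale / delta_ct, 0)
}

#' Score a batch of sample runs
#'
#' Runs the full four-step CM algorithm over a validated Ct table:
#' per-cartridge ACTB normalization, batch-wide integer shifts (mirrored
#' into the calibration medians so censoring is shift-invariant),
#' censoring at median + offset, the `m_scale / delta_ct` transform, and
#' the cumulative methylation sum over the nine-gene panel. Samples whose
#' ACTB reference gave no signal in either cartridge are marked invalid
#' and receive no CM.
#'
#' @param ct_table Long-format Ct table (see [ct_table_columns()]).
#' @param calibration A [build_calibration()] table covering all targets.
#' @param config An [assay_config()].
#' @return An object of class `cm_scores`: list with
#'   * `samples` — data frame `sample_id`, `subject_id`, `group_label`,
#'     `matrix`, `draw_day`, `cm`, `valid`, `invalid_reason`;
#'   * `genes` — long data frame `sample_id`, `gene`, `cartridge_id`,
#'     `delta_ct_raw`, `delta_ct` (post-shift, post-censor; 0 = censored),
#'     `censored`, `m`;
#'   * `calibration` — the calibration with batch shift constants applied;
#'   * `shifts` — the named shift vector.
#' @examples
#' sim <- simulate_spike_replicates(spike_design(copies = c(0, 300),
#'                                               replicates = 4), seed = 7)
#' cal <- build_calibration(sim$ct[sim$ct$sample_id %in%
#'   sim$truth$sample_id[sim$truth$copies == 300], ])
#' score_batch(sim$ct, cal)
#' @export
score_batch <- function(ct_table, calibration, config = assay_config()) {
  stopifnot(inherits(calibration, "cm_calibration"))
  constants <- config$constants
  ct_table <- validate_ct_table(ct_table, config = config)
  missing_cal <- setdiff(config$panel$target_genes, calibration$gene)
  if (length(missing_cal)) {
    stop("calibration table is missing gene(s): ",
         paste(missing_cal, collapse = ", "), call. = FALSE)
  }

  ref <- config$panel$reference_gene
  is_ref <- ct_table$gene == ref
  refs <- ct_table[is_ref, c("sample_id", "cartridge_id", "ct", "no_signal")]
  names(refs)[3:4] <- c("ct_reference", "reference_no_signal")
  targets <- ct_table[!is_ref, , drop = FALSE]
  targets <- merge(targets, refs, by = c("sample_id", "cartridge_id"),
                   sort = FALSE)

  invalid_ids <- unique(refs$sample_id[refs$reference_no_signal])
  targets$valid <- !(targets$sample_id %in% invalid_ids)

  targets$delta_ct_raw <- ifelse(targets$valid,
                                 targets$ct - targets$ct_reference, NA_real_)

  ok <- targets$valid
  shifts <- if (any(ok)) {
    compute_gene_shifts(split(targets$delta_ct_raw[ok], targets$gene[ok]))
  } else {
    integer(0)
  }
  all_genes <- config$panel$target_genes
  full_shifts <- structure(integer(length(all_genes)), names = all_genes)
  full_shifts[names(shifts)] <- shifts
  calibration$shift_constant <- unname(
    full_shifts[match(calibration$gene, names(full_shifts))]
  )
  calibration$shift_constant[is.na(calibration$shift_constant)] <- 0L

  k <- full_shifts[targets$gene]
  shifted <- targets$delta_ct_raw + k
  cal_idx <- match(targets$gene, calibration$gene)
  bound <- calibration$median_delta_ct_300[cal_idx] +
    calibration$shift_constant[cal_idx] + constants$censor_offset
  censored <- ok & shifted > bound
  targets$delta_ct <- ifelse(censored, 0, shifted)
  targets$censored <- censored
  targets$m <- ifelse(ok,
                      ifelse(targets$delta_ct > 0,
                             constants$m_scale / targets$delta_ct, 0),
                      NA_real_)

  ids <- unique(ct_table$sample_id)
  targets <- targets[order(match(targets$sample_id, ids),
                           match(targets$gene, all_genes)), , drop = FALSE]
  meta <- ct_table[!duplicated(ct_table$sample_id),
                   c("sample_id", "subject_id", "group_label", "matrix",
                     "draw_day"), drop = FALSE]
  cm <- tapply(targets$m, factor(targets$sample_id, levels = ids), sum)
  samples <- data.frame(meta, row.names = NULL)
  samples$cm <- as.numeric(cm[match(samples$sample_id, names(cm))])
  samples$valid <- !(samples$sample_id %in% invalid_ids)
  samples$invalid_reason <- ifelse(samples$valid, "",
                                   paste0("reference gene ", ref,
                                          " gave no signal"))
  samples$cm[!samples$valid] <- NA_real_

  genes <- targets[, c("sample_id", "gene", "cartridge_id", "delta_ct_raw",
                       "delta_ct", "censored", "m")]
  rownames(genes) <- NULL
  structure(list(samples = samples, genes = genes,
                 calibration = calibration, shifts = full_shifts),
            class = "cm_scores")
}

#' Score a single sample run
#'
#' Convenience wrapper running [score_batch()] on one sample. Note that
#' shift constants are defined batch-wide; scoring a sample alone uses
#' only its own delta-Ct values to determine shifts.
#'
#' @param run Ct-table rows for one sample.
#' @inheritParams score_batch
#' @return One-row `samples` scoring plus per-gene detail, as `cm_scores`.
#' @export
score_sample <- function(run, calibration, config = assay_config()) {
  if (length(unique(run$sample_id)) != 1L) {
    stop("score_sample() expects rows for exactly one sample", call. = FALSE)
  }
  score_batch(run, calibration, config = config)
}

#' @export
print.cm_scores <- function(x, ...) {
  n <- nrow(x$samples)
  cat("CM scores for ", n, " sample(s); ",
      sum(!x$samples$valid), " invalid\n", sep = "")
  print(utils::head(x$samples, 10))
  if (n > 10) cat("... (", n - 10, " more)\n", sep = "")
  invisible(x)
}

#' Construct a calibration table directly
#'
#' Used for hand-built tables in examples and tests; [build_calibration()]
#' derives the medians from replicate runs.
#'
#' @param medians Named numeric vector of per-gene historical replicate
#'   median delta-Ct at 300 spiked copies.
#' @param shift_constant Named or scalar nonnegative integer shifts
#'   (default 0).
#' @return A `cm_calibration` data frame with columns `gene`,
#'   `median_delta_ct_300`, `shift_constant`.
#' @examples
#' calibration_table(c(HOXB4 = 10.2, RASSF1 = 9.8))
#' @export
calibration_table <- function(medians, shift_constant = 0L) {
  if (is.null(names(medians)) || any(!nzchar(names(medians)))) {
    stop("medians must be a named numeric vector", call. = FALSE)
  }
  shift <- rep_len(as.integer(shift_constant), length(medians))
  if (any(shift < 0)) stop("shift constants must be >= 0", call. = FALSE)
  out <- data.frame(gene = canonical_gene(names(medians)),
                    median_delta_ct_300 = as.numeric(medians),
                    shift_constant = shift,
                    stringsAsFactors = FALSE)
  class(out) <- c("cm_calibration", "data.frame")
  out
}

#' Build a calibration table from 300-copy spike-in replicates
#'
#' Computes, for each panel target, the median raw delta-Ct across
#' replicate runs of 300 spiked copies of fully methylated DNA (the
#' standard sorted-value median: the mean of the two middle values for
#' even replicate counts). Shift constants start at 0 and are updated by
#' [score_batch()] when a study batch is scored.
#'
#' @param replicate_ct Ct table of at least three replicate runs at 300
#'   copies.
#' @param config An [assay_config()].
#' @return A `cm_calibration` data frame (see [calibration_table()]).
#' @export
build_calibration <- function(replicate_ct, config = assay_config()) {
  replicate_ct <- validate_ct_table(replicate_ct, config = config)
  n_rep <- length(unique(replicate_ct$sample_id))
  if (n_rep < 3L) {
    stop("calibration requires at least 3 replicate runs, got ", n_rep,
         call. = FALSE)
  }
  ref <- config$panel$reference_gene
  refs <- replicate_ct[replicate_ct$gene == ref,
                       c("sample_id", "cartridge_id", "ct", "no_signal")]
  if (any(refs$no_signal)) {
    stop("calibration replicate(s) with no-signal reference: ",
         paste(unique(refs$sample_id[refs$no_signal]), collapse = ", "),
         call. = FALSE)
  }
  names(refs)[3] <- "ct_reference"
  targets <- replicate_ct[replicate_ct$gene != ref, , drop = FALSE]
  targets <- merge(targets, refs[, c("sample_id", "cartridge_id",
                                     "ct_reference")],
                   by = c("sample_id", "cartridge_id"), sort = FALSE)
  dct <- targets$ct - targets$ct_reference
  med <- tapply(dct, targets$gene, stats::median)
  med <- med[config$panel$target_genes]
  calibration_table(structure(as.numeric(med), names = names(med)))
}

#' Read / write a calibration table CSV
#'
#' Fixed schema: columns `gene`, `median_delta_ct_300`, `shift_constant`.
#'
#' @param path CSV path.
#' @return For `read_calibration`, a `cm_calibration`; for
#'   `write_calibration`, `path` invisibly.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) {
    stop("calibration file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "median_delta_ct_300", "shift_constant")
  if (!identical(names(df)[seq_along(need)], need)) {
    stop("calibration CSV must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  calibration_table(structure(df$median_delta_ct_300,
                              names = df$gene),
                    shift_constant = df$shift_constant)
}

#' @rdname read_calibration
#' @param calibration A `cm_calibration`.
#' @export
write_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "cm_calibration"))
  utils::write.csv(as.data.frame(calibration), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Replicate coefficient of variation
#'
#' Assay quality-control statistic over replicate CM values: the sample
#' standard deviation (n - 1 denominator) divided by the mean, expressed
#' as a percentage.
#'
#' @param values Numeric vector of at least two replicate values.
#' @return CV in percent. A zero mean leaves the CV undefined and returns
#'   `NA` with a warning.
#' @examples
#' replicate_cv(c(90, 110))
#' @export
replicate_cv <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values)) {
    stop("replicate_cv() needs at least two non-missing values",
         call. = FALSE)
  }
  m <- mean(values)
  if (m <= 0) {
    warning("CV undefined: replicate mean is not positive", call. = FALSE)
    return(NA_real_)
  }
  100 * stats::sd(values) / m
}
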