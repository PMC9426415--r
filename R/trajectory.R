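#' Summarize a longitudinal CM trajectory
#'
#' Orders one subject's serial draws by day, anchors them at the baseline
#' (day 0, or earliest) draw, and labels each between-draw interval as
#' `rise`, `fall` or `flat` using a flatness tolerance. There is no
#' formal progression rule for this score; the labels are descriptive.
#'
#' @param draws Data frame with columns `draw_day` and `cm` for one
#'   subject (a `subject_id` column, if present, must be constant); at
#'   least two draws.
#' @param tolerance Flatness tolerance in CM units; absolute changes at or
#'   below it are labelled `flat` (default 5).
#' @return Object of class `cm_trajectory`: data frame `draw_day`, `cm`,
#'   `delta_baseline`, `direction` (first row `baseline`), with
#'   attributes `subject_id`, `baseline_cm` and `tolerance`.
#' @examples
#' summarize_trajectory(data.frame(draw_day = c(0, 21, 42),
#'                                 cm = c(400, 100, 50)))
#' @export
summarize_trajectory <- function(draws, tolerance = 5) {
  stopifnot(is.data.frame(draws), all(c("draw_day", "cm") %in% names(draws)))
  if (!is.null(draws$subject_id) &&
      length(unique(draws$subject_id)) > 1L) {
    stop("summarize_trajectory() expects draws from one subject",
         call. = FALSE)
  }
  if (tolerance < 0) stop("tolerance must be >= 0", call. = FALSE)
  draws <- draws[!is.na(draws$cm), , drop = FALSE]
  if (nrow(draws) < 2L) {
    stop("at least two draws with CM are required", call. = FALSE)
  }
  draws <- draws[order(draws$draw_day), , drop = FALSE]
  baseline <- draws$cm[1]
  diffs <- diff(draws$cm)
  direction <- ifelse(diffs > tolerance, "rise",
                      ifelse(diffs < -tolerance, "fall", "flat"))
  out <- data.frame(draw_day = draws$draw_day, cm = draws$cm,
                    delta_baseline = draws$cm - baseline,
                    direction = c("baseline", direction),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out,
            subject_id = if (is.null(draws$subject_id)) NA_character_ else
              as.character(draws$subject_id[1]),
            baseline_cm = baseline, tolerance = tolerance,
            class = c("cm_trajectory", "data.frame"))
}

#' Summarize trajectories for every subject in a scored batch
#'
#' @param scores A `cm_scores` object or a data frame with `subject_id`,
#'   `draw_day` and `cm` columns; subjects with fewer than two valid
#'   draws are skipped with a message.
#' @param tolerance Flatness tolerance in CM units.
#' @return Data frame `subject_id`, `draw_day`, `cm`, `delta_baseline`,
#'   `direction`, stacked over subjects.
#' @export
summarize_trajectories <- function(scores, tolerance = 5) {
  df <- if (inherits(scores, "cm_scores")) scores$samples else scores
  stopifnot(is.data.frame(df),
            all(c("subject_id", "draw_day", "cm") %in% names(df)))
  out <- lapply(unique(df$subject_id), function(sid) {
    sub <- df[df$subject_id == sid & !is.na(df$cm), , drop = FALSE]
    if (nrow(sub) < 2L) {
      message("skipping subject ", sid, ": fewer than two valid draws")
      return(NULL)
    }
    tr <- summarize_trajectory(sub, tolerance = tolerance)
    cbind(subject_id = sid, as.data.frame(tr))
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    stop("no subject has two or more valid draws", call. = FALSE)
  }
  rownames(res) <- NULL
  res
}
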