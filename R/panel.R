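#' Target gene panel
#'
#' Constructor for the marker panel scored by the cumulative methylation
#' (CM) algorithm: nine methylation target genes plus the endogenous ACTB
#' (beta-actin) reference, which tracks total cell-free DNA input. Gene
#' names are canonicalized (trimmed, upper-cased) so that qPCR exports with
#' inconsistent casing resolve to the same panel entry.
#'
#' @param target_genes Character vector of exactly nine distinct target
#'   gene names. Defaults to the shipped breast-cancer panel.
#' @param reference_gene Reference gene name, present in every cartridge.
#' @return An object of class `cm_panel`: a list with elements
#'   `target_genes` and `reference_gene`, both canonicalized.
#' @examples
#' gene_panel()
#' @export
gene_panel <- function(target_genes = c(
                         "HOXB4", "RASGRF2", "AKR1B1", "TM6SF1", "COL6A2",
                         "HIST1H3C", "TMEFF2", "RASSF1", "ZNF671"
                       ),
                       reference_gene = "ACTB") {
  targets <- canonical_gene(target_genes)
  ref <- canonical_gene(reference_gene)
  if (length(targets) != 9L) {
    stop("a gene panel must contain exactly 9 target genes, got ",
         length(targets), call. = FALSE)
  }
  if (anyDuplicated(targets)) {
    stop("duplicate target genes in panel: ",
         paste(targets[duplicated(targets)], collapse = ", "), call. = FALSE)
  }
  if (length(ref) != 1L || !nzchar(ref)) {
    stop("exactly one reference gene is required", call. = FALSE)
  }
  if (ref %in% targets) {
    stop("reference gene ", ref, " must not be among the targets",
         call. = FALSE)
  }
  structure(list(target_genes = targets, reference_gene = ref),
            class = "cm_panel")
}

#' Canonicalize gene names
#'
#' Trims surrounding whitespace and upper-cases, so instrument exports with
#' mixed case ("actb", " Rassf1 ") resolve against the panel.
#'
#' @param x Character vector of gene names.
#' @return Canonical (trimmed, upper-case) names.
#' @export
canonical_gene <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Detection cartridge layout
#'
#' The assay splits one bisulfite-converted sample across two detection
#' cartridges, each running a multiplexed methylation-specific PCR for 4-5
#' target genes plus the ACTB reference. The layout is configuration with
#' the shipped A/B split as default; the union of cartridge genes must
#' partition the panel targets.
#'
#' @param cartridges Named list mapping cartridge id to a character vector
#'   of target genes measured in that cartridge.
#' @param panel A [gene_panel()].
#' @return An object of class `cm_layout`: list with `cartridges` (named
#'   list of canonical gene vectors) and `reference_gene`.
#' @examples
#' cartridge_layout()
#' @export
cartridge_layout <- function(cartridges = list(
                               A = c("AKR1B1", "TM6SF1", "ZNF671", "TMEFF2"),
                               B = c("COL6A2", "HIST1H3C", "RASGRF2",
                                     "HOXB4", "RASSF1")
                             ),
                             panel = gene_panel()) {
  if (is.null(names(cartridges)) || any(!nzchar(names(cartridges)))) {
    stop("cartridges must be a named list", call. = FALSE)
  }
  cartridges <- lapply(cartridges, canonical_gene)
  all_genes <- unlist(cartridges, use.names = FALSE)
  if (anyDuplicated(all_genes)) {
    stop("gene(s) assigned to more than one cartridge: ",
         paste(unique(all_genes[duplicated(all_genes)]), collapse = ", "),
         call. = FALSE)
  }
  if (!setequal(all_genes, panel$target_genes)) {
    missing <- setdiff(panel$target_genes, all_genes)
    extra <- setdiff(all_genes, panel$target_genes)
    stop("cartridge genes must partition the panel targets",
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unknown: ",
                                   paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  structure(list(cartridges = cartridges,
                 reference_gene = panel$reference_gene),
            class = "cm_layout")
}

#' Algorithm constants
#'
#' Fixed constants of the CM algorithm: the no-signal Ct sentinel assigned
#' when a reaction never crosses the detection threshold, the censoring
#' offset added to the 300-copy calibration median (13 delta-Ct units,
#' i.e. a floor of 300 * 2^-13, just under 0.04 copies), the gene
#' methylation scale (M = m_scale / delta-Ct) and the locked CM
#' classification threshold.
#'
#' @param no_signal_ct Cycles assigned to undetected reactions.
#' @param censor_offset Delta-Ct units added to the calibration median to
#'   form the per-gene censoring bound.
#' @param m_scale Numerator of the gene methylation transform.
#' @param cm_threshold CM units; samples strictly above are called positive.
#' @return An object of class `cm_constants`.
#' @examples
#' algorithm_constants()
#' @export
algorithm_constants <- function(no_signal_ct = 45,
                                censor_offset = 13,
                                m_scale = 1200,
                                cm_threshold = 38.5) {
  vals <- c(no_signal_ct = no_signal_ct, censor_offset = censor_offset,
            m_scale = m_scale, cm_threshold = cm_threshold)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all algorithm constants must be finite and strictly positive",
         call. = FALSE)
  }
  structure(as.list(vals), class = "cm_constants")
}

#' Assay configuration
#'
#' Bundles the panel, cartridge layout and algorithm constants. The default
#' reproduces the shipped two-cartridge nine-gene breast cancer assay.
#'
#' @param panel A [gene_panel()].
#' @param layout A [cartridge_layout()] consistent with `panel`.
#' @param constants An [algorithm_constants()].
#' @return An object of class `cm_config`.
#' @examples
#' cfg <- assay_config()
#' cfg$layout$cartridges$A
#' @export
assay_config <- function(panel = gene_panel(),
                         layout = cartridge_layout(panel = panel),
                         constants = algorithm_constants()) {
  stopifnot(inherits(panel, "cm_panel"), inherits(layout, "cm_layout"),
            inherits(constants, "cm_constants"))
  if (!setequal(unlist(layout$cartridges), panel$target_genes) ||
      !identical(layout$reference_gene, panel$reference_gene)) {
    stop("layout is inconsistent with panel", call. = FALSE)
  }
  structure(list(panel = panel, layout = layout, constants = constants),
            class = "cm_config")
}

#' Read an assay configuration document
#'
#' Accepts YAML or JSON with top-level keys `panel` (`target_genes`,
#' `reference_gene`), `layout` (`cartridges`) and `constants`; omitted
#' sections fall back to the shipped defaults. The default document shipped
#' under `inst/extdata/default_config.yaml` reproduces [assay_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `cm_config`.
#' @export
read_assay_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(sub(".*\\.", "", path))
  doc <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: .", ext, call. = FALSE)
  }
  panel <- if (is.null(doc$panel)) gene_panel() else {
    gene_panel(target_genes = unlist(doc$panel$target_genes),
               reference_gene = doc$panel$reference_gene %||% "ACTB")
  }
  layout <- if (is.null(doc$layout)) cartridge_layout(panel = panel) else {
    cartridge_layout(cartridges = lapply(doc$layout$cartridges, unlist),
                     panel = panel)
  }
  constants <- if (is.null(doc$constants)) algorithm_constants() else {
    do.call(algorithm_constants, doc$constants)
  }
  assay_config(panel = panel, layout = layout, constants = constants)
}

#' Write an assay configuration document
#'
#' @param config A `cm_config`.
#' @param path Destination `.yaml`/`.yml` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_assay_config <- function(config, path) {
  stopifnot(inherits(config, "cm_config"))
  doc <- list(
    panel = list(target_genes = config$panel$target_genes,
                 reference_gene = config$panel$reference_gene),
    layout = list(cartridges = config$layout$cartridges),
    constants = config$constants[]
  )
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(doc, path)
  } else if (ext == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  } else {
    stop("unsupported config format: .", ext, call. = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cm_panel <- function(x, ...) {
  cat("Methylation gene panel: ", paste(x$target_genes, collapse = ", "),
      "\nReference gene: ", x$reference_gene, "\n", sep = "")
  invisible(x)
}

#' @export
print.cm_layout <- function(x, ...) {
  for (id in names(x$cartridges)) {
    cat("Cartridge ", id, ": ",
        paste(c(x$cartridges[[id]], x$reference_gene), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.cm_config <- function(x, ...) {
  print(x$panel)
  print(x$layout)
  cat(sprintf("Constants: no-signal Ct %g, censor offset %g, M scale %g, CM threshold %g\n",
              x$constants$no_signal_ct, x$constants$censor_offset,
              x$constants$m_scale, x$constants$cm_threshold))
  invisible(x)
}
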