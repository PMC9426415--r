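#' qPCR noise model
#'
#' Generative model for measured cycle thresholds: molecules are sampled
#' as `k ~ Poisson(expected copies)` (detection layer; `k = 0` emits the
#' no-signal sentinel), and detected reactions follow ideal one-cycle-per-
#' doubling kinetics `Ct = alpha_g - log2(k) + Normal(0, ct_sd)`, where
#' `alpha_g` is the per-gene amplification intercept (the Ct of a single
#' effective copy, with the 20-cycle preamplification folded in). On top
#' of the per-reaction Gaussian noise, each replicate carries a bounded
#' sample-level recovery effect, uniform on `[-recovery_halfwidth,
#' +recovery_halfwidth]` cycles, applied to the target genes' Poisson
#' means (it models run-to-run variation in spike recovery and bisulfite
#' conversion, which does not affect the endogenous ACTB reference).
#'
#' The matrix-specific defaults reflect that serum is substantially
#' noisier than plasma for this assay, and that serum carries more
#' background cfDNA (higher ACTB copy input).
#'
#' @param matrix `"plasma"` or `"serum"` — selects the default noise
#'   scale.
#' @param alpha Named vector of amplification intercepts (cycles) for the
#'   nine targets and the reference.
#' @param ct_sd Per-reaction Gaussian Ct noise sd (cycles); plasma default
#'   is smaller than serum's.
#' @param recovery_halfwidth Half-width (cycles) of the uniform
#'   sample-level recovery effect.
#' @param drift_span Total span (cycles) of the systematic between-run
#'   drift across a replicate series: replicate experiments are run
#'   sequentially over days, and reagent ageing / run-order effects give
#'   a slow bounded trend in effective recovery, modeled as a linear ramp
#'   from `-drift_span/2` to `+drift_span/2` over the series. Only
#'   [simulate_spike_replicates()] (replicate series of one material)
#'   applies it; single-draw cohort samples carry the random recovery
#'   effect only.
#' @param actb_copies Background cfDNA input driving the reference gene,
#'   copies per reaction (split across the two cartridges).
#' @param poisson If `FALSE`, the molecule-sampling layer is switched off
#'   and the expected copy number is used deterministically (useful for
#'   exactness checks).
#' @return Object of class `cm_noise`.
#' @examples
#' noise_model("plasma")
#' @export
noise_model <- function(matrix = c("plasma", "serum"),
                        alpha = NULL, ct_sd = NULL,
                        recovery_halfwidth = NULL, drift_span = NULL,
                        actb_copies = NULL, poisson = TRUE) {
  matrix <- match.arg(matrix)
  defaults <- list(
    plasma = list(ct_sd = 0.05, recovery_halfwidth = 0.15,
                  drift_span = 0.80, actb_copies = 3000),
    serum = list(ct_sd = 0.20, recovery_halfwidth = 0.40,
                 drift_span = 2.80, actb_copies = 6000)
  )[[matrix]]
  if (is.null(alpha)) {
    alpha <- c(HOXB4 = 35.6, RASGRF2 = 36.2, AKR1B1 = 35.9, TM6SF1 = 36.4,
               COL6A2 = 35.7, HIST1H3C = 36.1, TMEFF2 = 36.3,
               RASSF1 = 35.8, ZNF671 = 36.0, ACTB = 36.0)
  }
  ct_sd <- ct_sd %||% defaults$ct_sd
  recovery_halfwidth <- recovery_halfwidth %||% defaults$recovery_halfwidth
  drift_span <- drift_span %||% defaults$drift_span
  actb_copies <- actb_copies %||% defaults$actb_copies
  if (ct_sd < 0 || recovery_halfwidth < 0 || drift_span < 0 ||
      actb_copies <= 0) {
    stop("noise parameters must be nonnegative (actb_copies positive)",
         call. = FALSE)
  }
  structure(list(matrix = matrix, alpha = alpha, ct_sd = ct_sd,
                 recovery_halfwidth = recovery_halfwidth,
                 drift_span = drift_span, actb_copies = actb_copies,
                 poisson = isTRUE(poisson)),
            class = "cm_noise")
}

#' Simulate one cycle-threshold measurement
#'
#' Draws molecules through the Poisson detection layer and converts the
#' detected count to a Ct by the one-cycle-per-doubling law with Gaussian
#' noise; zero detected molecules emit the no-signal sentinel (Ct 45).
#' Uses the current RNG state — wrap in a seeded context (the public
#' generators do).
#'
#' @param expected_copies Nonnegative expected copies per reaction (may be
#'   a vector, paired with `gene`).
#' @param gene Gene name(s), resolved against `noise$alpha`.
#' @param noise A [noise_model()].
#' @param constants [algorithm_constants()] (no-signal sentinel).
#' @return Data frame `gene`, `ct`, `no_signal`.
#' @examples
#' set.seed(1)
#' simulate_ct(c(0, 300), c("HOXB4", "HOXB4"), noise_model("plasma"))
#' @export
simulate_ct <- function(expected_copies, gene, noise = noise_model(),
                        constants = algorithm_constants()) {
  stopifnot(inherits(noise, "cm_noise"))
  if (any(expected_copies < 0)) {
    stop("expected_copies must be >= 0", call. = FALSE)
  }
  gene <- canonical_gene(gene)
  n <- max(length(expected_copies), length(gene))
  expected_copies <- rep_len(expected_copies, n)
  gene <- rep_len(gene, n)
  a <- noise$alpha[gene]
  if (anyNA(a)) {
    stop("no amplification intercept for gene(s): ",
         paste(unique(gene[is.na(a)]), collapse = ", "), call. = FALSE)
  }
  m <- sim_ct_vec(expected_copies, a, noise, constants)
  data.frame(gene = gene, ct = m$ct, no_signal = m$no_signal,
             stringsAsFactors = FALSE)
}

# vector core of simulate_ct: alpha already resolved per element
sim_ct_vec <- function(expected_copies, alpha, noise, constants) {
  n <- length(expected_copies)
  k <- if (noise$poisson) stats::rpois(n, expected_copies) else
    expected_copies
  detected <- k > 0
  ct <- rep(constants$no_signal_ct, n)
  if (any(detected)) {
    raw <- alpha[detected] - log2(k[detected]) +
      stats::rnorm(sum(detected), 0, noise$ct_sd)
    ct[detected] <- pmin(pmax(raw, 0.05), constants$no_signal_ct - 0.1)
  }
  list(ct = ct, no_signal = !detected)
}

#' Spike-in replicate experiment design
#'
#' Replicates of known copy numbers of fully methylated DNA spiked into a
#' normal plasma- or serum-like matrix, measured through the two-cartridge
#' assay (the converted sample is split equally, so each cartridge sees
#' half the spiked copies).
#'
#' @param copies Copy numbers per condition (default `0, 75, 150, 300,
#'   600`).
#' @param replicates Replicates per condition (>= 2; default 11).
#' @param matrix `"plasma"` or `"serum"`.
#' @param seed Optional default seed carried by the design.
#' @return Object of class `cm_spike_design`.
#' @export
spike_design <- function(copies = c(0, 75, 150, 300, 600), replicates = 11,
                         matrix = c("plasma", "serum"), seed = NULL) {
  matrix <- match.arg(matrix)
  if (any(copies < 0)) stop("copies must be >= 0", call. = FALSE)
  if (replicates < 2) stop("replicates must be >= 2", call. = FALSE)
  structure(list(copies = copies, replicates = as.integer(replicates),
                 matrix = matrix, seed = seed),
            class = "cm_spike_design")
}

sample_meta_row <- function(sample_id, subject_id, group_label, matrix,
                            draw_day = NA_integer_) {
  list(sample_id = sample_id, subject_id = subject_id,
       group_label = group_label, matrix = matrix, draw_day = draw_day)
}

# Emit the 11 Ct-table rows of one two-cartridge run. `target_copies` is a
# named per-gene vector of per-cartridge Poisson means (recovery applied);
# ACTB comes either from `actb_copies` (per cartridge, through the Poisson
# layer) or from a directly supplied `actb_ct` per-cartridge vector.
simulate_run_rows <- function(meta, target_copies, noise, config,
                              actb_copies = NULL, actb_ct = NULL) {
  layout <- config$layout
  ref <- config$panel$reference_gene
  constants <- config$constants
  cart_ids <- names(layout$cartridges)
  gene <- character(0)
  cart <- character(0)
  copies <- numeric(0)
  is_ref_row <- logical(0)
  for (cid in cart_ids) {
    g <- layout$cartridges[[cid]]
    gene <- c(gene, g, ref)
    cart <- c(cart, rep(cid, length(g) + 1L))
    copies <- c(copies, unname(target_copies[g]),
                if (is.null(actb_ct)) actb_copies else 0)
    is_ref_row <- c(is_ref_row, rep(FALSE, length(g)), TRUE)
  }
  a <- noise$alpha[gene]
  if (anyNA(a)) {
    stop("no amplification intercept for gene(s): ",
         paste(unique(gene[is.na(a)]), collapse = ", "), call. = FALSE)
  }
  m <- sim_ct_vec(copies, a, noise, constants)
  ct <- m$ct
  no_signal <- m$no_signal
  if (!is.null(actb_ct)) {
    ref_ct <- unlist(actb_ct[cart[is_ref_row]], use.names = FALSE)
    ct[is_ref_row] <- pmin(pmax(ref_ct, 0.05), constants$no_signal_ct - 0.1)
    no_signal[is_ref_row] <- FALSE
  }
  data.frame(sample_id = meta$sample_id, subject_id = meta$subject_id,
             group_label = meta$group_label, matrix = meta$matrix,
             draw_day = meta$draw_day, cartridge_id = cart, gene = gene,
             ct = ct, no_signal = no_signal, stringsAsFactors = FALSE)
}

#' Simulate spike-in replicate runs
#'
#' Each replicate spikes the condition's copy number of fully methylated
#' DNA (equal for all nine targets) into the matrix, applies the bounded
#' sample-level recovery effect, splits the reaction across the two
#' detection cartridges (halving the effective copies per measurement)
#' and measures every gene plus the per-cartridge ACTB reference, which
#' is driven by the matrix's fixed background cfDNA level. Deterministic
#' given the seed.
#'
#' @param design A [spike_design()].
#' @param noise A [noise_model()]; defaults to the design matrix's noise.
#' @param config An [assay_config()].
#' @param seed Integer seed (mandatory; falls back to `design$seed`).
#' @return List with `ct` (Ct table), `truth` (per-sample spiked copies
#'   and recovery effect), and `noise`.
#' @export
simulate_spike_replicates <- function(design, noise = NULL,
                                      config = assay_config(),
                                      seed = design$seed) {
  stopifnot(inherits(design, "cm_spike_design"))
  noise <- noise %||% noise_model(design$matrix)
  with_seed(seed, {
    genes <- config$panel$target_genes
    ct_rows <- list()
    truth <- list()
    i <- 0L
    for (cond in seq_along(design$copies)) {
      copies <- design$copies[cond]
      for (rep_i in seq_len(design$replicates)) {
        i <- i + 1L
        drift <- if (design$replicates > 1L) {
          noise$drift_span * ((rep_i - 1) / (design$replicates - 1) - 0.5)
        } else 0
        u <- drift + stats::runif(1, -noise$recovery_halfwidth,
                                  noise$recovery_halfwidth)
        sid <- sprintf("spike_%s_c%04d_r%02d", design$matrix, copies, rep_i)
        per_cart <- structure(rep((copies / 2) * 2^u, length(genes)),
                              names = genes)
        meta <- sample_meta_row(sid, sid, "unknown", design$matrix)
        ct_rows[[i]] <- simulate_run_rows(meta, per_cart, noise, config,
                                          actb_copies = noise$actb_copies / 2)
        truth[[i]] <- data.frame(sample_id = sid, copies = copies,
                                 recovery_log2 = u)
      }
    }
    truth <- do.call(rbind, truth)
    truth_genes <- data.frame(
      sample_id = rep(truth$sample_id, each = length(genes)),
      gene = rep(genes, nrow(truth)),
      mean_copies = rep((truth$copies / 2) * 2^truth$recovery_log2,
                        each = length(genes)))
    list(ct = do.call(rbind, ct_rows), truth = truth,
         truth_genes = truth_genes, noise = noise, design = design)
  })
}

#' Case/control cohort design
#'
#' Generative design for a diagnostic cohort. Cancer samples draw
#' per-gene methylated copy numbers from a lognormal distribution for a
#' per-sample random subset of active genes; controls carry only a
#' near-zero stray-copy background. The ACTB reference Ct is drawn
#' uniformly within the class-specific range (cancer sera/plasma carry
#' more total cfDNA, hence a lower minimum Ct), with a small independent
#' per-cartridge jitter for the shared sample.
#'
#' The shipped defaults target the headline operating point of a
#' metastatic-cancer test cohort: `active_gene_prob = 0.17` puts the
#' fraction of cancers with no methylation signal near 17% (sensitivity
#' ~83% at the locked threshold) and `background_rate = 0.02` stray
#' copies per gene puts the fraction of controls with any detected signal
#' near 8.5% (specificity ~92%).
#'
#' @param n_cancer,n_benign,n_normal Class sizes (default 40 / 17 / 9).
#' @param cancer,control Per-class generative parameters: lists with
#'   `active_gene_prob`, `copies_meanlog`, `copies_sdlog`,
#'   `background_rate`.
#' @param actb_ct_range_cancer,actb_ct_range_normal ACTB Ct ranges
#'   (cycles); defaults 16.0-27.8 and 21.0-27.4.
#' @param actb_cartridge_sd Between-cartridge ACTB jitter sd (cycles).
#' @param matrix `"plasma"` or `"serum"`.
#' @param seed Optional default seed carried by the design.
#' @return Object of class `cm_cohort_design`.
#' @export
cohort_design <- function(n_cancer = 40, n_benign = 17, n_normal = 9,
                          cancer = list(active_gene_prob = 0.17,
                                        copies_meanlog = log(300),
                                        copies_sdlog = 1.2,
                                        background_rate = 0.02),
                          control = list(active_gene_prob = 0,
                                         copies_meanlog = log(300),
                                         copies_sdlog = 1.2,
                                         background_rate = 0.02),
                          actb_ct_range_cancer = c(16.0, 27.8),
                          actb_ct_range_normal = c(21.0, 27.4),
                          actb_cartridge_sd = 0.15,
                          matrix = c("plasma", "serum"), seed = NULL) {
  matrix <- match.arg(matrix)
  if (any(c(n_cancer, n_benign, n_normal) < 0)) {
    stop("class sizes must be >= 0", call. = FALSE)
  }
  for (rng in list(actb_ct_range_cancer, actb_ct_range_normal)) {
    if (length(rng) != 2L || any(rng <= 0) || any(rng >= 45) ||
        rng[1] > rng[2]) {
      stop("ACTB Ct ranges must lie within (0, 45)", call. = FALSE)
    }
  }
  structure(list(n_cancer = n_cancer, n_benign = n_benign,
                 n_normal = n_normal, cancer = cancer, control = control,
                 actb_ct_range_cancer = actb_ct_range_cancer,
                 actb_ct_range_normal = actb_ct_range_normal,
                 actb_cartridge_sd = actb_cartridge_sd,
                 matrix = matrix, seed = seed),
            class = "cm_cohort_design")
}

# Calibrated once by large-n simulation: effective sd of the latent
# log-signal separating the continuous cohort classes, so that a per-gene
# meanlog shift of qnorm(auc) * sqrt(2) * sigma gives a CM AUC of `auc`
# (anchored at auc = 0.90). See the methods vignette.
.cm_auc_sigma_eff <- 0.806

#' Continuous-signal cohort design for a target AUC
#'
#' A cohort profile in which every sample of both classes carries
#' methylation signal in all nine genes (elevated control background), so
#' the CM score is continuous in both classes with no ties at zero. The
#' separation between the class copy distributions is set from the
#' binormal relation `delta = qnorm(auc) * sqrt(2) * sigma_eff`, with
#' `sigma_eff` calibrated once against large-sample simulation. Intended
#' for statistical-recovery experiments (CI coverage, null behavior)
#' where a designed, analytically known AUC is needed; the zero-inflated
#' [cohort_design()] remains the clinically realistic default.
#'
#' @param auc Designed area under the ROC curve, in `[0.5, 1)`.
#' @param n_cancer,n_control Class sizes (controls are labelled normal).
#' @param matrix `"plasma"` or `"serum"`.
#' @param seed Optional default seed.
#' @return A `cm_cohort_design`.
#' @export
cohort_design_auc <- function(auc = 0.90, n_cancer = 40, n_control = 26,
                              matrix = "plasma", seed = NULL) {
  if (auc < 0.5 || auc >= 1) stop("auc must be in [0.5, 1)", call. = FALSE)
  delta <- stats::qnorm(auc) * sqrt(2) * .cm_auc_sigma_eff
  base <- list(active_gene_prob = 1, copies_meanlog = log(3),
               copies_sdlog = 0.8, background_rate = 0)
  cancer <- base
  cancer$copies_meanlog <- base$copies_meanlog + delta
  cohort_design(n_cancer = n_cancer, n_benign = 0, n_normal = n_control,
                cancer = cancer, control = base,
                actb_ct_range_cancer = c(21.0, 27.4),
                actb_ct_range_normal = c(21.0, 27.4),
                matrix = matrix, seed = seed)
}

#' Simulate a case/control cohort
#'
#' @param design A [cohort_design()].
#' @param noise A [noise_model()]; defaults to the design matrix's noise.
#' @param config An [assay_config()].
#' @param seed Integer seed (mandatory; falls back to `design$seed`).
#' @return List with `ct` (Ct table with class labels), `truth`
#'   (per-sample latent burden: total methylated copies, active genes,
#'   sample ACTB Ct), and `noise`.
#' @export
simulate_cohort <- function(design, noise = NULL, config = assay_config(),
                            seed = design$seed) {
  stopifnot(inherits(design, "cm_cohort_design"))
  noise <- noise %||% noise_model(design$matrix)
  with_seed(seed, {
    genes <- config$panel$target_genes
    groups <- c(rep("cancer", design$n_cancer),
                rep("benign", design$n_benign),
                rep("normal", design$n_normal))
    if (!length(groups)) stop("empty cohort design", call. = FALSE)
    ct_rows <- vector("list", length(groups))
    truth <- vector("list", length(groups))
    truth_genes <- vector("list", length(groups))
    for (i in seq_along(groups)) {
      grp <- groups[i]
      par <- if (grp == "cancer") design$cancer else design$control
      rng <- if (grp == "cancer") design$actb_ct_range_cancer else
        design$actb_ct_range_normal
      sid <- sprintf("cohort_%s_%03d", grp, i)
      active <- stats::rbinom(length(genes), 1, par$active_gene_prob)
      copies <- active * stats::rlnorm(length(genes), par$copies_meanlog,
                                       par$copies_sdlog)
      u <- stats::runif(1, -noise$recovery_halfwidth,
                        noise$recovery_halfwidth)
      per_cart <- structure(
        ((copies + par$background_rate) / 2) * 2^u, names = genes)
      actb_sample <- stats::runif(1, rng[1], rng[2])
      actb_ct <- lapply(config$layout$cartridges, function(g) {
        actb_sample + stats::rnorm(1, 0, design$actb_cartridge_sd)
      })
      meta <- sample_meta_row(sid, sid, grp, design$matrix)
      ct_rows[[i]] <- simulate_run_rows(meta, per_cart, noise, config,
                                        actb_ct = actb_ct)
      truth[[i]] <- data.frame(sample_id = sid, group_label = grp,
                               total_copies = sum(copies),
                               n_active = sum(active),
                               actb_ct = actb_sample,
                               recovery_log2 = u)
      truth_genes[[i]] <- data.frame(sample_id = sid, gene = genes,
                                     mean_copies = unname(per_cart))
    }
    list(ct = do.call(rbind, ct_rows), truth = do.call(rbind, truth),
         truth_genes = do.call(rbind, truth_genes), noise = noise,
         design = design)
  })
}

#' Simulate a duplicate-user measurement set
#'
#' Re-measures every run of a simulated dataset as a second user would:
#' the same aliquoted sample (identical latent copy numbers) goes through
#' an independent measurement realization with additional user-level Ct
#' noise. With `resample_molecules = TRUE` the Poisson detection layer is
#' redrawn from the latent truth (no-signal status can flip); with
#' `FALSE` the duplicate keeps the first user's molecule draws and only
#' perturbs the measured Ct values, so `user_noise_sd = 0` reproduces the
#' first user's table exactly.
#'
#' @param sim A simulation result from [simulate_spike_replicates()] or
#'   [simulate_cohort()] (needs `ct`, `truth`, `noise`).
#' @param user_noise_sd Additional between-user Ct noise sd (cycles,
#'   >= 0).
#' @param seed Integer seed (mandatory).
#' @param resample_molecules Redraw the Poisson layer from truth?
#' @param config An [assay_config()].
#' @return List with `user_a` and `user_b` Ct tables (paired by
#'   `sample_id`).
#' @export
simulate_interuser <- function(sim, user_noise_sd = 0.3, seed,
                               resample_molecules = TRUE,
                               config = assay_config()) {
  if (user_noise_sd < 0) stop("user_noise_sd must be >= 0", call. = FALSE)
  stopifnot(is.list(sim), !is.null(sim$ct))
  noise <- sim$noise
  constants <- config$constants
  ref <- config$panel$reference_gene
  with_seed(seed, {
    b <- sim$ct
    if (!resample_molecules) {
      live <- !b$no_signal
      b$ct[live] <- pmin(pmax(b$ct[live] +
                                stats::rnorm(sum(live), 0, user_noise_sd),
                              0.05), constants$no_signal_ct - 0.1)
      return(list(user_a = sim$ct, user_b = b))
    }
    stopifnot(!is.null(sim$truth_genes), inherits(noise, "cm_noise"))
    noise_b <- noise
    noise_b$ct_sd <- sqrt(noise$ct_sd^2 + user_noise_sd^2)
    is_ref <- b$gene == ref
    tg <- sim$truth_genes
    key_b <- paste(b$sample_id, b$gene)
    mean_copies <- tg$mean_copies[match(key_b[!is_ref],
                                        paste(tg$sample_id, tg$gene))]
    if (anyNA(mean_copies)) {
      stop("truth_genes does not cover every (sample, gene) cell",
           call. = FALSE)
    }
    tgt <- simulate_ct(mean_copies, b$gene[!is_ref], noise_b, constants)
    b$ct[!is_ref] <- tgt$ct
    b$no_signal[!is_ref] <- tgt$no_signal
    if (!is.null(sim$truth$actb_ct)) {     # cohort: direct reference Ct
      cart_sd <- sim$design$actb_cartridge_sd %||% 0.15
      base <- sim$truth$actb_ct[match(b$sample_id[is_ref],
                                      sim$truth$sample_id)]
      ct <- base + stats::rnorm(sum(is_ref), 0,
                                sqrt(cart_sd^2 + user_noise_sd^2))
      b$ct[is_ref] <- pmin(pmax(ct, 0.05), constants$no_signal_ct - 0.1)
      b$no_signal[is_ref] <- FALSE
    } else {                               # spike: background cfDNA copies
      refm <- simulate_ct(rep(noise$actb_copies / 2, sum(is_ref)),
                          b$gene[is_ref], noise_b, constants)
      b$ct[is_ref] <- refm$ct
      b$no_signal[is_ref] <- refm$no_signal
    }
    list(user_a = sim$ct, user_b = b)
  })
}

#' Simulate serial on-treatment draws
#'
#' Generates longitudinal two-cartridge runs for patients on cyclic
#' chemotherapy, one draw at baseline (day 0) and one per subsequent
#' cycle. A latent tumor-burden trajectory drives the per-gene methylated
#' copy numbers: `response` decays exponentially after treatment start,
#' `progression` decays to a nadir and regrows, `stable` stays at the
#' baseline burden (measurement layers still apply). Each patient has a
#' fixed random subset of methylated genes with fixed relative weights.
#'
#' @param n_patients Number of patients.
#' @param patterns Trajectory patterns cycled over patients; subset of
#'   `"response"`, `"progression"`, `"stable"`.
#' @param n_draws Draws per patient (>= 2), baseline included.
#' @param cycle_days Days between successive draws (default 21, a
#'   typical chemotherapy cycle).
#' @param baseline_meanlog,baseline_sdlog Lognormal parameters of the
#'   baseline burden (total methylated copies).
#' @param noise A [noise_model()].
#' @param config An [assay_config()].
#' @param seed Integer seed (mandatory).
#' @return List with `ct` (Ct table with `subject_id`/`draw_day` filled),
#'   `truth` (per-draw latent burden and pattern), and `noise`.
#' @export
simulate_longitudinal <- function(n_patients = 15,
                                  patterns = c("response", "progression",
                                               "stable"),
                                  n_draws = 5, cycle_days = 21,
                                  baseline_meanlog = log(400),
                                  baseline_sdlog = 0.6,
                                  noise = noise_model("serum"),
                                  config = assay_config(), seed) {
  patterns <- match.arg(patterns, several.ok = TRUE)
  if (n_draws < 2) stop("n_draws must be >= 2", call. = FALSE)
  with_seed(seed, {
    genes <- config$panel$target_genes
    ct_rows <- list()
    truth <- list()
    row_i <- 0L
    for (p in seq_len(n_patients)) {
      pattern <- patterns[((p - 1L) %% length(patterns)) + 1L]
      pid <- sprintf("patient_%02d", p)
      b0 <- stats::rlnorm(1, baseline_meanlog, baseline_sdlog)
      active <- stats::rbinom(length(genes), 1, 0.5)
      if (!any(active)) active[sample(length(genes), 1)] <- 1L
      w <- active * stats::rlnorm(length(genes), 0, 0.5)
      w <- w / sum(w)
      decay <- stats::runif(1, 0.6, 1.2)     # per-cycle log decay
      regrow <- stats::runif(1, 0.5, 1.0)    # per-cycle log regrowth
      nadir <- max(1L, floor((n_draws - 1L) / 2))
      actb_base <- stats::runif(1, 20, 26)
      days <- (seq_len(n_draws) - 1L) * cycle_days
      for (d in seq_len(n_draws)) {
        cyc <- d - 1L
        burden <- switch(pattern,
          response = b0 * exp(-decay * cyc),
          progression = b0 * exp(-decay * min(cyc, nadir) +
                                   regrow * max(0, cyc - nadir)),
          stable = b0)
        u <- stats::runif(1, -noise$recovery_halfwidth,
                          noise$recovery_halfwidth)
        per_cart <- structure((burden * w / 2) * 2^u, names = genes)
        actb_ct <- lapply(config$layout$cartridges, function(g) {
          actb_base + stats::rnorm(1, 0, 0.15 * (noise$ct_sd > 0))
        })
        sid <- sprintf("%s_d%03d", pid, days[d])
        meta <- sample_meta_row(sid, pid, "cancer", noise$matrix,
                                draw_day = days[d])
        row_i <- row_i + 1L
        ct_rows[[row_i]] <- simulate_run_rows(meta, per_cart, noise,
                                              config, actb_ct = actb_ct)
        truth[[row_i]] <- data.frame(sample_id = sid, subject_id = pid,
                                     pattern = pattern, draw_day = days[d],
                                     burden = burden)
      }
    }
    list(ct = do.call(rbind, ct_rows), truth = do.call(rbind, truth),
         noise = noise)
  })
}
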