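test_that("simulated Ct follows the one-cycle-per-doubling law", {
  nm0 <- noise_model("plasma", alpha = c(HOXB4 = 38), ct_sd = 0,
                     poisson = FALSE)
  set.seed(1)
  expect_equal(simulate_ct(300, "HOXB4", nm0)$ct, 38 - log2(300),
               tolerance = 1e-12)  # 29.77 cycles
  one <- simulate_ct(c(100, 200, 400), "HOXB4", nm0)
  expect_equal(diff(one$ct), c(-1, -1))

  # zero expected copies can never amplify
  set.seed(2)
  zero <- simulate_ct(rep(0, 50), "HOXB4", noise_model("plasma"))
  expect_true(all(zero$no_signal))
  expect_true(all(zero$ct == 45))

  expect_error(simulate_ct(-1, "HOXB4", nm0), ">= 0")
  expect_error(simulate_ct(10, "NOPE", nm0), "intercept")
})

test_that("generators are pure functions of design and seed", {
  d <- spike_design(copies = c(0, 300), replicates = 3)
  expect_identical(simulate_spike_replicates(d, seed = 7),
                   simulate_spike_replicates(d, seed = 7))
  expect_false(identical(simulate_spike_replicates(d, seed = 7)$ct$ct,
                         simulate_spike_replicates(d, seed = 8)$ct$ct))
  cd <- cohort_design(n_cancer = 4, n_benign = 2, n_normal = 2)
  expect_identical(simulate_cohort(cd, seed = 5),
                   simulate_cohort(cd, seed = 5))
  expect_identical(
    simulate_longitudinal(n_patients = 2, n_draws = 3, seed = 9),
    simulate_longitudinal(n_patients = 2, n_draws = 3, seed = 9))
  # a missing seed is an error, never an implicit clock seed
  expect_error(simulate_spike_replicates(d), "seed")
  expect_error(simulate_cohort(cd), "seed")
})

test_that("spike replicates behave like the bench experiment", {
  sim <- simulate_spike_replicates(
    spike_design(copies = c(0, 300), replicates = 11), seed = 21)
  ct <- sim$ct
  zero_ids <- sim$truth$sample_id[sim$truth$copies == 0]
  zero_targets <- ct[ct$sample_id %in% zero_ids & ct$gene != "ACTB", ]
  expect_true(all(zero_targets$no_signal))

  # scored against its own calibration, the 300-copy median shifted
  # delta-Ct reproduces the calibration median
  cal <- build_calibration(ct[!(ct$sample_id %in% zero_ids), ])
  sc <- score_batch(ct, cal)
  g300 <- sc$genes[!(sc$genes$sample_id %in% zero_ids), ]
  med <- tapply(g300$delta_ct, g300$gene, median)
  expect_equal(as.numeric(med[cal$gene]), cal$median_delta_ct_300,
               tolerance = 1e-9)
  expect_false(any(g300$censored))
  # and the 0-copy condition scores as the designed negative control
  cm0 <- sc$samples$cm[sc$samples$sample_id %in% zero_ids]
  expect_true(all(cm0 == 0))
})

test_that("cohorts honour class labels, ACTB ranges and background settings", {
  d <- cohort_design(n_cancer = 12, n_benign = 5, n_normal = 5,
                     control = list(active_gene_prob = 0,
                                    copies_meanlog = log(300),
                                    copies_sdlog = 1.2,
                                    background_rate = 0))
  sim <- simulate_cohort(d, seed = 33)
  expect_equal(table(sim$truth$group_label)[c("cancer", "benign", "normal")],
               c(cancer = 12, benign = 5, normal = 5), ignore_attr = TRUE)
  expect_true(all(sim$truth$actb_ct[sim$truth$group_label == "cancer"] >=
                    16 &
                  sim$truth$actb_ct[sim$truth$group_label == "cancer"] <=
                    27.8))
  expect_true(all(sim$truth$actb_ct[sim$truth$group_label != "cancer"] >=
                    21 &
                  sim$truth$actb_ct[sim$truth$group_label != "cancer"] <=
                    27.4))

  # zero background: every control scores CM = 0
  cal <- flat_calibration(3.3)
  sc <- score_batch(sim$ct, cal)
  ctrl <- sc$samples$group_label != "cancer"
  expect_true(all(sc$samples$cm[ctrl] == 0))

  # a large designed effect separates the classes completely
  strong <- cohort_design(n_cancer = 10, n_benign = 0, n_normal = 10,
                          cancer = list(active_gene_prob = 1,
                                        copies_meanlog = log(600),
                                        copies_sdlog = 0.3,
                                        background_rate = 0),
                          control = d$control)
  sc2 <- score_batch(simulate_cohort(strong, seed = 34)$ct, cal)
  ev <- evaluate_cohort(sc2, threshold = 38.5)
  expect_equal(ev$roc$auc, 1)
  expect_equal(ev$confusion$accuracy[1], 1)
})

test_that("matched class distributions give chance-level separation", {
  null_d <- cohort_design_auc(auc = 0.5, n_cancer = 20, n_control = 20)
  expect_equal(null_d$cancer$copies_meanlog, null_d$control$copies_meanlog)
  cal <- flat_calibration(3.3)
  aucs <- vapply(1:60, function(i) {
    sc <- score_batch(simulate_cohort(null_d, seed = 400 + i)$ct, cal)
    roc_auc(sc$samples$cm, sc$samples$group_label == "cancer")$auc
  }, numeric(1))
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 1e-12)
})

test_that("duplicate-user sets pair each run and track the user noise", {
  d <- cohort_design(n_cancer = 11, n_benign = 0, n_normal = 4)
  sim <- simulate_cohort(d, seed = 55)
  cal <- flat_calibration(3.3)

  # noiseless duplication with fixed molecules is a perfect copy
  dup0 <- simulate_interuser(sim, user_noise_sd = 0, seed = 1,
                             resample_molecules = FALSE)
  expect_identical(dup0$user_a, dup0$user_b)
  expect_equal(length(unique(dup0$user_b$sample_id)), 15)

  dup <- simulate_interuser(sim, user_noise_sd = 0.3, seed = 2)
  sa <- score_batch(dup$user_a, cal)
  sb <- score_batch(dup$user_b, cal)
  rho <- spearman_concordance(sa$samples$cm, sb$samples$cm)$rho
  expect_gt(rho, 0.8)
  expect_lt(rho, 1)
  # frozen regression value for the shipped defaults at this seed
  expect_equal(rho, 0.996031746, tolerance = 1e-6)
})

test_that("longitudinal patterns drive the expected trajectory shapes", {
  sim <- simulate_longitudinal(n_patients = 6, n_draws = 4, seed = 77)
  cal <- flat_calibration(4.3)
  sc <- score_batch(sim$ct, cal)
  tr <- summarize_trajectories(sc)
  patt <- sim$truth$pattern[match(tr$subject_id, sim$truth$subject_id)]
  resp <- tr[patt == "response" & tr$direction != "baseline", ]
  expect_gt(mean(resp$direction == "fall"), 0.5)

  rises <- vapply(1:3, function(s) {
    si <- simulate_longitudinal(n_patients = 3,
                                patterns = "progression",
                                n_draws = 5, seed = 100 + s)
    sci <- score_batch(si$ct, cal)
    tri <- summarize_trajectories(sci)
    sum(tri$direction == "rise")
  }, numeric(1))
  expect_true(all(rises >= 1))

  # a stable pattern with every noise layer off is exactly flat
  quiet <- noise_model("serum", ct_sd = 0, recovery_halfwidth = 0,
                       drift_span = 0, poisson = FALSE)
  sim0 <- simulate_longitudinal(n_patients = 2, patterns = "stable",
                                n_draws = 4, noise = quiet, seed = 5)
  tr0 <- summarize_trajectories(score_batch(sim0$ct, flat_calibration(4.3)))
  expect_true(all(tr0$direction[tr0$direction != "baseline"] == "flat"))
  expect_true(all(tr0$delta_baseline == 0))
})
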