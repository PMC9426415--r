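test_that("delta-Ct normalizes against the same-cartridge reference", {
  expect_equal(delta_ct(30, 25), 5)
  expect_equal(delta_ct(45, 25), 20)  # no-signal target propagates
  expect_equal(delta_ct(24, 24), 0)
  expect_equal(delta_ct(22, 25), -3)  # may be negative before shifting
  expect_error(delta_ct(30, 45), "reference gene has no signal")
  expect_error(delta_ct(NA_real_, 25), "finite")
})

test_that("shift constants are the smallest nonnegative integers reaching 1", {
  expect_equal(compute_gene_shifts(list(g = c(-2.4, 3.0))), c(g = 4L))
  expect_equal(compute_gene_shifts(list(g = c(5.0, 9.1))), c(g = 0L))
  expect_equal(compute_gene_shifts(list(g = 0.2)), c(g = 1L))
  expect_equal(compute_gene_shifts(list(g = 1.0)), c(g = 0L))
  expect_equal(compute_gene_shifts(list(g = c(-0.001, 8))), c(g = 2L))
  expect_equal(compute_gene_shifts(list(a = -3, b = 4)),
               c(a = 4L, b = 0L))
})

test_that("censoring removes signals above median + offset, strictly", {
  cal <- calibration_table(c(HOXB4 = 10))
  expect_equal(censor_low_signal(24, "HOXB4", cal), 0)
  expect_equal(censor_low_signal(23, "HOXB4", cal), 23)  # equality retained
  expect_equal(censor_low_signal(5, "HOXB4", cal), 5)
  expect_equal(censor_low_signal(c(24, 23, 22.999), "HOXB4", cal),
               c(0, 23, 22.999))
  expect_error(censor_low_signal(5, "GPX7", cal), "no calibration entry")

  # the shift constant moves the bound with the data
  cal2 <- calibration_table(c(HOXB4 = 10), shift_constant = 2L)
  expect_equal(censor_low_signal(24, "HOXB4", cal2), 24)
  expect_equal(censor_low_signal(25.5, "HOXB4", cal2), 0)
})

test_that("gene methylation is m_scale over delta-Ct with a zero sentinel", {
  expect_equal(gene_methylation(12), 100)
  expect_equal(gene_methylation(0), 0)
  expect_equal(gene_methylation(24), 50)
  expect_equal(gene_methylation(c(12, 0, 24)), c(100, 0, 50))
  expect_error(gene_methylation(-1), "nonnegative")
})

test_that("score_sample composes the four steps", {
  cal <- flat_calibration(3)  # censoring bound 16

  # negative-control behaviour: everything no-signal, ACTB present
  blank <- score_sample(run_from_cts("blank"), cal)
  expect_true(blank$samples$valid)
  expect_equal(blank$samples$cm, 0)
  expect_true(all(blank$genes$censored))

  # exactly one gene at delta-Ct 12, the rest censored -> CM = 100
  one <- score_sample(run_from_cts("one", c(AKR1B1 = 37)), cal)
  expect_equal(one$samples$cm, 100)
  expect_equal(one$genes$m[one$genes$gene == "AKR1B1"], 100)

  # reference dropout in either cartridge invalidates the whole sample
  run <- run_from_cts("dead", c(AKR1B1 = 30), actb = c(A = 45, B = 25))
  run$no_signal[run$gene == "ACTB" & run$cartridge_id == "A"] <- TRUE
  dead <- score_sample(run, cal)
  expect_false(dead$samples$valid)
  expect_true(is.na(dead$samples$cm))
  expect_match(dead$samples$invalid_reason, "ACTB")
})

test_that("CM sums per-gene M exactly and ignores row order", {
  cal <- flat_calibration(10)
  run <- run_from_cts("s", c(AKR1B1 = 30, HOXB4 = 31, RASSF1 = 33,
                             TM6SF1 = 29))
  sc <- score_sample(run, cal)
  expect_equal(sc$samples$cm, sum(sc$genes$m))
  shuffled <- run[rev(seq_len(nrow(run))), ]
  sc2 <- score_sample(shuffled, cal)
  expect_equal(sc2$samples$cm, sc$samples$cm)
})

test_that("M is strictly decreasing in delta-Ct, so CM never gains from later Ct", {
  cal <- flat_calibration(10)
  dct <- seq(0.5, 23, by = 0.5)  # within the censoring bound
  m <- gene_methylation(dct)
  expect_true(all(diff(m) < 0))

  # raising one gene's Ct (hence its delta-Ct) never raises CM
  base <- run_from_cts("s", c(AKR1B1 = 28, HOXB4 = 30))
  cm_of <- function(akr_ct) {
    r <- run_from_cts("s", c(AKR1B1 = akr_ct, HOXB4 = 30))
    score_sample(r, cal)$samples$cm
  }
  cms <- vapply(seq(28, 44.5, by = 1.5), cm_of, numeric(1))
  expect_true(all(diff(cms) <= 1e-12))
})

test_that("censoring is idempotent", {
  cal <- flat_calibration(4)
  x <- c(25, 16.99, 17.5, 0, 3)
  once <- censor_low_signal(x, "HOXB4", cal)
  expect_equal(censor_low_signal(once, "HOXB4", cal), once)
})

test_that("the censoring decision is invariant to batch shifting", {
  cal <- flat_calibration(5)
  offset <- cm_cfg$constants$censor_offset
  for (seed in 1:8) {
    set.seed(seed)
    # random batch: some genes driven negative so shifts engage
    runs <- do.call(rbind, lapply(1:6, function(i) {
      cts <- structure(runif(9, 20, 45), names = cm_genes)
      cts[sample(9, 3)] <- runif(3, 20, 24)  # below the 25-cycle reference
      run_from_cts(paste0("s", i), cts)
    }))
    runs$no_signal <- runs$ct == 45
    sc <- score_batch(runs, cal)
    expect_true(any(sc$shifts > 0))
    # oracle: raw-scale rule, no shift at all
    raw_censored <- sc$genes$delta_ct_raw >
      (cal$median_delta_ct_300[match(sc$genes$gene, cal$gene)] + offset)
    expect_equal(sc$genes$censored, raw_censored)
  }
})

test_that("calibration medians follow the sorted-median convention", {
  reps <- function(dcts, gene = "AKR1B1") {
    do.call(rbind, lapply(seq_along(dcts), function(i) {
      run_from_cts(paste0("r", i),
                   structure(25 + dcts[i], names = gene))
    }))
  }
  cal3 <- build_calibration(reps(c(10, 11, 12)))
  expect_equal(cal3$median_delta_ct_300[cal3$gene == "AKR1B1"], 11)
  cal4 <- build_calibration(reps(c(9, 10, 11, 14)))
  expect_equal(cal4$median_delta_ct_300[cal4$gene == "AKR1B1"], 10.5)
  expect_equal(unique(cal4$shift_constant), 0L)
  expect_error(build_calibration(reps(c(10, 12))), "at least 3")

  path <- withr::local_tempfile(fileext = ".csv")
  write_calibration(cal4, path)
  expect_equal(read_calibration(path), cal4, ignore_attr = TRUE)
})

test_that("replicate CV is the sample-sd to mean ratio in percent", {
  expect_equal(replicate_cv(c(100, 100, 100)), 0)
  expect_equal(replicate_cv(c(90, 110)), 14.14214, tolerance = 1e-6)
  expect_warning(cv0 <- replicate_cv(c(0, 0)), "undefined")
  expect_true(is.na(cv0))
  expect_error(replicate_cv(100), "at least two")
})
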