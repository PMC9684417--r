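test_that("peak matching applies the +-50 ms rule", {
  fs <- 500
  ann <- function(i, lab = "fetal_ref") annotation_set(i, fs, lab)
  # 20 ms apart: matched
  m1 <- match_peaks(ann(110, "fetal_det"), ann(100))
  expect_equal(unlist(m1[, c("tp", "fp", "fn")]), c(tp = 1, fp = 0, fn = 0))
  # 60 ms apart: unmatched on both sides
  m2 <- match_peaks(ann(130, "fetal_det"), ann(100))
  expect_equal(unlist(m2[, c("tp", "fp", "fn")]), c(tp = 0, fp = 1, fn = 1))
  # a double detection of one reference counts once
  m3 <- match_peaks(ann(c(100, 101, 200), "fetal_det"), ann(c(100, 200)))
  expect_equal(unlist(m3[, c("tp", "fp", "fn")]), c(tp = 2, fp = 1, fn = 0))
  expect_equal(brute_force_tp(c(100, 101, 200), c(100, 200), 25), 2)

  expect_error(match_peaks(ann(1), annotation_set(1, 250, "fetal_ref")),
               "sampling rate")
})

test_that("matching bookkeeping holds on random instances and agrees with brute force", {
  withr::with_seed(8, {
    for (i in 1:1000) {
      inst <- random_matching_instance()
      m <- match_peaks(annotation_set(inst$det, 500, "fetal_det"),
                       annotation_set(inst$ref, 500, "fetal_ref"))
      expect_identical(m$tp + m$fn, length(inst$ref))
      expect_identical(m$tp + m$fp, length(unique(inst$det)))
      # swapping roles swaps FP and FN
      m_sw <- match_peaks(annotation_set(inst$ref, 500, "fetal_det"),
                          annotation_set(inst$det, 500, "fetal_ref"))
      expect_identical(m_sw$tp, m$tp)
      expect_identical(m_sw$fp, m$fn)
      expect_identical(m_sw$fn, m$fp)
      if (i <= 200) {
        expect_identical(m$tp, brute_force_tp(unique(sort(inst$det)),
                                              inst$ref, 0.05 * 500))
      }
    }
  })
})

test_that("metric formulas reproduce the published per-record values", {
  # spot rows of the published benchmark
  r03 <- compute_metrics(547, 225, 169)
  expect_equal(round(unlist(r03[, c("acc", "se", "ppv", "f1")]), 2),
               c(acc = 58.13, se = 76.40, ppv = 70.85, f1 = 73.52))
  r10 <- compute_metrics(627, 0, 0)
  expect_equal(unlist(r10[, c("acc", "se", "ppv", "f1")]),
               c(acc = 100, se = 100, ppv = 100, f1 = 100))
  r08 <- compute_metrics(644, 0, 1)
  expect_equal(round(unlist(r08[, c("acc", "se", "ppv", "f1")]), 2),
               c(acc = 99.84, se = 99.84, ppv = 100.00, f1 = 99.92))

  # the full published table, all 22 rows, to 2 decimals
  bench <- benchmark_detection_counts()
  for (i in seq_len(nrow(bench))) {
    got <- compute_metrics(bench$tp[i], bench$fp[i], bench$fn[i])
    expect_equal(round(got$acc, 2), bench$acc[i])
    expect_equal(round(got$se, 2), bench$se[i])
    expect_equal(round(got$ppv, 2), bench$ppv[i])
    expect_equal(round(got$f1, 2), bench$f1[i])
  }
})

test_that("F1 equals its algebraic twin and degenerate counts error", {
  withr::with_seed(9, {
    for (i in 1:50) {
      tp <- sample(1:500, 1); fp <- sample(0:100, 1); fn <- sample(0:100, 1)
      st <- compute_metrics(tp, fp, fn)
      expect_equal(st$f1, 200 * tp / (2 * tp + fp + fn), tolerance = 1e-9)
    }
  })
  expect_error(compute_metrics(0, 0, 0), "zero")
  expect_error(compute_metrics(0, 5, 0), "SE undefined")
  expect_error(compute_metrics(0, 0, 5), "PPV undefined")
})

test_that("fHR traces turn RR intervals into bpm with a 30-beat smoother", {
  fs <- 500
  const <- annotation_set(seq(0, by = 250, length.out = 80), fs, "fetal_det")
  tr <- fhr_trace(const)
  expect_true(all(tr$bpm_raw == 120))
  expect_true(all(tr$bpm_smooth == 120))

  # alternating 0.4/0.6 s: raw alternates 150/100, interior smooth ~125
  rr <- rep(c(0.4, 0.6), 40)
  alt <- annotation_set(cumsum(c(0, rr)) * fs, fs, "fetal_det")
  tra <- fhr_trace(alt)
  expect_equal(sort(unique(tra$bpm_raw)), c(100, 150))
  interior <- tra$bpm_smooth[20:60]
  expect_true(all(abs(interior - 125) <= 1))

  expect_error(fhr_trace(annotation_set(5, fs, "fetal_det")), "2 peaks")
})

test_that("baseline follows the NICHD exclusion rule and optional rounding", {
  fs <- 500
  mk_trace <- function(bpm_of_minute, minutes = 10) {
    times <- c()
    t <- 0
    while (t < minutes * 60) {
      b <- bpm_of_minute(t)
      t <- t + 60 / b
      times <- c(times, t)
    }
    fhr_trace(annotation_set(round(times * fs), fs, "fetal_det"))
  }
  flat <- mk_trace(function(t) 140)
  expect_equal(baseline_rate(flat), 140, tolerance = 0.1)
  expect_equal(baseline_rate(flat, round_to_5 = TRUE), 140)

  near <- mk_trace(function(t) 142)
  expect_equal(baseline_rate(near, round_to_5 = TRUE), 140)

  # one 1-minute excursion of +30 bpm is excluded from the baseline
  exc <- mk_trace(function(t) if (t >= 240 && t < 300) 170 else 140)
  expect_equal(baseline_rate(exc), 140, tolerance = 0.5)

  expect_error(baseline_rate(fhr_trace(annotation_set(seq(0, 5000, by = 250),
                                                      fs, "fetal_det"))),
               "1 minute")
})

test_that("variability is the median per-minute peak-to-trough amplitude", {
  fs <- 500
  # constant trace: zero variability
  const <- annotation_set(seq(0, by = 214, length.out = 600), fs, "fetal_det")
  expect_equal(variability(fhr_trace(const)), 0, tolerance = 1e-9)

  # 5 bpm-amplitude sinusoid, 30 s period: ~10 bpm peak-to-trough
  times <- c(); t <- 0
  while (t < 300) {
    b <- 140 + 5 * sin(2 * pi * t / 30)
    t <- t + 60 / b
    times <- c(times, t)
  }
  tr <- fhr_trace(annotation_set(round(times * fs), fs, "fetal_det"),
                  smooth_window = 4)
  v <- variability(tr)
  expect_equal(v, 10, tolerance = 1)

  # one wild minute among quiet minutes does not move the median
  times2 <- c(); t <- 0
  while (t < 300) {
    b <- if (t >= 120 && t < 180) 140 + 20 * sin(2 * pi * t / 7) else
      140 + 2 * sin(2 * pi * t / 30)
    t <- t + 60 / b
    times2 <- c(times2, t)
  }
  tr2 <- fhr_trace(annotation_set(round(times2 * fs), fs, "fetal_det"),
                   smooth_window = 4)
  expect_lt(variability(tr2), 8)
})

test_that("signal quality indices obey the moment laws", {
  withr::with_seed(10, {
    g <- rnorm(1e6)
    expect_equal(ksqi(g), 3, tolerance = 0.05)
    expect_equal(ssqi(g), 0, tolerance = 0.01)

    # Laplace via inverse transform: kurtosis 6
    u <- runif(1e6) - 0.5
    lap <- -sign(u) * log(1 - 2 * abs(u))
    expect_equal(ksqi(lap), 6, tolerance = 0.2)

    # unit-rate exponential: skewness 2
    expect_equal(ssqi(rexp(1e6)), 2, tolerance = 0.02)
  })
  expect_error(ksqi(rep(1, 10)), "Zero-variance")
  expect_error(ssqi(1:3), "4 samples")
})

test_that("evaluate_record bundles the three protocols", {
  fs <- 500
  idx <- seq(0, by = 215, length.out = 400)
  ref <- annotation_set(idx, fs, "fetal_ref")
  det <- annotation_set(idx, fs, "fetal_det")
  rep1 <- evaluate_record(det, ref)
  expect_equal(rep1$stats$fp, 0)
  expect_equal(rep1$stats$fn, 0)
  expect_equal(unlist(rep1$stats[, c("acc", "se", "ppv", "f1")]),
               c(acc = 100, se = 100, ppv = 100, f1 = 100))
  expect_equal(rep1$clinical$baseline_bpm[1], rep1$clinical$baseline_bpm[2])

  # no detections: SE = 0 and PPV surfaces as NA instead of an error
  rep2 <- evaluate_record(annotation_set(numeric(0), fs, "fetal_det"), ref)
  expect_equal(rep2$stats$se, 0)
  expect_true(is.na(rep2$stats$ppv))

  out <- generate_record(synth_config(duration_s = 30, seed = 36))
  rep3 <- evaluate_record(det, ref, get_channel(out$record, 1))
  expect_true(is.finite(rep3$sqi$ksqi))
  expect_true(is.finite(rep3$sqi$ssqi))
  expect_s3_class(autoplot(rep3), "ggplot")
})
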