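test_that("cycle windows land exactly where the section durations say", {
  rec <- signal_record(rnorm(2000), fs = 500)
  segs <- segment_cycles(rec, annotation_set(1000, 500, "maternal_ref"))
  expect_equal(segs$win_start, 875)
  expect_equal(segs$win_end, 1225)
  expect_false(segs$truncated)
  expect_length(segs$p[[1]], 100)    # 0.20 s
  expect_length(segs$qrs[[1]], 50)   # 2 x 0.05 s
  expect_length(segs$t[[1]], 200)    # 0.40 s
  expect_equal(segs$win_end - segs$win_start, 350)  # 0.70 s total
  # QRS window is [r-25, r+25): the R sample itself is sample 26 of the QRS
  expect_equal(segs$qrs[[1]][26], rec$samples[1, 1001])
})

test_that("edge and overlap truncation rules apply", {
  rec <- signal_record(rnorm(2000), fs = 500)
  early <- segment_cycles(rec, annotation_set(10, 500, "maternal_ref"))
  expect_true(early$truncated)

  # two beats 0.4 s apart: T of beat 1 is cut at beat 2's P start
  two <- segment_cycles(rec, annotation_set(c(600, 800), 500, "maternal_ref"))
  expect_true(two$truncated[1])
  expect_equal(two$eff_end[1], 800 - 125)   # next P starts at r2 - 125
  expect_false(two$truncated[2])
  expect_length(two$t[[1]], 800 - 125 - 625)

  # empty annotation set -> empty segment table
  none <- segment_cycles(rec, annotation_set(numeric(0), 500, "maternal_ref"))
  expect_equal(nrow(none), 0)
})

test_that("averaging uses only full beats and degenerates sensibly", {
  x <- rep(0, 4000)
  beat <- sin(seq(0, pi, length.out = 350))
  for (r in c(1000, 2000, 3000)) x[(r - 125):(r + 224) + 1] <- beat
  rec <- signal_record(x, 500)
  peaks <- annotation_set(c(1000, 2000, 3000), 500, "maternal_ref")
  segs <- segment_cycles(rec, peaks)
  basis <- average_cycles(segs)
  # mean of identical beats is the beat
  expect_equal(c(basis$mu_p, basis$mu_qrs, basis$mu_t), beat)
  expect_equal(basis$n_beats, 3)

  # single available beat -> basis is that beat
  one <- average_cycles(segment_cycles(rec, annotation_set(1000, 500,
                                                           "maternal_ref")))
  expect_equal(c(one$mu_p, one$mu_qrs, one$mu_t), beat)

  # cancelling beats average to zero and the matrix build then fails
  x2 <- rep(0, 4000)
  x2[(1000 - 125):(1000 + 224) + 1] <- beat
  x2[(2000 - 125):(2000 + 224) + 1] <- -beat
  zero_basis <- average_cycles(segment_cycles(signal_record(x2, 500),
                                              annotation_set(c(1000, 2000), 500,
                                                             "maternal_ref")))
  expect_error(build_template_matrix(zero_basis), "rank")

  expect_error(average_cycles(segment_cycles(rec, annotation_set(10, 500,
                                                                 "maternal_ref"))),
               "No non-truncated")
})

test_that("the block matrix has the documented layout and diagonal Gram", {
  m <- build_template_matrix(toy_basis())
  expect_equal(unname(m),
               rbind(c(1, 0, 0), c(2, 0, 0), c(0, 3, 0), c(0, 0, 1)))
  expect_equal(unname(crossprod(m)), diag(c(5, 9, 1)))

  # default spec at 500 Hz gives a 350 x 3 matrix
  rec <- signal_record(rnorm(2000), 500)
  basis <- average_cycles(segment_cycles(rec, annotation_set(1000, 500,
                                                             "maternal_ref")))
  expect_equal(dim(build_template_matrix(basis)), c(350, 3))
})

test_that("least-squares scaling equals per-section projection and recovers", {
  m <- build_template_matrix(toy_basis())
  a <- ls_scaling(m, c(2, 4, 3, 0.5))
  expect_equal(unname(a), c(2, 1, 0.5))

  # exact recovery of a known scaling in the noiseless case
  truth <- c(1.5, 0.8, 1.2)
  expect_equal(unname(ls_scaling(m, as.numeric(m %*% truth))), truth)

  # self-scaling identity
  expect_equal(unname(ls_scaling(m, c(1, 2, 3, 1))), c(1, 1, 1))

  # normal-equations and per-section projection formulations agree
  withr::with_seed(3, {
    for (i in 1:20) {
      cyc <- rnorm(4)
      proj <- c(sum(c(1, 2) * cyc[1:2]) / 5, 3 * cyc[3] / 9, cyc[4] / 1)
      expect_equal(unname(ls_scaling(m, cyc)), proj, tolerance = 1e-10)
    }
  })
  expect_error(ls_scaling(m, 1:3), "length")
})

test_that("fitted residuals behave like a least-squares optimum", {
  m <- build_template_matrix(toy_basis())
  truth <- c(1.5, 0.8, 1.2)
  cyc <- as.numeric(m %*% truth)
  expect_equal(fit_template(m, ls_scaling(m, cyc), cyc)$residual_sq, 0)

  noisy <- cyc + c(0.1, -0.2, 0.05, 0.3)
  expect_equal(fit_template(m, c(0, 0, 0), noisy)$residual_sq, sum(noisy^2))

  a_ls <- ls_scaling(m, noisy)
  best <- fit_template(m, a_ls, noisy)$residual_sq
  withr::with_seed(4, {
    others <- vapply(1:1000, function(i) {
      fit_template(m, a_ls + rnorm(3, sd = 0.5), noisy)$residual_sq
    }, numeric(1))
  })
  expect_true(all(others >= best - 1e-12))
})

test_that("template subtraction cancels exactly and leaves the rest alone", {
  fs <- 500
  x <- rep(0, 3000)
  beat <- cos(seq(0, 4 * pi, length.out = 350))
  peaks <- c(800, 1600, 2400)
  for (r in peaks) x[(r - 125):(r + 224) + 1] <- beat
  spikes_at <- c(400, 1200, 2000) + 1   # between beats, outside all windows
  x[spikes_at] <- x[spikes_at] + 5
  rec <- signal_record(x, fs)
  ann <- annotation_set(peaks, fs, "maternal_ref")
  segs <- segment_cycles(rec, ann)
  basis <- average_cycles(segs)
  m <- build_template_matrix(basis)
  fits <- lapply(seq_len(nrow(segs)), function(k) {
    ck <- x[(segs$eff_start[k] + 1):segs$eff_end[k]]
    fit_template(m, ls_scaling(m, ck), ck)
  })
  out <- subtract_templates(rec, segs, fits)
  inside <- unlist(lapply(seq_len(nrow(segs)),
                          function(k) (segs$eff_start[k] + 1):segs$eff_end[k]))
  expect_lt(max(abs(out$samples[1, inside])), 1e-10)   # perfect cancellation
  expect_equal(out$samples[1, spikes_at], rep(5, 3))   # spikes preserved
  outside <- setdiff(seq_along(x), c(inside, spikes_at))
  expect_equal(out$samples[1, outside], x[outside])

  # no beats -> identity
  empty <- segment_cycles(rec, annotation_set(numeric(0), fs, "maternal_ref"))
  expect_equal(subtract_templates(rec, empty, list())$samples, rec$samples)

  # mismatched fit length is a shape error
  bad <- fits
  bad[[1]]$template <- bad[[1]]$template[-1]
  expect_error(subtract_templates(rec, segs, bad), "length")
})

test_that("subtraction is linear over disjoint additions", {
  fs <- 500
  withr::with_seed(5, base <- rnorm(3000, sd = 0.1))
  beat <- sin(seq(0, 2 * pi, length.out = 350))
  peaks <- c(700, 1500, 2300)
  x <- base
  for (r in peaks) x[(r - 125):(r + 224) + 1] <-
    x[(r - 125):(r + 224) + 1] + beat
  rec <- signal_record(x, fs)
  ann <- annotation_set(peaks, fs, "maternal_ref")
  segs <- segment_cycles(rec, ann)
  m <- build_template_matrix(average_cycles(segs))
  fits <- lapply(seq_len(nrow(segs)), function(k) {
    ck <- x[(segs$eff_start[k] + 1):segs$eff_end[k]]
    fit_template(m, ls_scaling(m, ck), ck)
  })
  out1 <- subtract_templates(rec, segs, fits)
  # adding content outside the windows commutes with subtraction
  y <- x
  extra_at <- c(300, 1100)
  y[extra_at] <- y[extra_at] + 2
  out2 <- subtract_templates(signal_record(y, fs), segs, fits)
  expect_equal(out2$samples[1, -extra_at], out1$samples[1, -extra_at])
  expect_equal(out2$samples[1, extra_at], out1$samples[1, extra_at] + 2)
})

test_that("fit_cycles_ls summarises per-beat fits", {
  fs <- 500
  x <- rep(0, 3000)
  beat <- sin(seq(0.3, 2 * pi, length.out = 350))
  peaks <- c(800, 1600, 2400)
  scal <- rbind(c(1.1, 0.9, 1.0), c(0.8, 1.2, 1.05), c(1, 1, 1))
  sec <- rep(1:3, times = c(100, 50, 200))
  for (k in seq_along(peaks)) {
    r <- peaks[k]
    x[(r - 125):(r + 224) + 1] <- beat * scal[k, sec]
  }
  rec <- signal_record(x, fs)
  basis <- structure(list(mu_p = beat[1:100], mu_qrs = beat[101:150],
                          mu_t = beat[151:350], n_beats = 1L),
                     class = "template_basis")
  fits <- fit_cycles_ls(rec, annotation_set(peaks, fs, "maternal_ref"),
                        basis = basis)
  expect_equal(as.matrix(fits[, c("a_p", "a_qrs", "a_t")]),
               scal, ignore_attr = TRUE, tolerance = 1e-10)
  expect_true(all(fits$residual_sq < 1e-18))
})
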