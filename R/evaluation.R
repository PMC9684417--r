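#' Match detected against reference R-peaks
#'
#' Greedy one-to-one matching under a timing tolerance: references are swept
#' in order and each is paired with the nearest still-unmatched detection
#' within `tol_s` (ties go to the earlier detection). Paired peaks are true
#' positives; unpaired detections are false positives and unpaired references
#' false negatives, so `tp + fn = |reference|` and `tp + fp = |detected|`
#' always hold.
#'
#' @param detected,reference [annotation_set]s sharing a sampling rate.
#' @param tol_s Matching tolerance in seconds (default the conventional
#'   +/- 50 ms).
#' @return One-row tibble with `tp`, `fp`, `fn`; the matched index pairs are
#'   attached as the `"pairs"` attribute.
#' @export
match_peaks <- function(detected, reference, tol_s = 0.05) {
  stopifnot(inherits(detected, "annotation_set"), inherits(reference, "annotation_set"))
  if (!isTRUE(all.equal(detected$fs, reference$fs))) {
    abort("Detected and reference annotations must share a sampling rate.")
  }
  tol <- tol_s * detected$fs
  det <- detected$indices
  ref <- reference$indices
  used <- rep(FALSE, length(det))
  pairs_ref <- numeric(0)
  pairs_det <- numeric(0)
  for (r in ref) {
    free <- which(!used)
    if (length(free) == 0) break
    d <- abs(det[free] - r)
    ok <- free[d <= tol]
    if (length(ok) == 0) next
    dd <- abs(det[ok] - r)
    best <- ok[order(dd, det[ok])][1]  # nearest; ties -> earlier detection
    used[best] <- TRUE
    pairs_ref <- c(pairs_ref, r)
    pairs_det <- c(pairs_det, det[best])
  }
  tp <- length(pairs_ref)
  out <- tibble(tp = tp, fp = length(det) - tp, fn = length(ref) - tp)
  attr(out, "pairs") <- tibble(reference = pairs_ref, detected = pairs_det)
  out
}

#' Beat-detection statistics
#'
#' The standard fetal R-peak detection metrics, as percentages:
#' `ACC = 100 TP / (TP + FP + FN)`, `SE = 100 TP / (TP + FN)`,
#' `PPV = 100 TP / (TP + FP)` and the F1 score
#' `F1 = 2 SE PPV / (SE + PPV)`.
#'
#' Values are computed unrounded; round only for display.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return A one-row tibble (class `detection_stats`) with the counts and
#'   `acc`, `se`, `ppv`, `f1` in percent.
#' @examples
#' compute_metrics(547, 225, 169)  # ACC 58.13, SE 76.40, PPV 70.85, F1 73.52
#' @export
compute_metrics <- function(tp, fp, fn) {
  if (tp < 0 || fp < 0 || fn < 0) abort("Counts must be non-negative.")
  if (tp + fp + fn == 0) abort("All counts are zero: metrics undefined.")
  if (tp + fn == 0) abort("No reference peaks (tp + fn = 0): SE undefined.")
  if (tp + fp == 0) abort("No detections (tp + fp = 0): PPV undefined.")
  se <- 100 * tp / (tp + fn)
  ppv <- 100 * tp / (tp + fp)
  f1 <- if (se + ppv == 0) 0 else 2 * se * ppv / (se + ppv)
  out <- tibble(
    tp = tp, fp = fp, fn = fn,
    acc = 100 * tp / (tp + fp + fn),
    se = se, ppv = ppv, f1 = f1
  )
  class(out) <- c("detection_stats", class(out))
  out
}

#' Beat-to-beat fetal heart rate trace
#'
#' `bpm_raw[i] = 60 fs / (indices[i+1] - indices[i])` for each RR interval;
#' `bpm_smooth` is a centred moving average over a 30-beat window, shrinking
#' symmetrically at the trace edges.
#'
#' @param r_peaks [annotation_set] with at least 2 peaks (31 or more for a
#'   full smoothing window).
#' @param smooth_window Moving-average window length in beats.
#' @return A tibble (class `fhr_trace`) with `beat`, `time_s` (interval end),
#'   `bpm_raw`, `bpm_smooth`.
#' @export
fhr_trace <- function(r_peaks, smooth_window = 30L) {
  stopifnot(inherits(r_peaks, "annotation_set"))
  idx <- r_peaks$indices
  if (length(idx) < 2) abort("Need at least 2 peaks for an fHR trace.")
  rr <- diff(idx) / r_peaks$fs
  if (any(rr <= 0)) abort("Non-positive RR interval.")
  bpm <- 60 / rr
  n <- length(bpm)
  half <- floor(smooth_window / 2)
  smooth <- vapply(seq_len(n), function(i) {
    k <- min(half, i - 1, n - i)
    mean(bpm[(i - k):(i + k)])
  }, numeric(1))
  out <- tibble(
    beat = seq_len(n),
    time_s = idx[-1] / r_peaks$fs,
    bpm_raw = bpm,
    bpm_smooth = smooth
  )
  attr(out, "fs") <- r_peaks$fs
  class(out) <- c("fhr_trace", class(out))
  out
}

#' @export
autoplot.fhr_trace <- function(object, ...) {
  ggplot(object, aes(x = .data$time_s)) +
    geom_line(aes(y = .data$bpm_raw), colour = "grey70") +
    geom_line(aes(y = .data$bpm_smooth), colour = "black") +
    labs(x = "Time (s)", y = "fHR (bpm)", title = "Fetal heart rate trace") +
    theme_minimal()
}

trace_duration <- function(trace) {
  max(trace$time_s) - min(trace$time_s) + median(60 / trace$bpm_raw)
}

#' NICHD-style baseline fetal heart rate
#'
#' Mean of the smoothed fHR over (at most) the first 10 minutes, iteratively
#' excluding 1-minute segments whose segment mean deviates from the running
#' estimate by more than 25 bpm (the NICHD exclusion criterion), until the
#' exclusion set stabilises (at most 10 passes). Optionally rounded to the
#' nearest multiple of 5 bpm as in clinical reporting.
#'
#' @param trace An [fhr_trace()] of at least 1 minute.
#' @param round_to_5 Round the result to the nearest 5 bpm?
#' @return Baseline rate in bpm.
#' @export
baseline_rate <- function(trace, round_to_5 = FALSE) {
  stopifnot(inherits(trace, "fhr_trace"))
  if (trace_duration(trace) < 60) abort("Trace shorter than 1 minute.")
  horizon <- min(600, max(trace$time_s))
  use <- trace[trace$time_s <= horizon, ]
  seg <- floor(use$time_s / 60)
  excluded <- integer(0)
  for (pass in seq_len(10)) {
    inc <- !(seg %in% excluded)
    if (!any(inc)) abort("All 1-minute segments excluded: baseline undefined.")
    est <- mean(use$bpm_smooth[inc])
    seg_means <- tapply(use$bpm_smooth, seg, mean)
    new_excluded <- as.integer(names(seg_means))[abs(seg_means - est) > 25]
    if (setequal(new_excluded, excluded)) break
    excluded <- new_excluded
  }
  inc <- !(seg %in% excluded)
  if (!any(inc)) abort("All 1-minute segments excluded: baseline undefined.")
  est <- mean(use$bpm_smooth[inc])
  if (round_to_5) est <- 5 * round(est / 5)
  est
}

#' Fetal heart rate variability
#'
#' Peak-to-trough amplitude of the smoothed fHR fluctuations around baseline:
#' per non-overlapping 1-minute window, the range (max minus min) of the
#' baseline-detrended smoothed trace is computed, and the median over windows
#' is returned (robust to a single disturbed minute).
#'
#' @param trace An [fhr_trace()] of at least 2 minutes.
#' @return Variability in bpm (peak-to-trough).
#' @export
variability <- function(trace) {
  stopifnot(inherits(trace, "fhr_trace"))
  if (trace_duration(trace) < 120) abort("Trace shorter than 2 minutes.")
  base <- baseline_rate(trace)
  detr <- trace$bpm_smooth - base
  seg <- floor(trace$time_s / 60)
  full <- seg[seg < floor(max(trace$time_s) / 60)]
  amps <- tapply(detr[seg %in% full], seg[seg %in% full],
                 function(v) max(v) - min(v))
  median(as.numeric(amps))
}

#' Kurtosis signal quality index (kSQI)
#'
#' Fourth standardized moment of the signal, Pearson convention (Gaussian =
#' 3), population estimator. For extracted fECG, kSQI above 5 is the usual
#' high-quality criterion: spiky, outlier-free ECG is strongly leptokurtic
#' while broadband noise is near-Gaussian.
#'
#' @param x Single-channel [signal_record] or numeric vector with at least 4
#'   samples and nonzero variance.
#' @return The index value.
#' @export
ksqi <- function(x) {
  sqi_moment(x, moment_kurtosis)
}

#' Skewness signal quality index (sSQI)
#'
#' Third standardized moment (population estimator); see [ksqi()].
#'
#' @inheritParams ksqi
#' @return The index value.
#' @export
ssqi <- function(x) {
  sqi_moment(x, moment_skewness)
}

sqi_moment <- function(x, fn) {
  if (inherits(x, "signal_record")) {
    if (n_channels(x) != 1L) abort("SQI expects a single channel.")
    x <- as.numeric(x$samples[1, ])
  }
  if (length(x) < 4) abort("Need at least 4 samples.")
  if (var(x) == 0) abort("Zero-variance signal: SQI undefined.")
  fn(x)
}

#' Full evaluation report for an extraction
#'
#' Bundles the three evaluation protocols: detection statistics of the
#' detected against the reference annotations under the +/- 50 ms rule,
#' NICHD clinical features (baseline rate, variability) for both annotation
#' sets, signal quality indices of the extracted signal, and the pair of fHR
#' traces for visual comparison. Metrics that are undefined for the given
#' inputs (e.g. PPV with no detections) are reported as `NA` rather than
#' raised.
#'
#' @param detected,reference [annotation_set]s at the same sampling rate.
#' @param extracted Optional single-channel [signal_record] (the extracted
#'   fECG) for the SQI block.
#' @param tol_s Matching tolerance, seconds.
#' @param round_to_5 Round baselines to the nearest 5 bpm?
#' @return An `extraction_report` list with tibbles `stats`, `clinical`,
#'   `sqi`, and the `traces` pair.
#' @export
evaluate_record <- function(detected, reference, extracted = NULL,
                            tol_s = 0.05, round_to_5 = FALSE) {
  counts <- match_peaks(detected, reference, tol_s)
  stats <- tryCatch(
    compute_metrics(counts$tp, counts$fp, counts$fn),
    error = function(e) {
      out <- tibble(tp = counts$tp, fp = counts$fp, fn = counts$fn,
                    acc = if (counts$tp + counts$fp + counts$fn > 0)
                      100 * counts$tp / (counts$tp + counts$fp + counts$fn) else NA_real_,
                    se = if (counts$tp + counts$fn > 0)
                      100 * counts$tp / (counts$tp + counts$fn) else NA_real_,
                    ppv = if (counts$tp + counts$fp > 0)
                      100 * counts$tp / (counts$tp + counts$fp) else NA_real_,
                    f1 = NA_real_)
      class(out) <- c("detection_stats", class(out))
      out
    }
  )
  one_side <- function(ann, which) {
    tr <- tryCatch(fhr_trace(ann), error = function(e) NULL)
    tibble(
      set = which,
      n_peaks = length(ann$indices),
      baseline_bpm = if (is.null(tr)) NA_real_ else
        tryCatch(baseline_rate(tr, round_to_5), error = function(e) NA_real_),
      variability_bpm = if (is.null(tr)) NA_real_ else
        tryCatch(variability(tr), error = function(e) NA_real_)
    )
  }
  clinical <- dplyr::bind_rows(one_side(detected, "detected"),
                               one_side(reference, "reference"))
  sqi <- if (!is.null(extracted)) {
    tibble(ksqi = tryCatch(ksqi(extracted), error = function(e) NA_real_),
           ssqi = tryCatch(ssqi(extracted), error = function(e) NA_real_))
  } else {
    tibble(ksqi = NA_real_, ssqi = NA_real_)
  }
  traces <- list(
    detected = tryCatch(fhr_trace(detected), error = function(e) NULL),
    reference = tryCatch(fhr_trace(reference), error = function(e) NULL)
  )
  structure(
    list(stats = stats, clinical = clinical, sqi = sqi, traces = traces),
    class = "extraction_report"
  )
}

#' @export
print.extraction_report <- function(x, ...) {
  cat("Extraction evaluation report\n")
  cat(sprintf("  detection: TP %d  FP %d  FN %d | ACC %.2f  SE %.2f  PPV %.2f  F1 %.2f\n",
              x$stats$tp, x$stats$fp, x$stats$fn,
              x$stats$acc, x$stats$se, x$stats$ppv, x$stats$f1))
  for (i in seq_len(nrow(x$clinical))) {
    cat(sprintf("  %-9s: %d peaks, baseline %.2f bpm, variability %.2f bpm\n",
                x$clinical$set[i], x$clinical$n_peaks[i],
                x$clinical$baseline_bpm[i], x$clinical$variability_bpm[i]))
  }
  cat(sprintf("  quality  : kSQI %.2f  sSQI %.2f\n", x$sqi$ksqi, x$sqi$ssqi))
  invisible(x)
}

#' @export
autoplot.extraction_report <- function(object, ...) {
  if (is.null(object$traces$detected) || is.null(object$traces$reference)) {
    abort("Both fHR traces are needed for the comparison plot.")
  }
  df <- dplyr::bind_rows(
    dplyr::mutate(object$traces$detected, set = "estimated"),
    dplyr::mutate(object$traces$reference, set = "reference")
  )
  ggplot(df, aes(x = .data$time_s, y = .data$bpm_smooth, colour = .data$set)) +
    geom_line() +
    labs(x = "Time (s)", y = "fHR (bpm)", colour = NULL,
         title = "Estimated vs reference fHR trace") +
    theme_minimal()
}

#' Published benchmark detection counts
#'
#' TP/FP/FN counts and the reported ACC/SE/PPV/F1 values for the SA-GWO
#' extraction method on the 12 Labour (5 min) and 10 Pregnancy (20 min)
#' clinical abdominal-ECG records, as published. Useful for verifying the
#' metric formulas and dataset averages without downloading the recordings.
#'
#' @return A tibble with columns `dataset`, `record`, `tp`, `fp`, `fn` and
#'   the reported `acc`, `se`, `ppv`, `f1` (percent, 2 decimals).
#' @export
benchmark_detection_counts <- function() {
  path <- system.file("extdata", "benchmark_detection_counts.csv",
                      package = "sagwo", mustWork = TRUE)
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
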