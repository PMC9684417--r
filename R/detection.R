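#' QRS detector configuration
#'
#' Settings for the energy-based (Pan-Tompkins-style) R-peak detector:
#' band-pass, differentiate, square, moving-window integrate, adaptive
#' threshold, refractory enforcement, and refinement to the local extremum of
#' the band-passed signal.
#'
#' @param band_low_hz,band_high_hz Band-pass corner frequencies, Hz.
#' @param refractory_s Minimum spacing between detections, seconds.
#' @param min_rate_bpm,max_rate_bpm Plausible heart-rate range; `min_rate_bpm`
#'   sizes the peak population used for the adaptive threshold level.
#' @param threshold_factor Detection threshold as a fraction of the median
#'   integrated-peak level.
#' @param searchback Enable the Pan-Tompkins search-back stage: RR gaps
#'   longer than `searchback_rr_factor` times the median RR are re-scanned
#'   for the strongest candidate above `searchback_frac` of the main
#'   threshold.
#' @param searchback_rr_factor,searchback_frac Search-back gap trigger and
#'   relaxed-threshold fraction.
#' @param integration_s Moving-window integration length, seconds; should be
#'   on the order of the QRS duration (0.15 s adult, 0.08 s fetal).
#' @param refine_half_s Half-width of the window, around each integrated-peak
#'   candidate, searched for the band-passed extremum that localises the
#'   R-peak.
#' @return A `qrs_detector_config` list.
#' @export
qrs_detector_config <- function(band_low_hz = 5, band_high_hz = 15,
                                refractory_s = 0.35,
                                min_rate_bpm = 40, max_rate_bpm = 180,
                                threshold_factor = 0.4,
                                searchback = TRUE,
                                searchback_rr_factor = 1.66,
                                searchback_frac = 0.25,
                                integration_s = 0.15,
                                refine_half_s = 0.025) {
  if (band_low_hz <= 0 || band_high_hz <= band_low_hz) {
    abort("Need 0 < band_low_hz < band_high_hz.")
  }
  if (refractory_s <= 0) abort("refractory_s must be positive.")
  structure(
    list(band_low_hz = band_low_hz, band_high_hz = band_high_hz,
         refractory_s = refractory_s, min_rate_bpm = min_rate_bpm,
         max_rate_bpm = max_rate_bpm, threshold_factor = threshold_factor,
         searchback = isTRUE(searchback),
         searchback_rr_factor = searchback_rr_factor,
         searchback_frac = searchback_frac,
         integration_s = integration_s,
         refine_half_s = refine_half_s),
    class = "qrs_detector_config"
  )
}

#' Maternal and fetal detector defaults
#'
#' Maternal: 5-15 Hz band, 0.35 s refractory (caps at ~170 bpm), 0.15 s
#' integration. Fetal: 10-30 Hz band for the narrower fetal QRS, 0.25 s
#' refractory (caps at 240 bpm), 0.08 s integration, tighter refinement and
#' a lower threshold with aggressive search-back — fetal complexes
#' coinciding with a maternal beat are attenuated by the template
#' subtraction, so the fetal stage must pick up weakened peaks.
#'
#' @return A `qrs_detector_config`.
#' @export
maternal_detector_config <- function() {
  qrs_detector_config(band_low_hz = 5, band_high_hz = 15, refractory_s = 0.35,
                      min_rate_bpm = 40, max_rate_bpm = 180)
}

#' @rdname maternal_detector_config
#' @export
fetal_detector_config <- function() {
  qrs_detector_config(band_low_hz = 10, band_high_hz = 30, refractory_s = 0.25,
                      min_rate_bpm = 90, max_rate_bpm = 240,
                      threshold_factor = 0.3, searchback_frac = 0.1,
                      integration_s = 0.08, refine_half_s = 0.012)
}

#' Detect R-peaks in a single-channel signal
#'
#' Energy detector: zero-phase band-pass, derivative, squaring, 150 ms
#' centred moving-window integration, then an adaptive threshold at
#' `threshold_factor` times the median of the strongest integrated peaks
#' (population sized by `min_rate_bpm`). Detections closer than the
#' refractory period are resolved in favour of the larger peak, overlong RR
#' gaps are optionally re-scanned at a relaxed threshold (search-back), and
#' each surviving detection is refined to the local absolute extremum of the
#' band-passed signal within `refine_half_s`.
#'
#' @param record Single-channel [signal_record] of at least 2 s.
#' @param cfg A [qrs_detector_config()].
#' @param label Annotation label for the output.
#' @return An [annotation_set] of detected R-peak sample indices (0-based).
#' @export
detect_qrs <- function(record, cfg = maternal_detector_config(),
                       label = "maternal_det") {
  stopifnot(inherits(record, "signal_record"))
  if (n_channels(record) != 1L) abort("detect_qrs expects a single channel.")
  fs <- record$fs
  if (fs < 2 * cfg$band_high_hz) abort("Sampling rate below 2x the detector band.")
  if (duration_s(record) < 2) {
    abort("Record shorter than 2 s: not enough data for threshold statistics.")
  }
  x <- as.numeric(record$samples[1, ])
  bf <- signal::butter(2, c(cfg$band_low_hz, cfg$band_high_hz) / (fs / 2),
                       type = "pass")
  bp <- as.numeric(signal::filtfilt(bf, x))
  der <- c(diff(bp), 0)
  sq <- der^2
  w <- max(3L, round(cfg$integration_s * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0
  n <- length(integ)
  is_max <- c(FALSE, integ[2:(n - 1)] >= integ[1:(n - 2)] &
                integ[2:(n - 1)] > integ[3:n], FALSE)
  cand <- which(is_max)
  cand <- cand[integ[cand] > 0]
  if (length(cand) == 0) {
    return(annotation_set(numeric(0), fs, label))
  }
  heights <- integ[cand]
  n_level <- max(3L, floor(duration_s(record) * cfg$min_rate_bpm / 60))
  level <- median(sort(heights, decreasing = TRUE)[seq_len(min(n_level, length(heights)))])
  thr <- cfg$threshold_factor * level
  keep <- cand[heights >= thr]
  if (length(keep) == 0) {
    return(annotation_set(numeric(0), fs, label))
  }
  refr <- round(cfg$refractory_s * fs)
  keep <- enforce_refractory(keep, integ[keep], refr)
  if (cfg$searchback && length(keep) >= 3) {
    keep <- search_back(keep, cand, heights, cfg$searchback_frac * thr,
                        cfg$searchback_rr_factor, refr)
  }
  # refine to the local absolute extremum of the band-passed signal
  half <- round(cfg$refine_half_s * fs)
  refined <- vapply(keep, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    lo + which.max(abs(bp[lo:hi])) - 1L
  }, numeric(1))
  refined <- sort(unique(refined))
  refined <- enforce_refractory(refined, abs(bp[refined]), refr)
  annotation_set(sort(refined) - 1, fs, label)  # back to 0-based
}

# Pan-Tompkins-style search-back: re-scan overlong RR gaps with a relaxed
# threshold, accepting the strongest remaining candidate per gap.
search_back <- function(keep, cand, heights, low_thr, rr_factor, refr) {
  for (pass in 1:3) {
    rr <- diff(keep)
    med_rr <- median(rr)
    additions <- numeric(0)  # appended after the scan so gap indices stay valid
    for (g in which(rr > rr_factor * med_rr)) {
      lo <- keep[g] + refr
      hi <- keep[g + 1] - refr
      in_gap <- cand > lo & cand < hi & heights >= low_thr
      if (any(in_gap)) {
        additions <- c(additions, cand[in_gap][which.max(heights[in_gap])])
      }
    }
    if (length(additions) == 0) break
    keep <- sort(c(keep, additions))
  }
  keep
}

# Keep the larger peak whenever two candidates are closer than min_gap.
enforce_refractory <- function(pos, strength, min_gap) {
  ord <- order(strength, decreasing = TRUE)
  kept <- numeric(0)
  for (i in ord) {
    p <- pos[i]
    if (all(abs(kept - p) >= min_gap)) kept <- c(kept, p)
  }
  sort(kept)
}

#' Detect maternal R-peaks
#'
#' [detect_qrs()] with maternal defaults.
#' @param record Single-channel [signal_record].
#' @return An [annotation_set] labelled `maternal_det`.
#' @export
detect_mqrs <- function(record) {
  detect_qrs(record, maternal_detector_config(), "maternal_det")
}

#' Detect fetal R-peaks
#'
#' [detect_qrs()] with fetal defaults.
#' @param record Single-channel [signal_record].
#' @return An [annotation_set] labelled `fetal_det`.
#' @export
detect_fqrs <- function(record) {
  detect_qrs(record, fetal_detector_config(), "fetal_det")
}

#' Principal component decomposition of a multichannel record
#'
#' Channels are mean-centred (no variance scaling: the channels share units
#' and amplitude carries the maternal-dominance information), the channel
#' covariance is eigendecomposed, and the projections are returned in
#' decreasing-variance order. Each component's sign is fixed so that its
#' largest-magnitude sample is positive.
#'
#' @param record A [signal_record] with at least 2 channels and at least as
#'   many samples as channels.
#' @return A `pca_result` with `components` (components x samples),
#'   `explained_variance_ratio`, `loadings` (channels x components) and the
#'   sampling metadata.
#' @export
pca_decompose <- function(record) {
  stopifnot(inherits(record, "signal_record"))
  if (n_channels(record) < 2L) abort("pca_decompose needs at least 2 channels.")
  if (n_samples(record) < n_channels(record)) {
    abort("Need at least as many samples as channels.")
  }
  x <- record$samples
  ctr <- rowMeans(x)
  xc <- x - ctr
  cv <- tcrossprod(xc) / (ncol(xc) - 1)
  if (sum(diag(cv)) <= 0) abort("Degenerate covariance: all channels constant.")
  eig <- eigen(cv, symmetric = TRUE)
  v <- eig$vectors
  comps <- crossprod(v, xc)  # components x samples
  for (i in seq_len(nrow(comps))) {
    j <- which.max(abs(comps[i, ]))
    if (comps[i, j] < 0) {
      comps[i, ] <- -comps[i, ]
      v[, i] <- -v[, i]
    }
  }
  ev <- pmax(eig$values, 0)
  structure(
    list(components = comps,
         explained_variance_ratio = ev / sum(ev),
         loadings = v,
         center = ctr,
         fs = record$fs,
         record_id = record$record_id),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result: %d components; variance ratios %s>\n",
              nrow(x$components),
              paste(sprintf("%.3f", x$explained_variance_ratio), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.pca_result <- function(x, ...) {
  tibble(component = seq_along(x$explained_variance_ratio),
         variance = apply(x$components, 1, var),
         explained_variance_ratio = x$explained_variance_ratio)
}

component_record <- function(pca, i, label) {
  signal_record(matrix(pca$components[i, ], nrow = 1), pca$fs, label,
                pca$record_id)
}

#' Maternal reference: the first principal component
#'
#' In abdominal mixtures the maternal ECG dominates, so the first principal
#' component is used as the maternal reference channel for mQRS detection.
#'
#' @param pca A `pca_result`.
#' @return Single-channel [signal_record].
#' @export
select_mecg_reference <- function(pca) {
  stopifnot(inherits(pca, "pca_result"))
  component_record(pca, 1L, "mecg_ref")
}

#' Fetal enhancement: the most kurtotic component
#'
#' After maternal cancellation the fetal QRS spikes are the sparsest,
#' heaviest-tailed structure left, so the residual component with the highest
#' sample kurtosis (Pearson convention) is selected; ties break to the lower
#' component index.
#'
#' The kurtosis is evaluated after winsorizing each component at the
#' `winsor_quantile` of its absolute values: a single imperfectly cancelled
#' maternal beat can put one enormous spike into a minor component and give
#' it a freak raw kurtosis, whereas the fetal QRS train owes its kurtosis to
#' hundreds of spikes and is barely touched by the clipping.
#'
#' @param pca A `pca_result` of the residual channels.
#' @param winsor_quantile Absolute-value quantile at which components are
#'   clipped before the kurtosis is computed; 1 reproduces the raw sample
#'   kurtosis.
#' @return Single-channel [signal_record].
#' @export
select_fecg_component <- function(pca, winsor_quantile = 0.999) {
  stopifnot(inherits(pca, "pca_result"))
  k <- apply(pca$components, 1, function(x) {
    if (var(x) == 0) return(-Inf)
    lim <- stats::quantile(abs(x), winsor_quantile)
    if (lim > 0) x <- pmin(pmax(x, -lim), lim)
    if (var(x) == 0) return(-Inf)
    moment_kurtosis(x)
  })
  component_record(pca, which.max(k), "fecg_enhanced")
}
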