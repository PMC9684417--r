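#' Beat window layout for sequential analysis
#'
#' Sequential analysis models each maternal cardiac cycle as three
#' independently scaled sections around the detected R-peak: the QRS complex
#' spans 0.05 s either side of the R-peak, the P-wave spans the 0.20 s ending
#' where the QRS window begins, and the T-wave spans the 0.40 s starting where
#' the QRS window ends — 0.70 s in total.
#'
#' @param qrs_half_s Half-width of the QRS window, seconds.
#' @param p_dur_s P-wave window duration, seconds.
#' @param t_dur_s T-wave window duration, seconds.
#' @return A `cycle_window_spec` with the derived `total_s`.
#' @export
cycle_window_spec <- function(qrs_half_s = 0.05, p_dur_s = 0.20, t_dur_s = 0.40) {
  if (qrs_half_s <= 0 || p_dur_s <= 0 || t_dur_s <= 0) {
    abort("All window durations must be positive.")
  }
  structure(
    list(qrs_half_s = qrs_half_s, p_dur_s = p_dur_s, t_dur_s = t_dur_s,
         total_s = p_dur_s + 2 * qrs_half_s + t_dur_s),
    class = "cycle_window_spec"
  )
}

# Section lengths in samples at rate fs; errors if any section is degenerate.
section_lengths <- function(spec, fs) {
  n <- list(
    p = round(spec$p_dur_s * fs),
    qrs = 2 * round(spec$qrs_half_s * fs),
    t = round(spec$t_dur_s * fs)
  )
  if (any(unlist(n) < 2)) {
    abort("Sampling rate too low: every P/QRS/T section needs at least 2 samples.")
  }
  n$half_qrs <- round(spec$qrs_half_s * fs)
  n$total <- n$p + n$qrs + n$t
  n
}

#' Segment a record into per-beat P/QRS/T windows
#'
#' For each R-peak at 0-based sample `r`, the full cycle window is
#' `[r - half - p, r + half + t)` (half-open, samples). A beat is flagged
#' `truncated` when its window would run past either record edge or into the
#' next beat's P window (the T-wave is cut there so no sample is claimed by
#' two templates). Truncated beats are excluded from template averaging but
#' still carry enough bookkeeping to be cancelled over their available span.
#'
#' @param record Single-channel [signal_record].
#' @param r_peaks [annotation_set] of maternal R-peaks.
#' @param spec A [cycle_window_spec()].
#' @return A tibble (class `cycle_segments`) with one row per beat:
#'   `beat_index`, `r_peak`, `win_start`, `win_end` (nominal, 0-based
#'   half-open), `eff_start`, `eff_end` (after clipping), `truncated`, and
#'   list-columns `p`, `qrs`, `t` holding the available section samples.
#' @export
segment_cycles <- function(record, r_peaks, spec = cycle_window_spec()) {
  stopifnot(inherits(record, "signal_record"), inherits(r_peaks, "annotation_set"))
  if (n_channels(record) != 1L) abort("segment_cycles expects a single channel.")
  ns <- section_lengths(spec, record$fs)
  x <- as.numeric(record$samples[1, ])
  nr <- length(x)
  peaks <- r_peaks$indices
  if (length(peaks) == 0) {
    return(empty_segments(record$fs, spec))
  }
  rows <- purrr::map(seq_along(peaks), function(k) {
    r <- peaks[k]
    win_start <- r - ns$half_qrs - ns$p
    win_end <- r + ns$half_qrs + ns$t
    next_p_start <- if (k < length(peaks)) peaks[k + 1] - ns$half_qrs - ns$p else Inf
    eff_start <- max(win_start, 0)
    eff_end <- min(win_end, nr, next_p_start)
    truncated <- (eff_start != win_start) || (eff_end != win_end)
    take <- function(from, to) {
      lo <- max(from, eff_start); hi <- min(to, eff_end)
      if (hi <= lo) numeric(0) else x[(lo + 1):hi]
    }
    tibble(
      beat_index = k, r_peak = r,
      win_start = win_start, win_end = win_end,
      eff_start = eff_start, eff_end = eff_end,
      truncated = truncated,
      p = list(take(win_start, win_start + ns$p)),
      qrs = list(take(r - ns$half_qrs, r + ns$half_qrs)),
      t = list(take(r + ns$half_qrs, win_end))
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "fs") <- record$fs
  attr(out, "spec") <- spec
  class(out) <- c("cycle_segments", class(out))
  out
}

empty_segments <- function(fs, spec) {
  out <- tibble(
    beat_index = integer(), r_peak = numeric(),
    win_start = numeric(), win_end = numeric(),
    eff_start = numeric(), eff_end = numeric(),
    truncated = logical(),
    p = list(), qrs = list(), t = list()
  )
  attr(out, "fs") <- fs
  attr(out, "spec") <- spec
  class(out) <- c("cycle_segments", class(out))
  out
}

#' Average the non-truncated cycles into a section template basis
#'
#' Per-sample arithmetic means of the P, QRS and T sections over all
#' non-truncated beats — the global maternal template that per-beat scaling
#' then adapts to each cycle.
#'
#' @param segments A `cycle_segments` tibble from [segment_cycles()].
#' @return A `template_basis` with `mu_p`, `mu_qrs`, `mu_t`.
#' @export
average_cycles <- function(segments) {
  usable <- segments[!segments$truncated, ]
  if (nrow(usable) == 0) {
    abort("No non-truncated beats available for template averaging.")
  }
  avg <- function(col) {
    m <- do.call(rbind, usable[[col]])
    colMeans(m)
  }
  structure(
    list(mu_p = avg("p"), mu_qrs = avg("qrs"), mu_t = avg("t"),
         n_beats = nrow(usable)),
    class = "template_basis"
  )
}

#' @export
print.template_basis <- function(x, ...) {
  cat(sprintf("<template_basis: P %d + QRS %d + T %d samples, averaged over %d beats>\n",
              length(x$mu_p), length(x$mu_qrs), length(x$mu_t), x$n_beats))
  invisible(x)
}

#' Assemble the block template matrix
#'
#' Stacks the three averaged sections into the (window x 3) block matrix M:
#' column 1 carries the P template over the P rows and zeros elsewhere,
#' columns 2 and 3 likewise for QRS and T. Because the blocks are disjoint,
#' `M'M` is diagonal and the least-squares scaling reduces to per-section
#' projections.
#'
#' @param basis A `template_basis` from [average_cycles()].
#' @return Numeric matrix of shape (window samples x 3).
#' @export
build_template_matrix <- function(basis) {
  stopifnot(inherits(basis, "template_basis"))
  np <- length(basis$mu_p); nq <- length(basis$mu_qrs); nt <- length(basis$mu_t)
  m <- matrix(0, nrow = np + nq + nt, ncol = 3)
  m[seq_len(np), 1] <- basis$mu_p
  m[np + seq_len(nq), 2] <- basis$mu_qrs
  m[np + nq + seq_len(nt), 3] <- basis$mu_t
  norms <- sqrt(colSums(m^2))
  if (any(norms == 0)) {
    abort("Template matrix is rank deficient: a section template has zero norm.")
  }
  colnames(m) <- c("p", "qrs", "t")
  m
}

#' Closed-form least-squares scaling vector
#'
#' Solves `a = (M'M)^{-1} M' m` for one observed cycle `m`. With the
#' disjoint-block layout this equals the per-section projections
#' `<mu_s, m_s> / ||mu_s||^2`.
#'
#' @param matrix_m Template matrix from [build_template_matrix()] (or any of
#'   its row-slices for truncated beats).
#' @param cycle_m Observed cycle samples, same length as `nrow(matrix_m)`.
#' @return Named numeric vector `c(a_p, a_qrs, a_t)`.
#' @export
ls_scaling <- function(matrix_m, cycle_m) {
  if (length(cycle_m) != nrow(matrix_m)) {
    abort("Cycle length must equal the template window length.")
  }
  gram <- crossprod(matrix_m)
  if (any(diag(gram) == 0) || abs(det(gram)) < 1e-300) {
    abort("Template matrix is rank deficient; scaling is undefined.")
  }
  a <- solve(gram, crossprod(matrix_m, cycle_m))
  setNames(as.numeric(a), c("a_p", "a_qrs", "a_t"))
}

#' Fitted template and squared residual for one cycle
#'
#' `template = M a`; `residual_sq = ||m - M a||^2`. When `a` comes from
#' [ls_scaling()] the residual is the global minimum over all scaling
#' vectors.
#'
#' @inheritParams ls_scaling
#' @param a Scaling vector (length 3).
#' @return A `template_fit` list with `template`, `a` and `residual_sq`.
#' @export
fit_template <- function(matrix_m, a, cycle_m) {
  if (length(cycle_m) != nrow(matrix_m)) {
    abort("Cycle length must equal the template window length.")
  }
  template <- as.numeric(matrix_m %*% as.numeric(a))
  structure(
    list(template = template, a = setNames(as.numeric(a), c("a_p", "a_qrs", "a_t")),
         residual_sq = sum((cycle_m - template)^2)),
    class = "template_fit"
  )
}

# The observed samples of one beat's effective window.
cycle_vector <- function(x, eff_start, eff_end) {
  x[(eff_start + 1):eff_end]
}

# Rows of the full template matrix corresponding to a beat's effective window.
beat_matrix_rows <- function(matrix_m, seg_row) {
  offset <- seg_row$eff_start - seg_row$win_start
  len <- seg_row$eff_end - seg_row$eff_start
  matrix_m[(offset + 1):(offset + len), , drop = FALSE]
}

#' Per-beat closed-form scaling fits for a whole record
#'
#' Convenience wrapper around [segment_cycles()], [build_template_matrix()]
#' and [ls_scaling()]: fits every beat's scaling vector by least squares
#' against a section basis (by default the record's own averaged basis) and
#' reports the squared residual of each fit. Truncated beats are fitted over
#' their available window rows.
#'
#' @param record Single-channel [signal_record].
#' @param r_peaks [annotation_set] of R-peaks.
#' @param spec A [cycle_window_spec()].
#' @param basis Optional `template_basis`; defaults to [average_cycles()] of
#'   the record's own non-truncated beats.
#' @return Tibble with `beat_index`, `r_peak`, `truncated`, `a_p`, `a_qrs`,
#'   `a_t`, `residual_sq`.
#' @export
fit_cycles_ls <- function(record, r_peaks, spec = cycle_window_spec(),
                          basis = NULL) {
  segs <- segment_cycles(record, r_peaks, spec)
  if (nrow(segs) == 0) abort("No beats to fit.")
  if (is.null(basis)) basis <- average_cycles(segs)
  m_full <- build_template_matrix(basis)
  x <- as.numeric(record$samples[1, ])
  rows <- purrr::map(seq_len(nrow(segs)), function(k) {
    s <- segs[k, ]
    mk <- beat_matrix_rows(m_full, s)
    ck <- cycle_vector(x, s$eff_start, s$eff_end)
    active <- colSums(mk^2) > 0
    a <- rep(NA_real_, 3)
    a[active] <- as.numeric(solve(crossprod(mk[, active, drop = FALSE]),
                                  crossprod(mk[, active, drop = FALSE], ck)))
    fit <- mk[, active, drop = FALSE] %*% a[active]
    tibble(beat_index = k, r_peak = s$r_peak, truncated = s$truncated,
           a_p = a[1], a_qrs = a[2], a_t = a[3],
           residual_sq = sum((ck - fit)^2))
  })
  dplyr::bind_rows(rows)
}

#' Subtract fitted maternal templates from a signal
#'
#' Cancels the maternal component: each beat's fitted template is subtracted
#' over that beat's effective window (so truncated beats are cancelled over
#' their available span only); samples outside all windows pass through
#' unchanged.
#'
#' @param record Single-channel [signal_record].
#' @param segments `cycle_segments` for the record (same R-peaks the fits were
#'   computed from).
#' @param fits List of `template_fit` objects, one per segment row.
#' @return A [signal_record] with the templates removed.
#' @export
subtract_templates <- function(record, segments, fits) {
  stopifnot(inherits(record, "signal_record"))
  if (n_channels(record) != 1L) abort("subtract_templates expects a single channel.")
  if (length(fits) != nrow(segments)) {
    abort("Need exactly one template fit per segmented beat.")
  }
  x <- as.numeric(record$samples[1, ])
  for (k in seq_len(nrow(segments))) {
    s <- segments[k, ]
    len <- s$eff_end - s$eff_start
    tpl <- fits[[k]]$template
    if (length(tpl) != len) {
      abort(sprintf("Beat %d: template length %d does not match window length %d.",
                    k, length(tpl), len))
    }
    idx <- (s$eff_start + 1):s$eff_end
    x[idx] <- x[idx] - tpl
  }
  signal_record(matrix(x, nrow = 1), record$fs, record$channel_labels,
                record$record_id)
}
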