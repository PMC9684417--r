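#' Multichannel sampled-signal container
#'
#' A `signal_record` holds a multichannel sampled signal as a numeric matrix
#' (rows = channels, columns = time samples) together with its sampling rate
#' and channel labels. All indexing in the package is 0-based on the sample
#' axis and windows are half-open `[start, end)`.
#'
#' @param samples Numeric matrix (channels x samples) or a numeric vector for
#'   a single channel. Values must be finite.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_labels Character vector of channel names; defaults to
#'   `ch1, ch2, ...`.
#' @param record_id Identifier string carried through the pipeline.
#'
#' @return An object of class `signal_record`.
#' @examples
#' rec <- signal_record(matrix(rnorm(1000), nrow = 2), fs = 500)
#' n_channels(rec)
#' @export
signal_record <- function(samples, fs, channel_labels = NULL, record_id = "record") {
  if (is.vector(samples) && is.numeric(samples)) {
    samples <- matrix(samples, nrow = 1)
  }
  if (!is.matrix(samples) || !is.numeric(samples)) {
    abort("`samples` must be a numeric matrix (channels x samples) or vector.")
  }
  if (nrow(samples) < 1L || ncol(samples) < 1L) {
    abort("A signal_record needs at least one channel and one sample.")
  }
  if (!all(is.finite(samples))) {
    abort("signal_record samples must be finite.")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a positive finite scalar (Hz).")
  }
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(samples)))
  }
  if (length(channel_labels) != nrow(samples)) {
    abort("`channel_labels` length must match the number of channels.")
  }
  dimnames(samples) <- NULL
  structure(
    list(
      samples = samples,
      fs = as.numeric(fs),
      channel_labels = as.character(channel_labels),
      record_id = as.character(record_id)
    ),
    class = "signal_record"
  )
}

#' @rdname signal_record
#' @param x,rec A `signal_record`.
#' @export
n_channels <- function(rec) nrow(rec$samples)

#' @rdname signal_record
#' @export
n_samples <- function(rec) ncol(rec$samples)

#' @rdname signal_record
#' @export
duration_s <- function(rec) ncol(rec$samples) / rec$fs

#' Extract one channel as a single-channel record
#'
#' @param rec A `signal_record`.
#' @param channel Channel index (1-based) or label.
#' @return A single-channel `signal_record`.
#' @export
get_channel <- function(rec, channel = 1L) {
  stopifnot(inherits(rec, "signal_record"))
  if (is.character(channel)) {
    channel <- match(channel, rec$channel_labels)
  }
  if (is.na(channel) || channel < 1L || channel > n_channels(rec)) {
    abort("Unknown channel.")
  }
  signal_record(rec$samples[channel, , drop = FALSE], rec$fs,
                rec$channel_labels[channel], rec$record_id)
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf(
    "<signal_record '%s': %d channel(s) x %d samples @ %g Hz (%.1f s)>\n",
    x$record_id, n_channels(x), n_samples(x), x$fs, duration_s(x)
  ))
  invisible(x)
}

#' @export
as_tibble.signal_record <- function(x, ...) {
  out <- as.data.frame(t(x$samples))
  names(out) <- x$channel_labels
  dplyr::bind_cols(
    tibble(time_s = (seq_len(n_samples(x)) - 1) / x$fs),
    as_tibble(out)
  )
}

valid_annotation_labels <- c("maternal_ref", "fetal_ref", "maternal_det", "fetal_det")

#' R-peak annotation container
#'
#' Stores a strictly increasing set of 0-based sample indices marking R-peaks,
#' with the sampling rate they refer to and a source label.
#'
#' @param indices Integer-valued sample positions (0-based). Sorted and
#'   deduplicated on construction.
#' @param fs Sampling rate in Hz.
#' @param label One of `"maternal_ref"`, `"fetal_ref"`, `"maternal_det"`,
#'   `"fetal_det"`.
#' @return An object of class `annotation_set`.
#' @examples
#' ann <- annotation_set(c(400, 100, 100), fs = 500, label = "fetal_ref")
#' ann$indices  # 100 400
#' @export
annotation_set <- function(indices, fs, label = "fetal_ref") {
  if (length(indices) > 0) {
    if (!is.numeric(indices) || any(!is.finite(indices))) {
      abort("Annotation indices must be finite numbers.")
    }
    if (any(indices != round(indices))) {
      abort("Annotation indices must be integers (sample positions).")
    }
    if (any(indices < 0)) {
      abort("Annotation indices must be non-negative (0-based).")
    }
  }
  if (!label %in% valid_annotation_labels) {
    abort(paste0("`label` must be one of: ",
                 paste(valid_annotation_labels, collapse = ", ")))
  }
  if (!is.numeric(fs) || fs <= 0) abort("`fs` must be positive.")
  structure(
    list(
      indices = sort(unique(as.numeric(indices))),
      fs = as.numeric(fs),
      label = label
    ),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set '%s': %d peaks @ %g Hz>\n",
              x$label, length(x$indices), x$fs))
  invisible(x)
}

#' @export
length.annotation_set <- function(x) length(x$indices)

#' @export
as_tibble.annotation_set <- function(x, ...) {
  tibble(
    index = x$indices,
    time_s = x$indices / x$fs,
    label = x$label
  )
}

check_annotations_in_record <- function(ann, rec) {
  if (length(ann$indices) > 0 &&
      (min(ann$indices) < 0 || max(ann$indices) >= n_samples(rec))) {
    abort("Annotation indices fall outside the record.")
  }
  if (!isTRUE(all.equal(ann$fs, rec$fs))) {
    abort("Annotation and record sampling rates differ.")
  }
  invisible(TRUE)
}
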