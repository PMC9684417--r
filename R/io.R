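#' Read a multichannel signal from CSV
#'
#' The on-disk format is UTF-8 text: optional `#`-prefixed metadata lines
#' (`# fs=<Hz>`, `# record_id=<id>`), a header row of channel labels, then one
#' row per sample with one column per channel.
#'
#' @param path Path to the CSV file.
#' @param fs Sampling-rate override in Hz. Required when the file carries no
#'   `# fs=` metadata line; ignored otherwise.
#' @return A [signal_record].
#' @seealso [write_signal_csv()]
#' @export
read_signal_csv <- function(path, fs = NULL) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  lines <- readLines(path, warn = FALSE)
  meta <- parse_meta_lines(lines)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) abort("Signal CSV needs a header row and at least one sample row.")
  labels <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  labels <- trimws(labels)
  rows <- strsplit(body[-1], ",", fixed = TRUE)
  widths <- lengths(rows)
  if (any(widths != length(labels))) {
    bad <- which(widths != length(labels))[1]
    abort(sprintf("Ragged row %d: expected %d columns, found %d.",
                  bad, length(labels), widths[bad]))
  }
  vals <- suppressWarnings(vapply(rows, function(r) as.numeric(r), numeric(length(labels))))
  if (length(labels) == 1L) vals <- matrix(vals, nrow = 1)
  if (anyNA(vals)) {
    bad <- which(apply(if (is.matrix(vals)) vals else rbind(vals), 2, anyNA))[1]
    abort(sprintf("Non-numeric cell in data row %d.", bad))
  }
  file_fs <- meta[["fs"]]
  use_fs <- if (!is.null(file_fs)) as.numeric(file_fs) else fs
  if (is.null(use_fs)) {
    abort("Sampling rate unknown: file has no '# fs=' line and no `fs` override was given.")
  }
  record_id <- meta[["record_id"]] %||% sub("\\.[^.]*$", "", basename(path))
  signal_record(vals, use_fs, labels, record_id)
}

#' Write a multichannel signal to CSV
#'
#' Emits `# fs=` and `# record_id=` metadata lines, a channel-label header and
#' a full-precision decimal body so that [read_signal_csv()] round-trips
#' exactly.
#'
#' @param record A [signal_record].
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(record, path) {
  stopifnot(inherits(record, "signal_record"))
  con <- try_open_write(path)
  on.exit(close(con))
  writeLines(c(
    sprintf("# fs=%s", format(record$fs, digits = 17)),
    sprintf("# record_id=%s", record$record_id),
    paste(record$channel_labels, collapse = ",")
  ), con)
  body <- apply(record$samples, 2, function(col) {
    paste(format(col, digits = 17, scientific = TRUE, trim = TRUE), collapse = ",")
  })
  writeLines(body, con)
  invisible(path)
}

#' Read an R-peak annotation file
#'
#' One 0-based integer sample index per line, with optional `# fs=` and
#' `# label=` metadata lines. Indices are sorted and deduplicated.
#'
#' @param path Path to the annotation text file.
#' @param fs Sampling-rate override (used when the file has no `# fs=` line).
#' @param label Label override (used when the file has no `# label=` line).
#' @return An [annotation_set].
#' @export
read_annotations <- function(path, fs = NULL, label = NULL) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  lines <- readLines(path, warn = FALSE)
  meta <- parse_meta_lines(lines)
  body <- trimws(lines[!grepl("^#", lines)])
  body <- body[nzchar(body)]
  idx <- numeric(0)
  if (length(body) > 0) {
    if (any(!grepl("^[+-]?[0-9]+$", body))) {
      abort("Annotation lines must be integers (one 0-based index per line).")
    }
    idx <- as.numeric(body)
    if (any(idx < 0)) abort("Negative annotation index.")
  }
  use_fs <- if (!is.null(meta[["fs"]])) as.numeric(meta[["fs"]]) else fs
  if (is.null(use_fs)) abort("Sampling rate unknown for annotations.")
  use_label <- meta[["label"]] %||% label %||% "fetal_ref"
  annotation_set(idx, use_fs, use_label)
}

#' Write an R-peak annotation file
#'
#' @param ann An [annotation_set].
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  con <- try_open_write(path)
  on.exit(close(con))
  writeLines(c(
    sprintf("# fs=%s", format(ann$fs, digits = 17)),
    sprintf("# label=%s", ann$label)
  ), con)
  if (length(ann$indices) > 0) {
    writeLines(format(ann$indices, scientific = FALSE, trim = TRUE), con)
  }
  invisible(path)
}

#' Load a record, sniffing WFDB-style versus CSV layout
#'
#' Clinical abdominal-ECG collections are commonly distributed as WFDB record
#' pairs (`<name>.hea` header plus `<name>.dat` 16-bit samples). This loader
#' accepts either a WFDB header path / record stem or a signal CSV and
#' dispatches on what it finds on disk. It is a convenience for real data and
#' is never required by the rest of the package.
#'
#' @param path Record stem, `.hea` path, or `.csv` path.
#' @param fs Sampling-rate override for CSV files without metadata.
#' @return A [signal_record].
#' @export
load_record <- function(path, fs = NULL) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(sub("\\.[^.]*$", "", path), ".hea")
  if (file.exists(hea)) {
    return(read_wfdb_record(hea))
  }
  read_signal_csv(path, fs = fs)
}

#' Read a WFDB format-16 record
#'
#' Minimal reader for the classic WFDB layout: a `.hea` text header
#' (`record nsig fs nsamples`, then one line per signal whose second token is
#' the storage format and third token the gain as `gain(baseline)/units`),
#' and an interleaved little-endian 16-bit `.dat` file. Only single-segment
#' format-16 records with one `.dat` file are supported, which covers the
#' public abdominal-ECG collections this package targets.
#'
#' @param hea_path Path to the `.hea` header.
#' @return A [signal_record] in physical units.
#' @export
read_wfdb_record <- function(hea_path) {
  if (!file.exists(hea_path)) abort(paste0("No such header: ", hea_path))
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  record_id <- first[1]
  nsig <- as.integer(first[2])
  fs <- if (length(first) >= 3) as.numeric(strsplit(first[3], "/")[[1]][1]) else 250
  nsamp <- if (length(first) >= 4) as.integer(first[4]) else NA_integer_
  sig_lines <- lines[2:(1 + nsig)]
  parse_sig <- function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    fmt <- sub("x[0-9]+$", "", tok[2])
    gain_tok <- if (length(tok) >= 3) tok[3] else "200"
    gain <- as.numeric(sub("\\(.*", "", strsplit(gain_tok, "/")[[1]][1]))
    baseline <- 0
    if (grepl("\\(", gain_tok)) {
      baseline <- as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_tok))
    }
    label <- if (length(tok) >= 9) tok[length(tok)] else paste0("sig", tok[1])
    list(dat = tok[1], fmt = fmt, gain = if (is.na(gain) || gain == 0) 200 else gain,
         baseline = baseline, label = label)
  }
  sigs <- lapply(sig_lines, parse_sig)
  fmts <- unique(vapply(sigs, `[[`, "", "fmt"))
  if (!identical(fmts, "16")) abort("Only WFDB format 16 is supported.")
  dat_path <- file.path(dirname(hea_path), sigs[[1]]$dat)
  raw_n <- file.size(dat_path) / 2L
  vals <- readBin(dat_path, what = "integer", n = raw_n, size = 2L,
                  signed = TRUE, endian = "little")
  nsamp <- if (is.na(nsamp)) floor(length(vals) / nsig) else min(nsamp, floor(length(vals) / nsig))
  mat <- matrix(vals[seq_len(nsig * nsamp)], nrow = nsig)
  for (i in seq_len(nsig)) {
    mat[i, ] <- (mat[i, ] - sigs[[i]]$baseline) / sigs[[i]]$gain
  }
  signal_record(mat, fs, vapply(sigs, `[[`, "", "label"), record_id)
}

parse_meta_lines <- function(lines) {
  meta_lines <- lines[grepl("^#", lines)]
  out <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    if (grepl("=", kv, fixed = TRUE)) {
      key <- trimws(sub("=.*", "", kv))
      val <- trimws(sub("^[^=]*=", "", kv))
      out[[key]] <- val
    }
  }
  out
}

try_open_write <- function(path) {
  con <- tryCatch(file(path, open = "w", encoding = "UTF-8"),
                  error = function(e) abort(paste0("Cannot write to ", path, ": ",
                                                   conditionMessage(e))))
  con
}

`%||%` <- function(a, b) if (is.null(a)) b else a
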