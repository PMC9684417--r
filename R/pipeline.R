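#' Extraction pipeline configuration
#'
#' Settings for the end-to-end extraction: preprocessing filters, the
#' sequential-analysis window layout, the per-beat Grey Wolf Optimizer budget
#' and its search box for the scaling vector, and the master seed from which
#' all per-(channel, beat) optimizer streams are derived.
#'
#' The scaling search box defaults to `[-2, 2]` per dimension: it contains
#' the unit vector (no rescaling) and allows sign flips, while per-cycle
#' physiological scaling rarely exceeds a factor 2.
#'
#' @param preprocess A [preprocess_config()].
#' @param window A [cycle_window_spec()].
#' @param n_agents,max_iter GWO budget per beat (published operating point:
#'   10 and 10).
#' @param scaling_bounds Length-2 numeric `c(lower, upper)` applied to all
#'   three scaling dimensions; must contain 1.
#' @param warm_start If `TRUE`, one agent starts at `(1, 1, 1)` instead of a
#'   random position.
#' @param seed Master seed for the stochastic optimizer streams.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(preprocess = preprocess_config(),
                            window = cycle_window_spec(),
                            n_agents = 10L, max_iter = 10L,
                            scaling_bounds = c(-2, 2),
                            warm_start = FALSE, seed = 1L) {
  if (length(scaling_bounds) != 2 || scaling_bounds[1] >= scaling_bounds[2]) {
    abort("scaling_bounds must be c(lower, upper) with lower < upper.")
  }
  if (scaling_bounds[1] > 1 || scaling_bounds[2] < 1) {
    abort("scaling_bounds must contain 1 (the unit scaling).")
  }
  if (max_iter < 1L) abort("max_iter must be >= 1.")
  structure(
    list(preprocess = preprocess, window = window,
         n_agents = as.integer(n_agents), max_iter = as.integer(max_iter),
         scaling_bounds = as.numeric(scaling_bounds),
         warm_start = isTRUE(warm_start), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

derive_seed <- function(seed, channel, beat) {
  as.integer((as.numeric(seed) + 7919 * channel + 104729 * beat) %% 2147483629)
}

#' Optimize one beat's scaling vector with GWO
#'
#' Minimises the mean squared error between the observed cycle and the scaled
#' template, `J = MSE(m - M a)`, over the 3-dimensional scaling box. Sections
#' absent from a truncated window (zero template columns) are held at unit
#' scaling and excluded from the search.
#'
#' @param matrix_m Template matrix rows for this beat's window.
#' @param cycle_m Observed cycle samples.
#' @param cfg A [pipeline_config()].
#' @param seed Seed for this beat's optimizer stream.
#' @return List with `a` (named length-3 scaling vector), `fitness` (achieved
#'   MSE) and `ls_fitness` (the closed-form least-squares MSE, the quadratic
#'   optimum).
#' @export
optimize_beat_scaling <- function(matrix_m, cycle_m, cfg = pipeline_config(),
                                  seed = cfg$seed) {
  active <- colSums(matrix_m^2) > 0
  if (!any(active)) abort("Template matrix has no active sections for this beat.")
  m_act <- matrix_m[, active, drop = FALSE]
  d <- ncol(m_act)
  objective <- function(a) mean((cycle_m - as.numeric(m_act %*% a))^2)
  a_ls_act <- as.numeric(solve(crossprod(m_act), crossprod(m_act, cycle_m)))
  ls_fitness <- objective(a_ls_act)
  gcfg <- gwo_config(
    lower = rep(cfg$scaling_bounds[1], d),
    upper = rep(cfg$scaling_bounds[2], d),
    n_agents = cfg$n_agents, max_iter = cfg$max_iter, seed = seed,
    warm_start_position = if (cfg$warm_start) rep(1, d) else NULL
  )
  res <- gwo_optimize(objective, gcfg)
  a <- rep(1, 3)
  a[active] <- res$best_position
  list(a = setNames(a, c("a_p", "a_qrs", "a_t")),
       fitness = res$best_fitness, ls_fitness = ls_fitness)
}

#' Extract the fetal ECG from a multichannel abdominal record
#'
#' The full extraction chain: (1) preprocess every channel (baseline and
#' powerline removal); (2) PCA across channels, taking the first principal
#' component as the maternal reference; (3) detect maternal R-peaks on it;
#' (4) on each abdominal channel independently, segment the maternal cycles
#' at those R-peaks, average the non-truncated cycles into a section
#' template, optimise each beat's scaling vector with GWO and subtract the
#' fitted templates; (5) PCA across the residual channels and select the most
#' kurtotic component as the enhanced fetal signal; (6) detect fetal R-peaks
#' on it. Single-channel records skip both PCA stages.
#'
#' Deterministic given `cfg$seed`: each (channel, beat) optimizer stream is
#' derived from the master seed.
#'
#' @param record A [signal_record] of at least 10 s.
#' @param cfg A [pipeline_config()].
#' @return An `extraction_result` with `fecg_signal`, `fqrs`, `mqrs`,
#'   `per_beat` (tibble of per-beat scaling vectors and GWO vs least-squares
#'   fitness), and `residual_record`.
#' @export
extract_fecg <- function(record, cfg = pipeline_config()) {
  stopifnot(inherits(record, "signal_record"))
  if (duration_s(record) < 10) abort("Record shorter than 10 s.")
  clean <- preprocess(record, cfg$preprocess)
  multi <- n_channels(clean) >= 2L
  m_ref <- if (multi) select_mecg_reference(pca_decompose(clean)) else get_channel(clean, 1L)
  mqrs <- detect_mqrs(m_ref)
  if (length(mqrs$indices) == 0) abort("No maternal beats detected.")

  residual <- clean$samples
  per_beat <- vector("list", n_channels(clean))
  for (ch in seq_len(n_channels(clean))) {
    chan <- get_channel(clean, ch)
    segs <- segment_cycles(chan, mqrs, cfg$window)
    basis <- average_cycles(segs)
    m_full <- build_template_matrix(basis)
    x <- as.numeric(chan$samples[1, ])
    fits <- vector("list", nrow(segs))
    rows <- vector("list", nrow(segs))
    for (k in seq_len(nrow(segs))) {
      s <- segs[k, ]
      mk <- beat_matrix_rows(m_full, s)
      ck <- cycle_vector(x, s$eff_start, s$eff_end)
      opt <- optimize_beat_scaling(mk, ck, cfg, seed = derive_seed(cfg$seed, ch, k))
      fits[[k]] <- fit_template(mk, opt$a, ck)
      rows[[k]] <- tibble(
        channel = ch, beat_index = k, r_peak = s$r_peak,
        a_p = opt$a[["a_p"]], a_qrs = opt$a[["a_qrs"]], a_t = opt$a[["a_t"]],
        gwo_fitness = opt$fitness, ls_fitness = opt$ls_fitness,
        truncated = s$truncated
      )
    }
    res_ch <- subtract_templates(chan, segs, fits)
    residual[ch, ] <- res_ch$samples[1, ]
    per_beat[[ch]] <- dplyr::bind_rows(rows)
  }
  per_beat <- dplyr::bind_rows(per_beat)
  stopifnot(all(per_beat$gwo_fitness >= per_beat$ls_fitness - 1e-12))

  residual_record <- signal_record(residual, clean$fs, clean$channel_labels,
                                   paste0(record$record_id, "_residual"))
  fecg <- if (multi) {
    select_fecg_component(pca_decompose(residual_record))
  } else {
    get_channel(residual_record, 1L)
  }
  fqrs <- detect_fqrs(fecg)
  structure(
    list(fecg_signal = fecg, fqrs = fqrs, mqrs = mqrs,
         per_beat = per_beat, residual_record = residual_record,
         config = cfg),
    class = "extraction_result"
  )
}

#' @export
print.extraction_result <- function(x, ...) {
  cat(sprintf(
    "<extraction_result: %d maternal beats cancelled on %d channel(s); %d fetal peaks detected>\n",
    length(x$mqrs$indices), n_channels(x$residual_record), length(x$fqrs$indices)
  ))
  invisible(x)
}

#' @export
tidy.extraction_result <- function(x, ...) {
  x$per_beat
}

#' @export
glance.extraction_result <- function(x, ...) {
  gap <- (x$per_beat$gwo_fitness - x$per_beat$ls_fitness) /
    pmax(x$per_beat$ls_fitness, 1e-12)
  tibble(
    n_maternal_beats = length(x$mqrs$indices),
    n_fetal_peaks = length(x$fqrs$indices),
    n_channels = n_channels(x$residual_record),
    median_fitness_gap = median(gap),
    n_agents = x$config$n_agents,
    max_iter = x$config$max_iter
  )
}

#' @export
autoplot.extraction_result <- function(object, ...) {
  df <- as_tibble(object$fecg_signal)
  names(df)[2] <- "amplitude"
  peaks <- tibble(
    time_s = object$fqrs$indices / object$fqrs$fs,
    amplitude = object$fecg_signal$samples[1, object$fqrs$indices + 1]
  )
  ggplot(df, aes(x = .data$time_s, y = .data$amplitude)) +
    geom_line(colour = "grey40") +
    geom_point(data = peaks, colour = "red", size = 1) +
    labs(x = "Time (s)", y = "Amplitude (a.u.)",
         title = "Extracted fetal ECG with detected R-peaks") +
    theme_minimal()
}
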