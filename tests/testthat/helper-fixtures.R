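# Shared fixtures: everything is generated in code at test time.

# Single sinusoid record.
sine_record <- function(freq_hz, fs = 500, dur_s = 10, amp = 1) {
  t <- (seq_len(round(dur_s * fs)) - 1) / fs
  signal_record(amp * sin(2 * pi * freq_hz * t), fs)
}

# Tiny block template matrix from the worked example:
# mu_p = (1, 2), mu_qrs = (3), mu_t = (1).
toy_basis <- function() {
  structure(list(mu_p = c(1, 2), mu_qrs = 3, mu_t = 1, n_beats = 1L),
            class = "template_basis")
}

# Brute-force maximum one-to-one matching count within tolerance (oracle for
# the greedy matcher on small instances).
brute_force_tp <- function(det, ref, tol) {
  if (length(ref) == 0 || length(det) == 0) return(0L)
  best <- 0L
  recurse <- function(ri, used) {
    if (ri > length(ref)) {
      best <<- max(best, sum(used))
      return(invisible())
    }
    # upper-bound prune
    if (sum(used) + (length(ref) - ri + 1) <= best) return(invisible())
    ok <- which(!used & abs(det - ref[ri]) <= tol)
    for (d in ok) {
      used[d] <- TRUE
      recurse(ri + 1, used)
      used[d] <- FALSE
    }
    recurse(ri + 1, used)  # leave this reference unmatched
  }
  recurse(1L, rep(FALSE, length(det)))
  best
}

# Random realistic matching instance: reference peaks spaced well beyond
# twice the tolerance (as R-peaks are), detections = jittered refs plus
# extras, with some refs dropped.
random_matching_instance <- function(fs = 500, tol_s = 0.05) {
  n_ref <- sample(1:8, 1)
  ref <- cumsum(sample(round(0.3 * fs):round(0.8 * fs), n_ref, replace = TRUE))
  keep <- runif(n_ref) > 0.2
  det <- ref[keep] + sample(-round(0.08 * fs):round(0.08 * fs), sum(keep),
                            replace = TRUE)
  n_extra <- sample(0:3, 1)
  if (n_extra > 0) {
    det <- c(det, sample(1:max(ref + fs), n_extra))
  }
  det <- sort(unique(det[det >= 0]))
  list(det = det, ref = ref)
}
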