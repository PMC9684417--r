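# Population (biased) standardized moments, Pearson convention:
# a standard Gaussian has skewness 0 and kurtosis 3.

moment_skewness <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  mean((x - m)^3) / s2^1.5
}

moment_kurtosis <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  mean((x - m)^4) / s2^2
}
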