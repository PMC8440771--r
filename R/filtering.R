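# Zero-phase IIR filtering. Same algorithm as the classic
# forward-backward filter (forward pass with zero padding, reversed
# second pass, truncation), implemented on stats::filter's C loops: the
# coefficients come from signal::butter, only the application is ours.

apply_iir <- function(b, a, x) {
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[nb:(nb - 1 + length(x))]
  if (length(a) > 1L)
    v <- as.numeric(stats::filter(v, -a[-1L] / a[1L],
                                  method = "recursive")) / a[1L]
  v
}

filtfilt_fast <- function(filt, x) {
  b <- filt$b
  a <- filt$a
  pad <- numeric(2L * max(length(a), length(b)))
  y <- apply_iir(b, a, c(x, pad))
  rev(apply_iir(b, a, rev(y)))[seq_along(x)]
}
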