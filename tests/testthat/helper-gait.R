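# shared fixtures and independent oracles for the test suite

# brute-force total overlap between two interval sets, optionally clipped
# to a window; deliberately naive (pairwise loop) so it can serve as an
# oracle for the package's interval accounting
oracle_overlap <- function(a, b, window = NULL) {
  total <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    lo <- max(a$start[i], b$start[j])
    hi <- min(a$end[i], b$end[j])
    if (!is.null(window)) { lo <- max(lo, window[1]); hi <- min(hi, window[2]) }
    if (hi > lo) total <- total + (hi - lo)
  }
  total
}

# forward-model the expected steady amplitude of a channel: divider voltage
# at the configured peak load minus the idle (zero-load) voltage
oracle_amplitude <- function(profile, channel, em = electrical_model()) {
  load_voltage(profile$peaks[[channel]], em) - load_voltage(0, em)
}

# per-step statistics computed the long way, element by element
oracle_series <- function(x, alpha = 0.95) {
  n <- length(x)
  m <- 0; for (v in x) m <- m + v; m <- m / n
  ss <- 0; for (v in x) ss <- ss + (v - m)^2
  sigma <- sqrt(ss / (n - 1))
  s_md <- sigma / sqrt(n)
  sc <- qt(1 - (1 - alpha) / 2, df = n - 1)
  list(mean = m, sigma = sigma, s_md = s_md, error = sc * s_md)
}

# a minimal synthetic pulse table (already-detected events) for the
# extraction arithmetic tests
make_pulses <- function(channel, onsets, widths, amps, rise = 0.1) {
  data.frame(channel = channel,
             onset_time = onsets,
             full_load_time = onsets + rise,
             offset_time = onsets + widths,
             peak_amplitude = amps,
             foot = ifelse(startsWith(channel, "L"), "left", "right"))
}
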