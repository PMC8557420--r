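# shared fixtures built in code

# closed-form Lomax CDF matching segment_pdf_extended
lomax_cdf <- function(l, t_m, k) 1 - exp(-(k + 1) * log1p(l * t_m / k))

# sup-norm distance between the empirical CDF of x and a reference CDF
ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  u <- cdf(x)
  max(pmax(abs(seq_len(n) / n - u), abs(u - (seq_len(n) - 1) / n)))
}

# a small fixed segment dataset (extended pulse, present-day sampling)
fixture_segments <- function(n = 2000, t_m = 1500, t_d = 1000, seed = 42) {
  simulate_segments(n, pulse_params(t_m = t_m, t_d = t_d), seed = seed)
}

# two-point HapMap-style map file: 0-1 Mb at a constant rate
write_toy_map <- function(rate = 1, path = tempfile(fileext = ".txt")) {
  writeLines(c(
    "Chromosome\tPosition(bp)\tRate(cM/Mb)\tMap(cM)",
    sprintf("chr1\t0\t%g\t0", rate),
    sprintf("chr1\t1000000\t%g\t%g", rate, rate)), path)
  path
}
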