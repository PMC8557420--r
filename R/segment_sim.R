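#' A set of admixture segments
#'
#' Container for simulated or observed introgressed-segment lengths, with
#' optional entry times and the sampling offset used to generate them.
#'
#' @param lengths Segment lengths, Morgan, all `> 0`.
#' @param times Optional entry times, generations before present; must all
#'   exceed `sampling_time`.
#' @param sampling_time Generations before present at which the admixed
#'   population was sampled (0 = present day).
#' @param G Optional genome size, Morgan.
#' @return An object of class `"segment_set"`.
#' @export
segment_set <- function(lengths, times = NULL, sampling_time = 0, G = NULL) {
  lengths <- as.numeric(lengths)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("all segment lengths must be positive and finite")
  if (!is.null(times)) {
    times <- as.numeric(times)
    if (length(times) != length(lengths))
      stop("`times` must match `lengths` in length")
    if (any(times <= sampling_time))
      stop("all entry times must exceed `sampling_time`")
  }
  structure(
    list(lengths = lengths, times = times, sampling_time = sampling_time,
         G = G, K = length(lengths)),
    class = "segment_set"
  )
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("Segment set: %d segments, mean length %.4g cM\n",
              x$K, 100 * mean(x$lengths)))
  if (x$sampling_time != 0)
    cat(sprintf("  sampled %.6g generations before present\n", x$sampling_time))
  invisible(x)
}

#' Draw segment entry times
#'
#' Entry times under the extended pulse are Gamma with shape `k + 1` and
#' rate `k / t_m` (mean `(k + 1) / k * t_m`).
#'
#' @param n Number of segments, `>= 0`.
#' @param params A [pulse_params()] object.
#' @param seed Optional integer seed (sets the global RNG state).
#' @return Numeric vector of `n` entry times, generations before present.
#' @export
draw_segment_times <- function(n, params, seed = NULL) {
  stopifnot(inherits(params, "pulse_params"), n >= 0)
  if (!is.null(seed)) set.seed(seed)
  stats::rgamma(n, shape = params$k + 1, rate = params$k / params$t_m)
}

#' Draw segment lengths given entry times
#'
#' Each segment entering `T_i` generations before present and observed at
#' `sampling_time` generations before present has had `T_i - sampling_time`
#' generations of recombination, so its length is exponential with rate
#' `T_i - sampling_time`. Sampling "50 generations after gene flow ended"
#' corresponds to `sampling_time = t_m - t_d / 2 - 50`.
#'
#' @param times Entry times, generations before present.
#' @param sampling_time Sampling offset, generations before present; every
#'   entry time must exceed it.
#' @param seed Optional integer seed.
#' @return A [segment_set()].
#' @export
draw_segment_lengths <- function(times, sampling_time = 0, seed = NULL) {
  if (any(times <= sampling_time))
    stop("entry time <= sampling_time: segment would enter after sampling")
  if (!is.null(seed)) set.seed(seed)
  lengths <- stats::rexp(length(times), rate = times - sampling_time)
  segment_set(lengths, times = times, sampling_time = sampling_time)
}

#' Simulate admixture segments under the extended pulse
#'
#' Convenience wrapper: draws entry times with [draw_segment_times()] and
#' lengths with [draw_segment_lengths()]. When `sampling_time > 0` the Gamma
#' entry-time distribution can place mass at or before the sampling time;
#' such draws are resampled (i.e. times are drawn conditional on
#' `T > sampling_time`).
#'
#' @inheritParams draw_segment_times
#' @inheritParams draw_segment_lengths
#' @return A [segment_set()].
#' @examples
#' p <- pulse_params(t_m = 1500, t_d = 1000)
#' s <- simulate_segments(1000, p, seed = 1)
#' mean(s$lengths)  # about 1 / 1500
#' @export
simulate_segments <- function(n, params, sampling_time = 0, seed = NULL) {
  stopifnot(inherits(params, "pulse_params"))
  if (!is.null(seed)) set.seed(seed)
  times <- stats::rgamma(n, shape = params$k + 1, rate = params$k / params$t_m)
  if (sampling_time > 0) {
    bad <- which(times <= sampling_time)
    while (length(bad) > 0) {
      times[bad] <- stats::rgamma(length(bad), shape = params$k + 1,
                                  rate = params$k / params$t_m)
      bad <- bad[times[bad] <= sampling_time]
    }
  }
  draw_segment_lengths(times, sampling_time = sampling_time)
}

#' Simulate a noisy ALD decay curve
#'
#' Generates a weighted-LD curve from the extended-pulse expectation
#' [ald_extended()] with i.i.d. Gaussian noise, as a synthetic stand-in for
#' weighted-LD output computed from genotype panels.
#'
#' @param grid Strictly increasing genetic distances, Morgan.
#' @param t_m,k,A,c Curve parameters; see [ald_extended()].
#' @param noise_sd Standard deviation of the additive noise (0 = exact).
#' @param seed Optional integer seed.
#' @param d0 Minimum-distance cutoff recorded on the curve, Morgan
#'   (defaults to the smallest grid point).
#' @return An [ald_curve()] object.
#' @export
simulate_ald_curve <- function(grid, t_m, k, A = 1, c = 0, noise_sd = 0,
                               seed = NULL, d0 = min(grid)) {
  stopifnot(all(diff(grid) > 0), noise_sd >= 0)
  if (any(grid < d0)) stop("all grid distances must be >= d0")
  if (!is.null(seed)) set.seed(seed)
  ld <- ald_extended(grid, t_m = t_m, k = k, A = A, c = c)
  if (noise_sd > 0) ld <- ld + stats::rnorm(length(grid), sd = noise_sd)
  ald_curve(distance = grid, ld = ld, d0 = d0)
}

#' Discretized migration schedule
#'
#' Discretizes the Gamma migration density onto integer generations within a
#' truncation window, rescaling the rates to sum exactly to `alpha`. The
#' default window is `[t_m - t_d/2, t_m + t_d/2]` (two Gamma standard
#' deviations either side of the mean), clipped to positive generations.
#' `t_d = 1` places all mass in a single generation, recovering the simple
#' pulse up to discretization. The schedule can be consumed as
#' per-generation pulse events by standard coalescent simulators.
#'
#' @param params A [pulse_params()] object.
#' @param window Optional `c(g_min, g_max)` truncation window, generations;
#'   must contain the default window. A user-supplied window excluding more
#'   than 1% of the migration density triggers a warning.
#' @return An object of class `"migration_schedule"`: a data frame with
#'   columns `generation` and `migrant_fraction`, plus attributes `window`
#'   and `alpha`.
#' @examples
#' sch <- make_migration_schedule(pulse_params(1500, t_d = 1))
#' sum(sch$migrant_fraction)  # exactly alpha
#' @export
make_migration_schedule <- function(params, window = NULL) {
  stopifnot(inherits(params, "pulse_params"))
  t_m <- params$t_m; k <- params$k; t_d <- params$t_d; alpha <- params$alpha
  default_window <- c(max(t_m - t_d / 2, 1), t_m + t_d / 2)
  if (is.null(window)) {
    window <- default_window
  } else {
    stopifnot(length(window) == 2L, window[1] < window[2])
    window[1] <- max(window[1], 1)
    if (window[1] > default_window[1] + 0.5 || window[2] < default_window[2] - 0.5)
      stop("`window` must contain [t_m - t_d/2, t_m + t_d/2]")
    excluded <- 1 - diff(stats::pgamma(window, shape = k, rate = k / t_m))
    if (excluded > 0.01)
      warning(sprintf("window excludes %.2f%% of the migration density",
                      100 * excluded))
  }
  gens <- seq.int(max(1, ceiling(window[1])), floor(window[2]))
  lp <- stats::dgamma(gens, shape = k, rate = k / t_m, log = TRUE)
  w <- exp(lp - max(lp))
  rates <- alpha * w / sum(w)
  if (any(rates > 1)) stop("discretized migrant fraction exceeds 1")
  structure(
    data.frame(generation = gens, migrant_fraction = rates),
    window = window, alpha = alpha,
    class = c("migration_schedule", "data.frame")
  )
}

## ---- text I/O for simulated objects ---------------------------------------

#' Read and write segment tables
#'
#' Segments are stored as tab-separated text with a `length_cM` column and
#' optional `chrom`, `start`, `end` (physical bp, 0-based half-open) and
#' `entry_time_gen` columns. Lengths are converted between cM (file) and
#' Morgan (in memory) at this boundary.
#'
#' @param set A [segment_set()].
#' @param path File path.
#' @return `read_segments()` returns a [segment_set()];
#'   `write_segments()` returns `path` invisibly.
#' @export
write_segments <- function(set, path) {
  stopifnot(inherits(set, "segment_set"))
  df <- data.frame(length_cM = 100 * set$lengths)
  if (!is.null(set$times)) df$entry_time_gen <- set$times
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments
#' @param sampling_time Sampling offset recorded on the returned set.
#' @export
read_segments <- function(path, sampling_time = 0) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!"length_cM" %in% names(df))
    stop("segment table must contain a `length_cM` column: ", path)
  segment_set(df$length_cM / 100,
              times = if ("entry_time_gen" %in% names(df)) df$entry_time_gen,
              sampling_time = sampling_time)
}

#' @rdname make_migration_schedule
#' @param schedule A `"migration_schedule"`.
#' @param path File path for the two-column TSV (`generation`,
#'   `migrant_fraction`).
#' @export
write_migration_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "migration_schedule"))
  utils::write.table(as.data.frame(schedule), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
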