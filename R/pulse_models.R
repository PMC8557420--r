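#' Parameters of an admixture pulse
#'
#' Bundles the parameters of the extended admixture pulse model: the mean
#' admixture time `t_m` (generations before sampling), the Gamma shape `k`
#' of the migration-rate density, the total introgressed fraction `alpha`,
#' and the derived admixture duration `t_d = 4 * t_m / sqrt(k)`.
#'
#' The migration rate over time is `alpha` times a Gamma density with shape
#' `k` and **rate** `k / t_m`, so its mean is `t_m`. Segment entry times are
#' then Gamma with shape `k + 1` and the same rate. `k -> Inf` (`t_d -> 0`)
#' recovers the simple single-generation pulse; `k = 1` is the
#' constant-migration model with rate `m = 1 / t_m`.
#'
#' Exactly one of `k` or `t_d` must be given; the other is derived.
#'
#' @param t_m Mean admixture time in generations, `> 0`.
#' @param k Gamma shape of the migration density, `>= 1`.
#' @param t_d Admixture duration in generations, `<= 4 * t_m`.
#' @param alpha Total introgressed fraction, in `(0, 1)`.
#' @return An object of class `"pulse_params"`: a list with elements
#'   `t_m`, `k`, `t_d`, `alpha`.
#' @examples
#' pulse_params(t_m = 1500, t_d = 1000)  # k = 36
#' pulse_params(t_m = 1500, k = 16)      # t_d = 1500
#' @export
pulse_params <- function(t_m, k = NULL, t_d = NULL, alpha = 0.03) {
  stopifnot(is.numeric(t_m), length(t_m) == 1L, is.finite(t_m))
  if (t_m <= 0) stop("`t_m` must be positive")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)")
  if (is.null(k) && is.null(t_d))
    stop("one of `k` or `t_d` must be given")
  if (!is.null(k) && !is.null(t_d)) {
    if (abs(k - shape_from_duration(t_m, t_d)) > 1e-6 * k)
      stop("`k` and `t_d` are inconsistent; give only one")
  }
  if (is.null(k)) k <- shape_from_duration(t_m, t_d)
  if (k < 1) stop("`k` must be >= 1 (equivalently t_d <= 4 * t_m)")
  structure(
    list(t_m = t_m, k = k, t_d = duration_from_shape(t_m, k), alpha = alpha),
    class = "pulse_params"
  )
}

#' @export
print.pulse_params <- function(x, ...) {
  cat("Extended admixture pulse parameters\n")
  cat(sprintf("  mean time  t_m   = %.6g generations\n", x$t_m))
  cat(sprintf("  shape      k     = %.6g\n", x$k))
  cat(sprintf("  duration   t_d   = %.6g generations\n", x$t_d))
  cat(sprintf("  fraction   alpha = %.6g\n", x$alpha))
  invisible(x)
}

#' Convert between pulse shape and duration
#'
#' The admixture duration is defined as `t_d = 4 * t_m / sqrt(k)`, i.e. four
#' standard deviations of the Gamma migration density; `k = 16 * t_m^2 /
#' t_d^2` inverts it. The two conversions are exact inverses.
#'
#' @param t_m Mean admixture time, generations, `> 0`.
#' @param k Gamma shape, `>= 1`.
#' @param t_d Duration, generations, `0 < t_d <= 4 * t_m`.
#' @return `duration_from_shape()` returns `t_d`; `shape_from_duration()`
#'   returns `k`.
#' @examples
#' duration_from_shape(1500, k = 16)   # 1500
#' shape_from_duration(1500, t_d = 1000)  # 36
#' @export
duration_from_shape <- function(t_m, k) {
  stopifnot(t_m > 0, k > 0)
  4 * t_m / sqrt(k)
}

#' @rdname duration_from_shape
#' @export
shape_from_duration <- function(t_m, t_d) {
  stopifnot(t_m > 0, t_d > 0)
  if (any(t_d > 4 * t_m))
    stop("`t_d` > 4 * t_m implies shape k < 1, outside the model")
  16 * t_m^2 / t_d^2
}

## ---- closed-form densities -------------------------------------------------

check_lt <- function(l, t_m) {
  if (any(l < 0)) stop("segment length `l` must be non-negative")
  if (t_m <= 0) stop("`t_m` must be positive")
}

#' Segment-length density under the simple pulse
#'
#' Under a single-generation pulse `t_m` generations ago, admixture-segment
#' lengths are exponential with rate `t_m`: `f(l) = t_m * exp(-t_m * l)`.
#' Lengths are in Morgan.
#'
#' @param l Segment length(s), Morgan, `>= 0`.
#' @param t_m Admixture time, generations, `> 0`.
#' @param log Return the log density?
#' @return Density per Morgan (or its log).
#' @examples
#' segment_pdf_simple(0, 1500)          # 1500
#' segment_pdf_simple(1 / 1500, 1500)   # 1500 * exp(-1)
#' @export
segment_pdf_simple <- function(l, t_m, log = FALSE) {
  check_lt(l, t_m)
  stats::dexp(l, rate = t_m, log = log)
}

#' Segment-length density under the extended pulse
#'
#' When the migration rate is Gamma(shape `k`, rate `k / t_m`), segment
#' lengths follow a Lomax (Pareto type II) distribution with shape `k + 1`
#' and scale `k / t_m`:
#' `f(l) = (k + 1) (k / t_m)^(k + 1) (k / t_m + l)^(-(k + 2))`.
#' As `k -> Inf` this converges to [segment_pdf_simple()]; `k = 1` with
#' `t_m = 1 / m` gives the constant-migration form `2 m^2 / (m + l)^3`.
#'
#' Evaluated on the log scale for numerical stability at large `k`.
#'
#' @inheritParams segment_pdf_simple
#' @param k Gamma shape of the migration density, `>= 1`.
#' @return Density per Morgan (or its log).
#' @examples
#' segment_pdf_extended(0, t_m = 1500, k = 4)   # (k + 1) * t_m / k = 1875
#' @export
segment_pdf_extended <- function(l, t_m, k, log = FALSE) {
  check_lt(l, t_m)
  if (k < 1) stop("`k` must be >= 1")
  lp <- log(k + 1) - log(k / t_m + l) - (k + 1) * log1p(l * t_m / k)
  if (log) lp else exp(lp)
}

#' Moments of the segment-length distribution
#'
#' Mean and variance of the extended-pulse (Lomax) segment-length
#' distribution. The mean is `1 / t_m` for every shape `k` — identical to
#' the simple pulse — while the variance, `(k + 1) / ((k - 1) * t_m^2)`, is
#' inflated for finite `k` and decreases to the simple-pulse value
#' `1 / t_m^2` as `k -> Inf`. At `k = 1` the variance is infinite and an
#' error is signalled.
#'
#' @param t_m Admixture time, generations, `> 0`.
#' @param k Gamma shape, `>= 1`.
#' @return A list with elements `mean` (Morgan) and `variance` (Morgan^2).
#' @examples
#' segment_moments(1500, k = 2)  # mean 1/1500, variance 3/1500^2
#' @export
segment_moments <- function(t_m, k) {
  stopifnot(t_m > 0, k >= 1)
  if (k == 1)
    stop("variance of the segment-length distribution is infinite at k = 1")
  list(mean = 1 / t_m, variance = (k + 1) / ((k - 1) * t_m^2))
}

#' Density of segment entry times
#'
#' Segment entry times (generations before sampling) under the extended
#' pulse are Gamma with shape `k + 1` and rate `k / t_m`: older migrants
#' contribute proportionally more segments, which tilts the Gamma(`k`)
#' migration density by a factor `t`. Mean `(k + 1) / k * t_m`, variance
#' `(k + 1) * t_m^2 / k^2`.
#'
#' @param t Time(s) before sampling, generations, `>= 0`.
#' @inheritParams segment_moments
#' @param log Return the log density?
#' @return Density per generation.
#' @export
segment_time_pdf <- function(t, t_m, k, log = FALSE) {
  if (any(t < 0)) stop("`t` must be non-negative")
  stopifnot(t_m > 0, k >= 1)
  stats::dgamma(t, shape = k + 1, rate = k / t_m, log = log)
}

#' Migration rate over time
#'
#' The per-generation migrant fraction of the extended pulse:
#' `m(t) = alpha * dgamma(t, shape = k, rate = k / t_m)`. It integrates to
#' the total introgressed fraction `alpha` and has mean `t_m`. With `k = 1`
#' and `t_m = 1 / m` it reduces to constant migration,
#' `alpha * m * exp(-m t)`.
#'
#' @param t Time(s) before sampling, generations, `>= 0`.
#' @inheritParams segment_moments
#' @param alpha Total introgressed fraction.
#' @return Migrant fraction per generation.
#' @export
migration_density <- function(t, t_m, k, alpha = 0.03) {
  if (any(t < 0)) stop("`t` must be non-negative")
  stopifnot(t_m > 0, k >= 1, alpha > 0)
  alpha * stats::dgamma(t, shape = k, rate = k / t_m)
}

## ---- ALD decay curves ------------------------------------------------------

#' ALD decay under the simple pulse
#'
#' Expected weighted LD at genetic distance `l` after a single-generation
#' pulse: `A * exp(-t_m * l) + c`, where `A` is the amplitude at distance 0
#' and `c` a constant background-LD term.
#'
#' @param l Genetic distance(s), Morgan, `>= 0`.
#' @param t_m Admixture time, generations, `> 0`.
#' @param A Amplitude (intercept), `>= 0`.
#' @param c Constant background LD.
#' @return Weighted LD values.
#' @export
ald_simple <- function(l, t_m, A = 1, c = 0) {
  check_lt(l, t_m)
  if (A < 0) stop("`A` must be non-negative")
  A * exp(-t_m * l) + c
}

#' ALD decay under the extended pulse
#'
#' Expected weighted LD at genetic distance `l`:
#' `A * (1 + t_m * l / k)^(-k) + c`. This is the (scaled) moment-generating
#' function of the Gamma migration density evaluated at `-l`. `k -> Inf`
#' recovers [ald_simple()]; `k = 1`, `t_m = 1 / m` gives `A * m / (m + l) + c`.
#'
#' @inheritParams ald_simple
#' @param k Gamma shape of the migration density, `>= 1`.
#' @return Weighted LD values.
#' @export
ald_extended <- function(l, t_m, k, A = 1, c = 0) {
  check_lt(l, t_m)
  if (k < 1) stop("`k` must be >= 1")
  if (A < 0) stop("`A` must be non-negative")
  A * exp(-k * log1p(t_m * l / k)) + c
}

## ---- segment <-> ALD duality ----------------------------------------------

#' ALD curve from a segment-length density
#'
#' The ALD decay is, up to the constant `E(K) / G` (expected segment count
#' over genome size), the integrated tail of the segment-length density:
#' `D(l) = E(K) / G * integral_l^Inf P(x) (x - l) dx`. Evaluated by adaptive
#' quadrature. For the extended-pulse Lomax density the result is
#' proportional to `(1 + t_m * l / k)^(-k)`; at `l = 0` it equals
#' `E(K) / G` times the mean segment length.
#'
#' @param pdf A vectorized, non-negative density function of length (Morgan).
#' @param l Genetic distance(s), Morgan, `>= 0`.
#' @param EK Expected number of segments.
#' @param G Genome size, Morgan.
#' @param rel.tol Relative tolerance passed to [stats::integrate()].
#' @return Unnormalized weighted LD at each `l`.
#' @seealso [segment_density_from_ald()] for the inverse transform.
#' @export
ald_from_segment_density <- function(pdf, l, EK = 1, G = 1, rel.tol = 1e-10) {
  stopifnot(is.function(pdf), all(l >= 0), EK > 0, G > 0)
  probe <- pdf(c(l, l + 1e-4))
  if (any(!is.finite(probe)) || any(probe < -1e-12))
    stop("`pdf` must be finite and non-negative")
  vapply(l, function(li) {
    EK / G * stats::integrate(function(x) pdf(x) * (x - li),
                              lower = li, upper = Inf,
                              rel.tol = rel.tol, subdivisions = 500L)$value
  }, numeric(1))
}

#' Segment-length density from an ALD curve
#'
#' The segment-length density is proportional to the second derivative of
#' the ALD decay curve, `P(l) propto D''(l)`. The derivative is taken by a
#' central finite difference with step `step`; optionally the result is
#' renormalized to unit mass over `grid` by the trapezoid rule.
#'
#' @param D A twice-differentiable function of genetic distance (Morgan).
#' @param grid Strictly increasing distances (Morgan) at which to evaluate.
#' @param step Finite-difference step, Morgan. Must be small relative to the
#'   grid spacing; a warning is issued otherwise.
#' @param normalize Renormalize to unit mass over `grid`?
#' @return Density values on `grid` (unnormalized if `normalize = FALSE`).
#' @export
segment_density_from_ald <- function(D, grid, step = 1e-6, normalize = TRUE) {
  stopifnot(is.function(D), length(grid) >= 2L, all(diff(grid) > 0), step > 0)
  if (step > min(diff(grid)))
    warning("finite-difference step exceeds the grid spacing; ",
            "the grid may be too coarse for the curvature of `D`")
  d2 <- (D(grid + step) - 2 * D(grid) + D(grid - step)) / step^2
  if (normalize) {
    mass <- trapz(grid, d2)
    if (mass <= 0) stop("second derivative has non-positive mass on `grid`")
    d2 <- d2 / mass
  }
  d2
}

# trapezoid rule on an irregular grid
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Effective migration rate
#'
#' Corrects a migration-rate function for replacement of earlier migrants:
#' `m_e(t) = m(t) * exp(-integral_0^t m(s) ds)`, the density of the event
#' that migration at time `t` was the most recent one at a locus. For
#' constant `m(t) = m0` this is `m0 * exp(-m0 * t)`; if `m` integrates to
#' `alpha`, `m_e` integrates to `1 - exp(-alpha)`.
#'
#' @param m A non-negative, integrable migration-rate function of time.
#' @param t Time(s) before sampling, generations, `>= 0`.
#' @return Effective migration rate at each `t`.
#' @export
effective_migration <- function(m, t) {
  stopifnot(is.function(m), all(t >= 0))
  vapply(t, function(ti) {
    cum <- if (ti == 0) 0 else
      stats::integrate(m, 0, ti, rel.tol = 1e-10, subdivisions = 500L)$value
    m(ti) * exp(-cum)
  }, numeric(1))
}

## ---- unit helpers ----------------------------------------------------------

#' Convert generations to years
#'
#' @param t Time(s) in generations, `>= 0`.
#' @param gen_time Generation time in years (default 29).
#' @return `generations_to_years()` returns years; `generations_to_ky()`
#'   returns thousands of years rounded to the nearest integer.
#' @examples
#' generations_to_years(1682)  # 48778
#' generations_to_ky(1682)     # 49
#' @export
generations_to_years <- function(t, gen_time = 29) {
  stopifnot(all(t >= 0), gen_time > 0)
  t * gen_time
}

#' @rdname generations_to_years
#' @export
generations_to_ky <- function(t, gen_time = 29) {
  round(generations_to_years(t, gen_time) / 1000)
}
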