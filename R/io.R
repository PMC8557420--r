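## File formats and genetic-distance utilities. All in-memory distances are
## Morgan; cM appears only at the I/O boundary (factor 100).

#' A weighted-LD decay curve
#'
#' @param distance Strictly increasing genetic distances, Morgan.
#' @param ld Weighted LD values, finite.
#' @param d0 Minimum-distance cutoff, Morgan; points below it are dropped.
#' @return A data frame of class `"ald_curve"` with columns `distance` and
#'   `ld` and attribute `d0`.
#' @export
ald_curve <- function(distance, ld, d0 = min(distance)) {
  stopifnot(length(distance) == length(ld))
  if (any(!is.finite(distance)) || any(!is.finite(ld)))
    stop("distances and LD values must be finite")
  ord <- order(distance)
  distance <- distance[ord]
  ld <- ld[ord]
  keep <- distance >= d0
  distance <- distance[keep]
  ld <- ld[keep]
  if (length(distance) == 0) stop("no points at or above the d0 cutoff")
  if (any(diff(distance) <= 0)) stop("distances must be strictly increasing")
  structure(data.frame(distance = distance, ld = ld),
            d0 = d0, class = c("ald_curve", "data.frame"))
}

#' @export
print.ald_curve <- function(x, ...) {
  cat(sprintf("ALD curve: %d points, %.4g-%.4g cM (d0 = %.4g cM)\n",
              nrow(x), 100 * min(x$distance), 100 * max(x$distance),
              100 * attr(x, "d0")))
  invisible(x)
}

#' Plot an ALD decay curve with optional fitted models
#'
#' @param x An [ald_curve()].
#' @param fits Optional list of `"pulse_fit"` objects from [fit_ald()] to
#'   overlay.
#' @param log_y Log-scale the LD axis?
#' @param ... Passed to [plot()].
#' @export
plot.ald_curve <- function(x, fits = NULL, log_y = FALSE, ...) {
  plot(100 * x$distance, x$ld, pch = 16, cex = 0.5, col = "grey40",
       xlab = "genetic distance (cM)", ylab = "weighted LD",
       log = if (log_y) "y" else "", ...)
  if (!is.null(fits)) {
    for (i in seq_along(fits)) {
      f <- fits[[i]]
      yy <- if (f$model == "simple")
        ald_simple(x$distance, f$t_m, f$A, f$c)
      else
        ald_extended(x$distance, f$t_m, f$k, f$A, f$c)
      graphics::lines(100 * x$distance, yy, col = i + 1, lwd = 2)
    }
    graphics::legend("topright", legend = vapply(fits, `[[`, "", "model"),
                     col = seq_along(fits) + 1, lwd = 2, bty = "n")
  }
  invisible(x)
}

#' Read and write ALD curve files
#'
#' Curves are stored as whitespace-delimited text with two numeric columns,
#' distance in cM and weighted LD — the numeric core of ALDER-style output.
#' Lines starting with `#` (and an optional non-numeric header line) are
#' ignored. On reading, rows below the `d0` cutoff are dropped and the
#' curve is sorted by distance; non-numeric data rows raise an error naming
#' the line.
#'
#' @param path File path.
#' @param d0 Minimum genetic distance to retain, cM (default 0.05; the
#'   short-range LD below it can reflect incomplete lineage sorting rather
#'   than gene flow).
#' @param curve An [ald_curve()].
#' @return `read_ald_curve()` returns an [ald_curve()] (distances in
#'   Morgan); `write_ald_curve()` returns `path` invisibly.
#' @export
read_ald_curve <- function(path, d0 = 0.05) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) stop("no data rows in ", path)
  parse_row <- function(i) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(fields) < 2)
      stop("line ", i, " of ", path, ": expected two columns")
    suppressWarnings(as.numeric(fields[1:2]))
  }
  first <- parse_row(idx[1])
  if (any(is.na(first))) idx <- idx[-1]  # tolerate one header line
  if (length(idx) == 0) stop("no numeric data rows in ", path)
  vals <- vapply(idx, function(i) {
    v <- parse_row(i)
    if (any(is.na(v)))
      stop("line ", i, " of ", path, ": non-numeric value")
    v
  }, numeric(2))
  ald_curve(distance = vals[1, ] / 100, ld = vals[2, ], d0 = d0 / 100)
}

#' @rdname read_ald_curve
#' @export
write_ald_curve <- function(curve, path) {
  stopifnot(inherits(curve, "ald_curve"))
  df <- data.frame(distance_cM = 100 * curve$distance, weighted_LD = curve$ld)
  writeLines(c("# ALD decay curve: distance_cM weighted_LD",
               sprintf("%.*g\t%.*g", 17, df$distance_cM, 17, df$weighted_LD)),
             path)
  invisible(path)
}

## ---- recombination maps ----------------------------------------------------

#' Read a HapMap-format genetic map
#'
#' Expects whitespace- or tab-delimited text with a header and columns
#' physical position (bp), recombination rate (cM/Mb) and cumulative map
#' position (cM); an optional leading chromosome column is detected and
#' ignored. Positions must be strictly increasing, rates non-negative and
#' the cumulative map non-decreasing; violations raise an error naming the
#' offending line.
#'
#' @param path File path.
#' @return An object of class `"recomb_map"`: list with `position` (bp),
#'   `rate` (cM/Mb), `map` (cM), and the `mean_rate` (cM/Mb) over the
#'   covered span.
#' @export
read_recombination_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (length(lines) < 3) stop("map needs a header and at least two rows")
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  ncol <- length(rows[[1]])
  if (ncol < 3) stop("map must have at least three columns")
  off <- ncol - 3L  # skip a leading chromosome column if present
  parse <- function(r, i) {
    v <- suppressWarnings(as.numeric(r[off + 1:3]))
    if (any(is.na(v)))
      stop("line ", i + 1, " of ", path, ": non-numeric value")
    v
  }
  vals <- t(vapply(seq_along(rows), function(i) parse(rows[[i]], i),
                   numeric(3)))
  position <- vals[, 1]; rate <- vals[, 2]; map <- vals[, 3]
  if (any(diff(position) <= 0))
    stop("line ", which(diff(position) <= 0)[1] + 2, " of ", path,
         ": positions not strictly increasing")
  if (any(rate < 0))
    stop("line ", which(rate < 0)[1] + 1, " of ", path, ": negative rate")
  if (any(diff(map) < 0))
    stop("line ", which(diff(map) < 0)[1] + 2, " of ", path,
         ": cumulative map decreases")
  span_mb <- (position[length(position)] - position[1]) / 1e6
  structure(
    list(position = position, rate = rate, map = map,
         mean_rate = (map[length(map)] - map[1]) / span_mb),
    class = "recomb_map"
  )
}

#' @export
print.recomb_map <- function(x, ...) {
  cat(sprintf(
    "Recombination map: %d points, %.4g-%.4g Mb, mean rate %.4g cM/Mb\n",
    length(x$position), x$position[1] / 1e6,
    x$position[length(x$position)] / 1e6, x$mean_rate))
  invisible(x)
}

# interpolate cumulative map position (cM) at physical bp, clamped to ends
interp_map <- function(map, bp) {
  rng <- range(map$position)
  if (any(bp < rng[1] | bp > rng[2]))
    warning("position outside the map span; clamped to the nearest end")
  bp <- pmin(pmax(bp, rng[1]), rng[2])
  stats::approx(map$position, map$map, xout = bp, rule = 2)$y
}

#' Genetic length of a physical interval
#'
#' Converts a physical interval to genetic length in Morgan, either by
#' interpolating a recombination map (difference of cumulative map
#' positions) or by applying a constant rate in cM/Mb. Intervals extending
#' beyond the map span are clamped with a warning.
#'
#' @param start_bp,end_bp Physical coordinates, bp, `start_bp <= end_bp`.
#' @param map A `"recomb_map"` from [read_recombination_map()]; give either
#'   this or `rate_cM_per_Mb`.
#' @param rate_cM_per_Mb Constant recombination rate, cM/Mb.
#' @return Genetic length(s) in Morgan.
#' @examples
#' assign_genetic_length(0, 2e6, rate_cM_per_Mb = 1)  # 0.02 Morgan
#' @export
assign_genetic_length <- function(start_bp, end_bp, map = NULL,
                                  rate_cM_per_Mb = NULL) {
  if (any(start_bp > end_bp)) stop("inverted interval: start_bp > end_bp")
  if (is.null(map) == is.null(rate_cM_per_Mb))
    stop("give exactly one of `map` or `rate_cM_per_Mb`")
  if (!is.null(map)) {
    stopifnot(inherits(map, "recomb_map"))
    (interp_map(map, end_bp) - interp_map(map, start_bp)) / 100
  } else {
    (end_bp - start_bp) / 1e6 * rate_cM_per_Mb / 100
  }
}

#' Filter segments by length cutoffs
#'
#' Retains segments with length between `min_cM` and `max_cM` (inclusive),
#' the standard guard against unreliable very short calls and spuriously
#' merged long ones. The default cutoffs are 0.05 and 1.2 cM.
#'
#' @param set A [segment_set()].
#' @param min_cM,max_cM Length cutoffs, cM, `0 < min_cM < max_cM`.
#' @return A filtered [segment_set()]; the numbers removed at each end are
#'   attached as attribute `removed` and an all-removed result warns.
#' @export
filter_segments <- function(set, min_cM = 0.05, max_cM = 1.2) {
  stopifnot(inherits(set, "segment_set"), min_cM >= 0, min_cM < max_cM)
  len_cM <- 100 * set$lengths
  keep <- len_cM >= min_cM & len_cM <= max_cM
  removed <- c(short = sum(len_cM < min_cM), long = sum(len_cM > max_cM))
  if (!any(keep)) {
    warning("all segments removed by the length cutoffs")
    out <- structure(list(lengths = numeric(0), times = NULL,
                          sampling_time = set$sampling_time, G = set$G,
                          K = 0L), class = "segment_set")
  } else {
    out <- segment_set(set$lengths[keep],
                       times = if (!is.null(set$times)) set$times[keep],
                       sampling_time = set$sampling_time, G = set$G)
  }
  attr(out, "removed") <- removed
  out
}
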