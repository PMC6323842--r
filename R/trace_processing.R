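#' Zero-phase low-pass filtering of a breathing trace
#'
#' Applies a 4th-order Butterworth low-pass filter forward and backward
#' ([signal::filtfilt()]), so the filter is zero-phase and peak/valley
#' timestamps are not shifted. Used to smooth jagged fiducial-tracking
#' traces before cycle segmentation.
#'
#' @param trace a `breathing_trace`.
#' @param cutoff_hz cutoff frequency (Hz); must be below the Nyquist
#'   frequency of the trace. Breathing fundamentals sit at 0.2-0.5 Hz, so the
#'   default 1 Hz passes the motion and removes sampling noise.
#' @param order filter order.
#' @return the filtered `breathing_trace` (same length and sampling).
#' @export
lowpass_filter <- function(trace, cutoff_hz = 1, order = 4) {
  stopifnot(inherits(trace, "breathing_trace"))
  fs <- 1 / trace$sample_interval_s
  if (cutoff_hz >= fs / 2) {
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cutoff_hz, fs / 2))
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  z0 <- trace$displacement_mm
  n <- length(z0)
  # odd-reflection padding suppresses the forward/backward filter edge
  # transients (which would otherwise shift or erase boundary extrema)
  p <- min(n - 1, ceiling(10 * fs / cutoff_hz))
  pre <- 2 * z0[1] - z0[seq(p + 1, 2)]
  post <- 2 * z0[n] - z0[seq(n - 1, n - p)]
  zf <- as.numeric(signal::filtfilt(bf, c(pre, z0, post)))
  out <- trace
  out$displacement_mm <- zf[(p + 1):(p + n)]
  out
}

# locate raw local extrema (1-based sample indices); plateaus resolve to
# their first sample; trace endpoints count as extrema of the matching type
find_raw_extrema <- function(z) {
  n <- length(z)
  dz <- diff(z)
  s <- sign(dz)
  nz <- which(s != 0)
  idx <- integer(0)
  type <- integer(0) # +1 peak, -1 valley
  if (length(nz) == 0) return(list(idx = idx, type = type))
  # leading endpoint
  idx <- c(idx, 1L)
  type <- c(type, if (s[nz[1]] < 0) 1L else -1L)
  if (length(nz) > 1) {
    for (j in seq_len(length(nz) - 1)) {
      if (s[nz[j]] > 0 && s[nz[j + 1]] < 0) {
        idx <- c(idx, nz[j] + 1L)   # first sample of the top plateau
        type <- c(type, 1L)
      } else if (s[nz[j]] < 0 && s[nz[j + 1]] > 0) {
        idx <- c(idx, nz[j] + 1L)
        type <- c(type, -1L)
      }
    }
  }
  # trailing endpoint
  idx <- c(idx, n)
  type <- c(type, if (s[nz[length(nz)]] > 0) 1L else -1L)
  list(idx = idx, type = type)
}

# enforce peak/valley alternation: among consecutive same-type extrema keep
# the most extreme one (first on ties)
enforce_alternation <- function(z, idx, type) {
  keep_i <- 1L
  out_idx <- idx[1]
  out_type <- type[1]
  for (j in seq_along(idx)[-1]) {
    last <- length(out_idx)
    if (type[j] == out_type[last]) {
      better <- if (type[j] > 0) z[idx[j]] > z[out_idx[last]] else
        z[idx[j]] < z[out_idx[last]]
      if (better) out_idx[last] <- idx[j]
    } else {
      out_idx <- c(out_idx, idx[j])
      out_type <- c(out_type, type[j])
    }
  }
  list(idx = out_idx, type = out_type)
}

#' Segment a breathing trace into cycles at its peaks and valleys
#'
#' Detects local maxima and minima, enforces peak/valley alternation, and
#' prunes shallow wiggles whose peak-to-valley excursion is below
#' `prominence_frac` times the inter-quartile range of the trace. A
#' neighboring peak and valley delimit a half-cycle segment; consecutive
#' peaks delimit a full breathing cycle.
#'
#' @param trace a `breathing_trace` (filtered or noise-free).
#' @param prominence_frac minimum peak-to-valley excursion, as a fraction of
#'   the displacement IQR, for a pair of extrema to survive pruning.
#' @return an object of class `cycle_segmentation` with fields
#'   `peak_indices`, `valley_indices`, `segments` (two-column matrix of
#'   consecutive-extrema index pairs), `full_cycles` (two-column matrix of
#'   consecutive-peak index pairs), and `extrema` (all indices with types).
#' @export
segment_cycles <- function(trace, prominence_frac = 0.2) {
  stopifnot(inherits(trace, "breathing_trace"))
  z <- trace$displacement_mm
  raw <- find_raw_extrema(z)
  if (length(raw$idx) < 2) {
    stop("no extremum found: the trace has no alternating peaks and valleys")
  }
  ex <- enforce_alternation(z, raw$idx, raw$type)
  thr <- prominence_frac * IQR(z)
  # iteratively remove the shallowest adjacent extremum pair below threshold
  repeat {
    if (length(ex$idx) < 2) break
    dz <- abs(diff(z[ex$idx]))
    j <- which.min(dz)
    if (dz[j] >= thr) break
    keep <- setdiff(seq_along(ex$idx), c(j, j + 1L))
    if (length(keep) < 2) break
    ex <- enforce_alternation(z, ex$idx[keep], ex$type[keep])
  }
  if (length(unique(ex$type)) < 2) {
    stop("no extremum found: could not identify both a peak and a valley")
  }
  peaks <- ex$idx[ex$type > 0]
  valleys <- ex$idx[ex$type < 0]
  segments <- cbind(start = ex$idx[-length(ex$idx)], end = ex$idx[-1])
  pk <- which(ex$type > 0)
  full <- NULL
  if (length(pk) >= 2) {
    full <- cbind(start = ex$idx[pk[-length(pk)]], end = ex$idx[pk[-1]])
  }
  structure(
    list(
      peak_indices = peaks,
      valley_indices = valleys,
      segments = segments,
      full_cycles = full,
      extrema = list(idx = ex$idx, type = ex$type)
    ),
    class = "cycle_segmentation"
  )
}

#' @export
print.cycle_segmentation <- function(x, ...) {
  cat(sprintf(
    "Cycle segmentation: %d peaks, %d valleys, %d segments, %d full cycles\n",
    length(x$peak_indices), length(x$valley_indices),
    nrow(x$segments), if (is.null(x$full_cycles)) 0L else nrow(x$full_cycles)
  ))
  invisible(x)
}

#' Ten-phase sampling of one segment
#'
#' Splits the time span of a segment into 10 equal intervals and samples the
#' displacement at each interval midpoint (phase-based sorting): phase `i`
#' takes `Z((t_S^i + t_E^i)/2)`, with linear interpolation between trace
#' samples.
#'
#' @param trace a `breathing_trace`.
#' @param segment length-2 vector of sample indices (start, end), e.g. one
#'   row of a [segment_cycles()] `segments` or `full_cycles` matrix.
#' @return numeric vector of 10 displacements (mm), ordered by phase 0..9.
#' @export
phase_sample_segment <- function(trace, segment) {
  stopifnot(inherits(trace, "breathing_trace"), length(segment) == 2)
  t_s <- trace$time_s[segment[1]]
  t_e <- trace$time_s[segment[2]]
  if (!(t_e > t_s)) stop("degenerate segment: end time must exceed start time")
  mids <- t_s + (seq_len(10) - 0.5) / 10 * (t_e - t_s)
  approx(trace$time_s, trace$displacement_mm, xout = mids)$y
}

#' Ten-phase sample sets for every cycle of a trace
#'
#' Applies [phase_sample_segment()] to each breathing cycle. Two conventions
#' are supported for what the 10 phases span: the default `"full_cycle"`
#' splits each peak-to-peak cycle into 10 intervals (the common clinical
#' phase-sorting convention); `"half_cycle"` splits each half-cycle
#' (consecutive peak-valley segment) into 10 intervals, the literal
#' neighboring-peak-and-valley reading.
#'
#' @param trace a `breathing_trace`.
#' @param segmentation optional [segment_cycles()] result (computed if NULL).
#' @param mode `"full_cycle"` or `"half_cycle"`.
#' @return matrix with one row per cycle (or half-cycle segment) and 10
#'   columns, phases 0..9.
#' @export
phase_sample_cycles <- function(trace, segmentation = NULL,
                                mode = c("full_cycle", "half_cycle")) {
  mode <- match.arg(mode)
  if (is.null(segmentation)) segmentation <- segment_cycles(trace)
  spans <- if (mode == "full_cycle") segmentation$full_cycles else
    segmentation$segments
  if (is.null(spans) || nrow(spans) == 0) {
    stop("no ", mode, " spans available in the segmentation")
  }
  out <- t(apply(spans, 1, function(s) phase_sample_segment(trace, s)))
  colnames(out) <- paste0("phase", 0:9)
  out
}

new_position_pdf <- function(positions_mm, probabilities) {
  o <- order(positions_mm)
  positions_mm <- positions_mm[o]
  probabilities <- probabilities[o]
  stopifnot(all(probabilities >= 0),
            abs(sum(probabilities) - 1) <= 1e-9)
  structure(
    list(positions_mm = positions_mm, probabilities = probabilities),
    class = "position_pdf"
  )
}

#' @export
print.position_pdf <- function(x, ...) {
  cat(sprintf("Position pdf over %d bins, [%g, %g] mm\n",
              length(x$positions_mm), min(x$positions_mm), max(x$positions_mm)))
  invisible(x)
}

#' Empirical tumor-position probability density
#'
#' Occupancy histogram of the trace: displacements are rounded to the
#' nearest `bin_mm` (ties away from zero) and each bin's probability is the
#' fraction of trace samples falling in it.
#'
#' @param trace a `breathing_trace`.
#' @param bin_mm bin width in mm (default 1, the phantom's sample-image
#'   spacing).
#' @return an object of class `position_pdf` with `positions_mm` (ascending)
#'   and `probabilities` (summing to 1).
#' @export
empirical_position_pdf <- function(trace, bin_mm = 1) {
  stopifnot(inherits(trace, "breathing_trace"),
            length(trace$displacement_mm) > 0)
  b <- round_half_away(trace$displacement_mm, bin_mm)
  tb <- table(b)
  new_position_pdf(as.numeric(names(tb)), as.numeric(tb) / sum(tb))
}

#' Probability density of per-cycle extreme positions
#'
#' Builds a `position_pdf` from the displacement at every detected peak and
#' valley of the trace (one peak and one valley position per breathing
#' cycle). This is the distribution that drives the robust planning
#' strategy: a phase-image position set covering its central mass covers the
#' positions breathing cycles actually reach, whereas the occupancy
#' histogram of [empirical_position_pdf()] is dominated by the long dwell
#' near the valley of the cos^4 waveform.
#'
#' @param trace a `breathing_trace` (filtered or noise-free).
#' @param segmentation optional [segment_cycles()] result (computed if NULL).
#' @param bin_mm bin width in mm.
#' @return an object of class `position_pdf`.
#' @export
cycle_extreme_pdf <- function(trace, segmentation = NULL, bin_mm = 1) {
  stopifnot(inherits(trace, "breathing_trace"))
  if (is.null(segmentation)) segmentation <- segment_cycles(trace)
  ext <- c(trace$displacement_mm[segmentation$peak_indices],
           trace$displacement_mm[segmentation$valley_indices])
  b <- round_half_away(ext, bin_mm)
  tb <- table(b)
  new_position_pdf(as.numeric(names(tb)), as.numeric(tb) / sum(tb))
}

#' Pool several position pdfs
#'
#' Sample-weighted combination of position pdfs (e.g. across treatment
#' fractions), assuming equal weights by default.
#'
#' @param pdfs list of `position_pdf` objects.
#' @param weights optional non-negative weights, one per pdf.
#' @return an object of class `position_pdf`.
#' @export
pool_position_pdfs <- function(pdfs, weights = NULL) {
  stopifnot(length(pdfs) > 0)
  if (is.null(weights)) weights <- rep(1, length(pdfs))
  weights <- weights / sum(weights)
  acc <- new.env()
  for (i in seq_along(pdfs)) {
    p <- pdfs[[i]]
    for (j in seq_along(p$positions_mm)) {
      key <- as.character(p$positions_mm[j])
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) +
        weights[i] * p$probabilities[j]
    }
  }
  pos <- as.numeric(ls(acc))
  prob <- vapply(ls(acc), function(k) acc[[k]], numeric(1))
  new_position_pdf(pos, prob / sum(prob))
}

#' Equal-tail coverage interval of a position pdf
#'
#' Walks the cumulative distribution from below: `lo` is the smallest
#' position whose cumulative probability reaches `(1 - coverage)/2`, `hi`
#' the smallest reaching `1 - (1 - coverage)/2`. The returned interval
#' therefore holds at least `coverage` of the probability mass with equal
#' tails.
#'
#' @param pdf a `position_pdf`.
#' @param coverage target central probability mass, in (0, 1].
#' @return named numeric vector `c(lo = ..., hi = ...)` in mm.
#' @export
coverage_interval <- function(pdf, coverage = 0.8) {
  stopifnot(inherits(pdf, "position_pdf"))
  if (!is.numeric(coverage) || length(coverage) != 1 ||
      coverage <= 0 || coverage > 1) {
    stop("'coverage' must be in (0, 1]")
  }
  cum <- cumsum(pdf$probabilities)
  tail <- (1 - coverage) / 2
  eps <- 1e-12
  lo <- pdf$positions_mm[which(cum >= tail - eps)[1]]
  hi <- pdf$positions_mm[which(cum >= 1 - tail - eps)[1]]
  c(lo = lo, hi = hi)
}
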