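# Spectral-Doppler quantification: envelope segmentation, velocity-trace
# extraction, ejection-window detection and the clinical measurements
# Vmax / mPG / VTI.

#' Velocity trace
#'
#' @param times Monotone increasing times (s).
#' @param velocities Non-negative velocity magnitudes from the baseline (m/s).
#' @param flagged Logical; `TRUE` marks a degenerate (e.g. empty-mask) trace.
#' @return Object of class `velocity_trace`.
#' @export
velocity_trace <- function(times, velocities, flagged = FALSE) {
  if (length(times) != length(velocities))
    stop("times and velocities must have equal length")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (any(!is.finite(velocities)) || any(velocities < 0))
    stop("velocities must be finite and >= 0")
  structure(list(times = times, velocities = velocities,
                 flagged = isTRUE(flagged)), class = "velocity_trace")
}

#' @export
print.velocity_trace <- function(x, ...) {
  cat(sprintf("velocity_trace: %d samples, peak %.2f m/s%s\n",
              length(x$times), if (length(x$velocities)) max(x$velocities) else 0,
              if (x$flagged) " [flagged: no envelope]" else ""))
  invisible(x)
}

#' Segment the Doppler flow envelope
#'
#' Two interchangeable providers return a per-pixel probability of belonging
#' to the flow envelope on the spectrum grid:
#' * `"threshold"` - deterministic oracle: intensity threshold (isodata
#'   midpoint between background and foreground means) restricted to the
#'   flow side, keeping the connected components comparable in size to the
#'   largest (one per ejection cycle).
#' * `"learned"` - a small fully-convolutional network trained on phantom
#'   (spectrogram, truth-mask) pairs; see [train_doppler_segmenter()].
#'
#' @param spectrum A [doppler_spectrum()].
#' @param provider `"threshold"` or `"learned"`.
#' @param model Trained model (required for `provider = "learned"`).
#' @return Matrix of probabilities in `[0,1]`, same grid as the spectrum.
#' @export
segment_envelope <- function(spectrum, provider = c("threshold", "learned"),
                             model = NULL) {
  stopifnot(inherits(spectrum, "doppler_spectrum"))
  provider <- match.arg(provider)
  if (provider == "threshold") {
    img <- spectrum$intensity
    side <- flow_side_mask(spectrum)
    vals <- img[side]
    thr <- intensity_threshold(vals)
    bin <- img > thr & side
    if (!any(bin)) return(matrix(0, nrow(img), ncol(img)))
    cc <- EBImage::bwlabel(bin * 1)
    sizes <- tabulate(cc[cc > 0])
    # keep every component comparable to the largest (one per ejection
    # cycle); small speckle blobs are discarded
    keep <- which(sizes >= 0.2 * max(sizes))
    prob <- matrix(0, nrow(img), ncol(img))
    prob[cc %in% keep] <- 1
    prob
  } else {
    if (is.null(model)) stop("learned provider requires a trained model")
    predict_segmenter(model, spectrum$intensity)[, , 2]
  }
}

flow_side_mask <- function(spectrum) {
  m <- matrix(FALSE, nrow(spectrum$intensity), ncol(spectrum$intensity))
  if (spectrum$flow_side == "below") {
    if (spectrum$baseline_row < nrow(m))
      m[(spectrum$baseline_row + 1):nrow(m), ] <- TRUE
  } else {
    if (spectrum$baseline_row > 1) m[1:(spectrum$baseline_row - 1), ] <- TRUE
  }
  m
}

# midpoint-iteration threshold (isodata); falls back to 0.5 on flat images
intensity_threshold <- function(vals) {
  thr <- mean(range(vals))
  for (i in 1:20) {
    lo <- vals[vals <= thr]; hi <- vals[vals > thr]
    if (!length(lo) || !length(hi)) return(0.5)
    new <- (mean(lo) + mean(hi)) / 2
    if (abs(new - thr) < 1e-6) break
    thr <- new
  }
  thr
}

#' Velocity trace from an envelope mask
#'
#' For every time column the velocity is the distance (in rows) from the
#' baseline to the furthest envelope pixel on the flow side, times the
#' velocity calibration.  Columns without envelope pixels map to 0; an empty
#' mask yields an all-zero trace flagged as degenerate.
#'
#' @param mask Probability map (binarised at 0.5) on the spectrum grid.
#' @param spectrum The [doppler_spectrum()] providing calibration.
#' @return A [velocity_trace()].
#' @export
trace_from_mask <- function(mask, spectrum) {
  stopifnot(inherits(spectrum, "doppler_spectrum"))
  bin <- mask >= 0.5 & flow_side_mask(spectrum)
  n_col <- ncol(bin)
  tt <- (seq_len(n_col) - 0.5) * spectrum$time_per_col
  v <- numeric(n_col)
  for (j in seq_len(n_col)) {
    rows <- which(bin[, j])
    if (length(rows))
      v[j] <- max(abs(rows - spectrum$baseline_row)) * spectrum$velocity_per_row
  }
  velocity_trace(tt, v, flagged = !any(bin))
}

#' Detect ejection windows in a velocity trace
#'
#' Maximal runs with `v(t) >= threshold_frac * max(v)` lasting at least
#' `min_duration`, then expanded outwards to the surrounding zero crossings
#' so the full ejection profile (including sub-threshold tails) is measured.
#'
#' @param trace A [velocity_trace()].
#' @param threshold_frac Fraction of the global peak (default 0.15).
#' @param min_duration Minimum run duration in seconds (default 0.1).
#' @return Data frame with `start` and `end` columns (seconds); zero rows for
#'   an all-zero trace.
#' @export
detect_ejection_windows <- function(trace, threshold_frac = 0.15,
                                    min_duration = 0.1) {
  stopifnot(inherits(trace, "velocity_trace"))
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stop("threshold_frac must be in (0, 1)")
  v <- trace$velocities; tt <- trace$times
  if (!length(v) || max(v) <= 0)
    return(data.frame(start = numeric(0), end = numeric(0)))
  above <- v >= threshold_frac * max(v)
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  out <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    i0 <- starts[k]; i1 <- ends[k]
    if (tt[i1] - tt[i0] < min_duration) next
    while (i0 > 1 && v[i0 - 1] > 0) i0 <- i0 - 1
    while (i1 < length(v) && v[i1 + 1] > 0) i1 <- i1 + 1
    out[[length(out) + 1]] <- c(tt[i0], tt[i1])
  }
  if (!length(out)) return(data.frame(start = numeric(0), end = numeric(0)))
  m <- do.call(rbind, out)
  # expansion can merge adjacent runs; drop duplicates
  m <- unique(m)
  data.frame(start = m[, 1], end = m[, 2])
}

#' Measure Vmax, mPG and VTI from a velocity trace
#'
#' Per ejection window: `Vmax_w = max v`, `mPG_w` = time average of the
#' instantaneous simplified-Bernoulli gradient `4 v^2`, `VTI_w` = trapezoidal
#' integral of `v` converted to cm.  Windows are aggregated by `policy`
#' (default `mean`); Vmax is additionally reported as the global maximum.
#'
#' @param trace A [velocity_trace()].
#' @param windows Data frame from [detect_ejection_windows()].
#' @param policy `"mean"` or `"max"` cross-window aggregation.
#' @return List with `vmax` (m/s), `mpg` (mmHg), `vti` (cm) and the
#'   `per_window` data frame; all three are `NA` when no window is given.
#' @export
measure_spectral <- function(trace, windows, policy = c("mean", "max")) {
  stopifnot(inherits(trace, "velocity_trace"))
  policy <- match.arg(policy)
  if (is.null(windows) || nrow(windows) == 0)
    return(list(vmax = NA_real_, mpg = NA_real_, vti = NA_real_,
                per_window = data.frame()))
  per <- lapply(seq_len(nrow(windows)), function(k) {
    sel <- trace$times >= windows$start[k] & trace$times <= windows$end[k]
    tt <- trace$times[sel]; v <- trace$velocities[sel]
    if (length(tt) < 2) return(NULL)
    vti_m <- trapz(tt, v)
    # support duration: one sampling interval per sample, so the window is
    # not undercounted by half a column at each edge
    dur <- length(tt) * median(diff(tt))
    data.frame(vmax = max(v), mpg = trapz(tt, bernoulli_pressure(v)) / dur,
               vti = vti_m * 100)
  })
  per <- do.call(rbind, per)
  if (is.null(per) || nrow(per) == 0)
    return(list(vmax = NA_real_, mpg = NA_real_, vti = NA_real_,
                per_window = data.frame()))
  agg <- if (policy == "mean") colMeans(per) else apply(per, 2, max)
  list(vmax = max(per$vmax), mpg = unname(agg["mpg"]),
       vti = unname(agg["vti"]), per_window = per)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Quantify a Doppler spectrum end to end
#'
#' Convenience wrapper: segment (oracle or learned provider), trace, detect
#' windows, measure.
#'
#' @inheritParams segment_envelope
#' @param policy Aggregation policy, see [measure_spectral()].
#' @return As [measure_spectral()], plus the `trace` and `windows`.
#' @export
quantify_doppler <- function(spectrum, provider = c("threshold", "learned"),
                             model = NULL, policy = c("mean", "max")) {
  provider <- match.arg(provider)
  prob <- segment_envelope(spectrum, provider, model)
  trace <- trace_from_mask(prob, spectrum)
  windows <- detect_ejection_windows(trace)
  res <- measure_spectral(trace, windows, match.arg(policy))
  res$trace <- trace
  res$windows <- windows
  res
}
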