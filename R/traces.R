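#' Moving-window percentile of a trace
#'
#' Per-frame percentile over a centered moving window truncated at the trace
#' edges, using the linear-interpolation percentile definition (R quantile
#' type 7). The default 8th percentile over 500-frame windows tracks the
#' slowly varying baseline underneath sparse positive transients.
#'
#' @param trace Numeric vector (nonempty).
#' @param window_frames Window length in frames (>= 2).
#' @param q Percentile in \[0, 100\].
#' @param align `"centered"` (default) or `"causal"` (window ends at the
#'   current frame).
#' @return Numeric vector of the same length.
#' @export
moving_percentile <- function(trace, window_frames = 500L, q = 8,
                              align = c("centered", "causal")) {
  align <- match.arg(align)
  n <- length(trace)
  if (n == 0) stop("empty trace")
  if (window_frames < 2) stop("window_frames must be >= 2")
  if (q < 0 || q > 100) stop("q must be in [0, 100]")
  half_lo <- floor((window_frames - 1) / 2)
  half_hi <- window_frames - 1 - half_lo
  out <- numeric(n)
  for (t in seq_len(n)) {
    if (align == "centered") {
      lo <- max(1L, t - half_lo); hi <- min(n, t + half_hi)
    } else {
      lo <- max(1L, t - window_frames + 1L); hi <- t
    }
    out[t] <- quantile(trace[lo:hi], q / 100, type = 7, names = FALSE)
  }
  out
}

#' Detrend a denoised trace by a moving percentile
#'
#' Removes the moving 8th percentile (500-frame windows by default) from a
#' denoised trace; the removed trend is returned because it re-enters the
#' baseline estimate.
#'
#' @param denoised Numeric trace.
#' @param window_frames,q,align Passed to [moving_percentile()].
#' @return List with `detrended` and `trend`.
#' @export
detrend_trace <- function(denoised, window_frames = 500L, q = 8,
                          align = "centered") {
  trend <- moving_percentile(denoised, window_frames, q, align)
  list(detrended = denoised - trend, trend = trend)
}

#' Baseline F0 for the moving-percentile (CNMF-style) variant
#'
#' The baseline is the cell's detrending residual (trend) plus the moving
#' 8th percentile of the global background component restricted to the
#' cell's spatial mask.
#'
#' @param trend Per-frame trend removed by [detrend_trace()].
#' @param background_model A `background_model` (or `NULL` for none).
#' @param mask The cell's `cell_mask`.
#' @param window_frames,q Moving-percentile parameters.
#' @return Per-frame baseline `f0` (must be positive wherever used).
#' @export
baseline_f0_cnmf <- function(trend, background_model, mask,
                             window_frames = 500L, q = 8) {
  bg <- 0
  if (!is.null(background_model)) {
    stopifnot(inherits(background_model, "background_model"))
    w <- mean(background_model$spatial_map[mask$pixels])
    bg_trace <- w * background_model$temporal_trace
    bg <- moving_percentile(bg_trace, window_frames, q)
  }
  f0 <- trend + bg
  if (any(f0 <= 0)) stop("non-positive baseline")
  f0
}

#' Delta-F-over-F, moving-percentile variant
#'
#' The denoised, detrended trace divided by the baseline from
#' [baseline_f0_cnmf()]; unitless.
#'
#' @param detrended Detrended denoised trace.
#' @param f0 Per-frame positive baseline.
#' @param frame_rate_hz Acquisition rate, carried in the result.
#' @return Object of class `dff_trace` with fields `dff`, `f0`,
#'   `frame_rate_hz`, `variant = "cnmf"`.
#' @export
dff_cnmf <- function(detrended, f0, frame_rate_hz = NA_real_) {
  if (any(f0 <= 0)) stop("non-positive baseline")
  structure(list(dff = detrended / f0, f0 = f0,
                 frame_rate_hz = frame_rate_hz, variant = "cnmf"),
            class = "dff_trace")
}

#' Delta-F-over-F, simple background-subtraction variant (percent)
#'
#' `F` is the raw ROI trace minus a background trace (e.g. the mean pixel
#' value of a blood-vessel region without indicator expression). `F0` is
#' the mean of `F` over an inactive window, found automatically as the
#' contiguous segment of about `inactive_seconds` minimizing the trace
#' variance (a reproducible stand-in for manual selection). The result is
#' `(F - F0) / F0 * 100`, in percent.
#'
#' @param raw_trace Raw ROI fluorescence per frame.
#' @param background_trace Background trace (scalar or per frame).
#' @param frame_rate_hz Frame rate (Hz), used to size the inactive window.
#' @param inactive_seconds Length of the inactive window (seconds).
#' @return Object of class `dff_trace` with `dff` in percent, scalar-`f0`
#'   expanded per frame, `variant = "simple"`, and attribute
#'   `inactive_window` (frame range used).
#' @export
dff_simple <- function(raw_trace, background_trace = 0, frame_rate_hz,
                       inactive_seconds = 2) {
  f <- raw_trace - background_trace
  n <- length(f)
  w <- max(2L, min(n, round(inactive_seconds * frame_rate_hz)))
  # contiguous window of minimum variance
  best <- 1L; best_var <- Inf
  for (s in seq_len(n - w + 1L)) {
    v <- var(f[s:(s + w - 1L)])
    if (v < best_var) { best_var <- v; best <- s }
  }
  f0 <- mean(f[best:(best + w - 1L)])
  if (f0 <= 0) stop("non-positive baseline F0")
  out <- structure(list(dff = (f - f0) / f0 * 100, f0 = rep(f0, n),
                        frame_rate_hz = frame_rate_hz, variant = "simple"),
                   class = "dff_trace")
  attr(out, "inactive_window") <- c(best, best + w - 1L)
  out
}

#' Full moving-percentile ΔF/F pipeline for one component
#'
#' Convenience wrapper chaining detrending, baseline estimation and
#' division for a component extracted by [extract_components()]. The
#' denoised trace rides on top of the component's baseline offset (the 8th
#' percentile of its background-subtracted raw trace), so that offset is
#' restored before detrending to keep the baseline positive.
#'
#' @param component An extracted `component`.
#' @param background A `background_model`.
#' @param frame_rate_hz Acquisition rate.
#' @param window_frames,q Moving-percentile parameters.
#' @return A `dff_trace` (variant `"cnmf"`).
#' @export
component_dff <- function(component, background, frame_rate_hz = NA_real_,
                          window_frames = 500L, q = 8) {
  stopifnot(inherits(component, "component"))
  raw0 <- component$raw_trace - component$background_at_mask
  offset <- as.numeric(quantile(raw0, 0.08, type = 7))
  full <- component$denoised_trace + offset
  dt <- detrend_trace(full, window_frames, q)
  f0 <- baseline_f0_cnmf(dt$trend, background, component$mask,
                         window_frames, q)
  dff_cnmf(dt$detrended, f0, frame_rate_hz)
}
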