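#' Align ΔF/F traces to the choice time
#'
#' For each completed trial, extracts the window ending at the choice time,
#' averages frames into fixed-width time bins, and stacks the result into a
#' cells x trials x bins tensor. Timeout trials (no choice time) are
#' excluded and counted.
#'
#' @param dff_traces Matrix `[cells, frames]` of ΔF/F values.
#' @param behavior A `behavior_log` on the same clock as the traces.
#' @param frame_rate_hz Frame rate of `dff_traces`; defaults to the
#'   behavior log's rate.
#' @param window_s Length of the pre-choice window (seconds).
#' @param bin_s Bin width (seconds); must tile the window exactly.
#' @param t0_s Time of the first frame's center (seconds).
#' @return Object of class `trial_tensor`: `values` (`[cell, trial, bin]`,
#'   `NA` for bins without frames), `bin_centers_s` (relative to choice),
#'   `bin_s`, `window_s`, `trial_index` (rows of `behavior$trials` used),
#'   `n_excluded` (timeout trials), `truncated` (trials with empty bins).
#' @export
align_to_choice <- function(dff_traces, behavior, frame_rate_hz = NULL,
                            window_s = 4, bin_s = 0.5, t0_s = NULL) {
  stopifnot(is.matrix(dff_traces), inherits(behavior, "behavior_log"))
  if (is.null(frame_rate_hz)) frame_rate_hz <- behavior$frame_rate_hz
  n_bins <- window_s / bin_s
  if (abs(n_bins - round(n_bins)) > 1e-9)
    stop("bin_s must tile window_s exactly")
  n_bins <- as.integer(round(n_bins))
  nf <- ncol(dff_traces)
  frame_t <- if (is.null(t0_s)) (seq_len(nf) - 0.5) / frame_rate_hz
             else t0_s + (seq_len(nf) - 1L) / frame_rate_hz
  tr <- behavior$trials
  usable <- which(!is.na(tr$t_choice))
  n_excl <- nrow(tr) - length(usable)
  if (length(usable) == 0) stop("no alignable trials")
  vals <- array(NA_real_, c(nrow(dff_traces), length(usable), n_bins))
  truncated <- logical(length(usable))
  for (k in seq_along(usable)) {
    tc <- tr$t_choice[usable[k]]
    edges <- tc - window_s + (0:n_bins) * bin_s
    bin_of <- findInterval(frame_t, edges, rightmost.closed = FALSE,
                           left.open = FALSE)
    inside <- bin_of >= 1 & bin_of <= n_bins & frame_t < tc
    for (b in seq_len(n_bins)) {
      f <- which(inside & bin_of == b)
      if (length(f)) vals[, k, b] <- rowMeans(dff_traces[, f, drop = FALSE])
    }
    truncated[k] <- anyNA(vals[1, k, ])
  }
  structure(list(values = vals,
                 bin_centers_s = -window_s + (seq_len(n_bins) - 0.5) * bin_s,
                 bin_s = bin_s, window_s = window_s,
                 trial_index = usable, n_excluded = n_excl,
                 truncated = truncated,
                 alignment_event = "choice"),
            class = "trial_tensor")
}

#' Trial-averaged activity matrix from a trial tensor
#'
#' @param tensor A `trial_tensor`.
#' @return Matrix `[cells, bins]` of across-trial means (NA bins skipped).
#' @export
trial_mean <- function(tensor) {
  stopifnot(inherits(tensor, "trial_tensor"))
  apply(tensor$values, c(1, 3), mean, na.rm = TRUE)
}

#' Normalize per-cell activity to 0-1 and sort by peak bin
#'
#' Each cell's row is min-max normalized to the range 0-1; cells are then
#' ordered by the time bin of their maximum (ties by cell index).
#' Degenerate cells with zero range become all-zero rows and sort last.
#'
#' @param activity Matrix `[cells, bins]` (e.g. from [trial_mean()]), or a
#'   `trial_tensor`.
#' @return Object of class `sorted_activity_map`: `normalized` (rows
#'   reordered), `order` (cell permutation), `peak_bin` (per cell, in
#'   original cell order; `NA` for degenerate cells).
#' @export
normalize_and_sort <- function(activity) {
  if (inherits(activity, "trial_tensor")) activity <- trial_mean(activity)
  stopifnot(is.matrix(activity), nrow(activity) >= 1, ncol(activity) >= 1)
  n <- nrow(activity)
  norm <- activity
  peak <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    r <- activity[i, ]
    rng <- max(r, na.rm = TRUE) - min(r, na.rm = TRUE)
    if (!is.finite(rng) || rng == 0) {
      norm[i, ] <- 0
    } else {
      norm[i, ] <- (r - min(r, na.rm = TRUE)) / rng
      peak[i] <- which.max(norm[i, ])
    }
  }
  ord <- order(ifelse(is.na(peak), Inf, peak), seq_len(n))
  structure(list(normalized = norm[ord, , drop = FALSE], order = ord,
                 peak_bin = peak),
            class = "sorted_activity_map")
}

#' Indices of the k most active cells
#'
#' Cells ranked by session-mean ΔF/F, descending, ties broken by cell
#' index.
#'
#' @param dff_traces Matrix `[cells, frames]`.
#' @param k Number of cells (1 <= k <= number of cells).
#' @return Integer vector of length `k`.
#' @export
top_k_cells <- function(dff_traces, k = 10L) {
  stopifnot(is.matrix(dff_traces))
  if (k <= 0) stop("k must be positive")
  if (k > nrow(dff_traces)) stop("k exceeds the number of cells")
  means <- rowMeans(dff_traces)
  order(-means, seq_len(nrow(dff_traces)))[seq_len(k)]
}

#' Compare trial-aligned activity across two sessions
#'
#' Builds the matched-versus-unique activity maps: cells matched across the
#' sessions are shown in both maps in the order of their session-A peak
#' bin, while cells unique to each session are normalized and sorted within
#' their own session.
#'
#' @param activity_a,activity_b Matrices `[cells, bins]` (or
#'   `trial_tensor`s) on identical windows and bins.
#' @param match A `match_result` with `i` indexing session-A cells and `j`
#'   session-B cells.
#' @return List with `matched_a`, `matched_b` (both `sorted_activity_map`s
#'   in session-A peak order), `unique_a`, `unique_b` (each session's own
#'   order), and `pairs`.
#' @export
compare_sessions <- function(activity_a, activity_b, match) {
  if (inherits(activity_a, "trial_tensor")) activity_a <- trial_mean(activity_a)
  if (inherits(activity_b, "trial_tensor")) activity_b <- trial_mean(activity_b)
  stopifnot(inherits(match, "match_result"))
  if (ncol(activity_a) != ncol(activity_b))
    stop("sessions analyzed on different bin grids")
  pr <- match$pairs
  matched_a <- matched_b <- NULL
  if (nrow(pr)) {
    matched_a <- normalize_and_sort(activity_a[pr$i, , drop = FALSE])
    # impose the session-A peak order on both matched maps
    mb_raw <- normalize_and_sort(activity_b[pr$j, , drop = FALSE])
    norm_b <- mb_raw$normalized[order(mb_raw$order), , drop = FALSE]  # unsorted
    matched_b <- structure(list(normalized = norm_b[matched_a$order, , drop = FALSE],
                                order = matched_a$order,
                                peak_bin = mb_raw$peak_bin),
                           class = "sorted_activity_map")
  }
  ua <- setdiff(seq_len(nrow(activity_a)), pr$i)
  ub <- setdiff(seq_len(nrow(activity_b)), pr$j)
  list(pairs = pr,
       matched_a = matched_a,
       matched_b = matched_b,
       unique_a = if (length(ua))
         normalize_and_sort(activity_a[ua, , drop = FALSE]),
       unique_b = if (length(ub))
         normalize_and_sort(activity_b[ub, , drop = FALSE]),
       unique_a_cells = ua,
       unique_b_cells = ub)
}
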