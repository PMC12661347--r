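#' Construct a cell mask
#'
#' @param pixels Two-column matrix of `(row, col)` pixel coordinates.
#' @param plane_index Imaging plane the mask belongs to.
#' @param check Verify the mask is a nonempty single 4-connected component.
#' @return Object of class `cell_mask` with `pixels`, `plane_index`,
#'   `centroid_px` (row, col) and `area_px2`.
#' @export
cell_mask <- function(pixels, plane_index = 1L, check = TRUE) {
  pixels <- matrix(as.integer(pixels), ncol = 2)
  if (check) {
    if (nrow(pixels) == 0) stop("empty mask")
    if (!is_4connected(pixels)) stop("mask is not a single 4-connected component")
  }
  structure(list(
    pixels = pixels,
    plane_index = as.integer(plane_index),
    centroid_px = if (nrow(pixels)) colMeans(pixels) else c(NA_real_, NA_real_),
    area_px2 = nrow(pixels)
  ), class = "cell_mask")
}

is_4connected <- function(pixels) {
  n <- nrow(pixels)
  if (n == 1L) return(TRUE)
  key <- paste(pixels[, 1], pixels[, 2])
  seen <- logical(n); seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- integer(0)
    for (i in frontier) {
      nb <- rbind(pixels[i, ] + c(1L, 0L), pixels[i, ] - c(1L, 0L),
                  pixels[i, ] + c(0L, 1L), pixels[i, ] - c(0L, 1L))
      hits <- match(paste(nb[, 1], nb[, 2]), key)
      hits <- hits[!is.na(hits)]
      hits <- hits[!seen[hits]]
      seen[hits] <- TRUE
      nxt <- c(nxt, hits)
    }
    frontier <- nxt
  }
  all(seen)
}

# Binary matrix for a mask within the given image dimensions.
mask_to_matrix <- function(mask, dim) {
  m <- matrix(0L, dim[1], dim[2])
  if (nrow(mask$pixels)) m[mask$pixels] <- 1L
  m
}

#' Detect cell masks by adaptive thresholding
#'
#' Thresholds a summary image (typically the brightness-corrected mean
#' projection) against a local-mean surface, removes small holes, drops
#' small components, and labels the remaining 4-connected components as
#' candidate cell masks.
#'
#' @param summary_image Numeric matrix.
#' @param block_px Side of the local-mean window (odd, >= 3).
#' @param offset Absolute intensity offset over the local mean; if `NULL`,
#'   `offset_k` times the robust noise SD (MAD of the image) is used.
#' @param offset_k Multiplier for the automatic offset.
#' @param min_size_px2 Components smaller than this are dropped.
#' @param min_hole_px2 Interior holes smaller than this are filled before
#'   labeling.
#' @param plane_index Plane label carried into the masks.
#' @return List of `cell_mask` objects (empty list for a blank image).
#' @export
detect_masks <- function(summary_image, block_px = 51L, offset = NULL,
                         offset_k = 3, min_size_px2 = 6L, min_hole_px2 = 4L,
                         plane_index = 1L) {
  stopifnot(is.matrix(summary_image))
  if (block_px %% 2 != 1 || block_px < 3) stop("block_px must be odd and >= 3")
  img <- summary_image
  rng <- max(img) - min(img)
  if (rng <= 0) return(list())
  if (is.null(offset)) {
    sigma <- stats::mad(img)
    if (sigma <= 0) sigma <- rng / 100
    offset <- offset_k * sigma
  }
  w <- (block_px - 1L) / 2L
  norm <- (img - min(img)) / rng
  bw <- as_plain_matrix(EBImage::thresh(norm, w = w, h = w,
                                        offset = offset / rng))
  bw <- fill_small_holes(bw, min_hole_px2)
  lab <- as_plain_matrix(EBImage::bwlabel(bw))
  if (max(lab) == 0) return(list())
  masks <- list()
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < min_size_px2) next
    masks[[length(masks) + 1L]] <- cell_mask(idx, plane_index = plane_index,
                                             check = FALSE)
  }
  masks
}

# Fill interior background holes smaller than min_hole_px2 pixels.
fill_small_holes <- function(bw, min_hole_px2) {
  if (min_hole_px2 <= 0) return(bw)
  inv <- 1L - bw
  lab <- as_plain_matrix(EBImage::bwlabel(inv))
  if (max(lab) == 0) return(bw)
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sizes <- tabulate(lab, nbins = max(lab))
  for (k in seq_len(max(lab))) {
    if (k %in% border_labels) next
    if (sizes[k] < min_hole_px2) bw[lab == k] <- 1L
  }
  bw
}

#' Count cells in a recording
#'
#' Brightness-corrects the mean projection of a movie and counts the masks
#' found by [detect_masks()]. Applied to functional and structural channels
#' alike to track the stability of fluorophore expression across days.
#'
#' @param recording An `imaging_session`, a 3-D array `[rows, cols, frames]`,
#'   or a summary matrix.
#' @param plane Plane to analyze when `recording` is a multi-plane session.
#' @param ... Passed to [detect_masks()].
#' @return Integer cell count.
#' @export
count_cells <- function(recording, plane = 1L, ...) {
  img <- summary_image(recording, plane)
  img <- brightness_correct(img)
  length(detect_masks(img, ...))
}

summary_image <- function(recording, plane = 1L) {
  if (inherits(recording, "imaging_session"))
    return(apply(recording$movie[, , plane, , drop = FALSE], c(1, 2), mean))
  if (is.array(recording) && length(dim(recording)) == 3L)
    return(apply(recording, c(1, 2), mean))
  if (is.matrix(recording)) return(recording)
  stop("cannot reduce recording to a summary image")
}

#' Extract component traces and a rank-1 background model
#'
#' Seeds one component per cell mask: the raw trace is the mean over the
#' mask's pixels per frame. A global rank-1 nonnegative background
#' (spatial map x temporal trace) is estimated by alternating least squares
#' on the non-cell pixels and extended to cell pixels by regression on each
#' component's least-active frames. Each component also receives an AR(1)
#' coefficient estimate and a deconvolution of its background-subtracted,
#' baseline-subtracted trace.
#'
#' @param movie 3-D array `[rows, cols, frames]` (one plane), or an
#'   `imaging_session` (use `plane`).
#' @param masks List of `cell_mask`s within the movie frame.
#' @param plane Plane to extract when a session is given.
#' @param gamma AR(1) coefficient; `NULL` to estimate per component.
#' @param lambda_sd Sparsity weight for deconvolution, in units of each
#'   trace's robust noise SD.
#' @param bg_iter Alternating-update iterations for the background model.
#' @return List with `components` (list of `component` objects) and
#'   `background` (class `background_model`: `spatial_map` max-normalized
#'   to 1, `temporal_trace`).
#' @export
extract_components <- function(movie, masks, plane = 1L, gamma = NULL,
                               lambda_sd = 2, bg_iter = 25L) {
  if (inherits(movie, "imaging_session"))
    movie <- movie$movie[, , plane, ]
  stopifnot(length(dim(movie)) == 3L)
  H <- dim(movie)[1]; W <- dim(movie)[2]; Tn <- dim(movie)[3]
  Y <- matrix(movie, H * W, Tn)
  cell_px <- matrix(FALSE, H, W)
  for (m in masks) {
    if (any(m$pixels[, 1] > H | m$pixels[, 2] > W | m$pixels < 1))
      stop("mask outside movie frame")
    cell_px[m$pixels] <- TRUE
  }
  # warn on fully-overlapped masks
  if (length(masks) > 1) {
    for (i in seq_along(masks)) {
      others <- matrix(FALSE, H, W)
      for (j in seq_along(masks)) if (j != i) others[masks[[j]]$pixels] <- TRUE
      if (all(others[masks[[i]]$pixels]))
        warning("mask ", i, " fully overlapped by other masks")
    }
  }
  bg <- rank1_background(Y, as.vector(!cell_px), H, W, n_iter = bg_iter)
  components <- vector("list", length(masks))
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    lin <- (m$pixels[, 2] - 1L) * H + m$pixels[, 1]
    raw <- colMeans(Y[lin, , drop = FALSE])
    bg_here <- mean(bg$spatial_map[m$pixels]) * bg$temporal_trace
    sub <- raw - bg_here
    g <- if (is.null(gamma)) estimate_gamma(sub) else gamma
    base <- as.numeric(quantile(sub, 0.08, type = 7))
    lam <- lambda_sd * robust_noise_sd(sub)
    dec <- deconvolve_ar1(sub - base, g, lambda = lam)
    components[[i]] <- structure(list(
      mask = m, raw_trace = raw, background_at_mask = bg_here,
      denoised_trace = dec$denoised, spikes = dec$spikes, gamma = g,
      snr = NA_real_, rvalue = NA_real_, decision = "undecided"
    ), class = "component")
  }
  list(components = components, background = bg)
}

# Alternating nonnegative rank-1 factorization of the movie restricted to
# background (non-cell) pixels, then extended to all pixels.
rank1_background <- function(Y, bg_mask_vec, H, W, n_iter = 25L) {
  B <- Y[bg_mask_vec, , drop = FALSE]
  if (nrow(B) == 0) {
    map <- matrix(1, H, W)
    tr <- colMeans(Y)
    return(structure(list(spatial_map = map, temporal_trace = tr),
                     class = "background_model"))
  }
  f <- colMeans(B)
  if (sum(f^2) == 0)
    return(structure(list(spatial_map = matrix(0, H, W),
                          temporal_trace = rep(0, ncol(B))),
                     class = "background_model"))
  a <- rep(1, nrow(B))
  for (it in seq_len(n_iter)) {
    a <- pmax(as.vector(B %*% f) / sum(f^2), 0)
    denom <- sum(a^2)
    if (denom == 0) break
    f <- pmax(as.vector(crossprod(B, a)) / denom, 0)
  }
  # Extend spatial weights to cell pixels by local interpolation from the
  # surrounding non-cell pixels: the global background is spatially smooth,
  # and regressing cell pixels on the background trace would wrongly absorb
  # each cell's constant resting fluorescence into the background.
  a_all <- rep(NA_real_, nrow(Y))
  a_all[bg_mask_vec] <- a
  amat <- matrix(a_all, H, W)
  holes <- which(!bg_mask_vec)
  if (length(holes)) {
    hr <- (holes - 1L) %% H + 1L
    hc <- (holes - 1L) %/% H + 1L
    for (k in seq_along(holes)) {
      r <- 3L
      repeat {
        rows <- max(1L, hr[k] - r):min(H, hr[k] + r)
        cols <- max(1L, hc[k] - r):min(W, hc[k] + r)
        nb <- amat[rows, cols]
        nb <- nb[!is.na(nb)]
        if (length(nb) >= 8L || r > max(H, W)) break
        r <- r * 2L
      }
      a_all[holes[k]] <- if (length(nb)) stats::median(nb) else 0
    }
  }
  a_all <- pmax(a_all, 0)
  mx <- max(a_all)
  if (mx > 0) {
    a_all <- a_all / mx
    f <- f * mx
  }
  structure(list(spatial_map = matrix(a_all, H, W), temporal_trace = f),
            class = "background_model")
}

#' Evaluate a component's SNR and spatial consistency
#'
#' Computes the two screening metrics used to triage candidate components:
#'
#' * `snr`: the equivalent-Gaussian score of the largest transient under a
#'   gamma null. A gamma distribution is fitted by the method of moments to
#'   the positive residuals (raw minus denoised trace) to accommodate the
#'   skewed, shot-noise-like residuals of the darkest parts of the field;
#'   the survival probability `p` of the denoised trace's peak is corrected
#'   for the number of frames (the chance of such a peak anywhere in the
#'   trace) and mapped through the standard-normal quantile:
#'   `snr = qnorm((1 - p)^T)`, clipped to \[0, 100\].
#' * `rvalue`: the Pearson correlation, within the mask's bounding box,
#'   between the mask footprint and the movie averaged over the component's
#'   most-active frames (top decile of the denoised trace, at least 5
#'   frames).
#'
#' @param component A `component` (with a denoised trace).
#' @param movie The movie array `[rows, cols, frames]` the component was
#'   extracted from (or an `imaging_session`, with `plane`).
#' @param plane Plane index for session input.
#' @param active_quantile Quantile of the denoised trace defining the
#'   most-active frames.
#' @param min_active_frames Minimum number of active frames.
#' @return The component with `snr` and `rvalue` filled in.
#' @export
evaluate_component <- function(component, movie, plane = 1L,
                               active_quantile = 0.9, min_active_frames = 5L) {
  stopifnot(inherits(component, "component"))
  if (inherits(movie, "imaging_session")) movie <- movie$movie[, , plane, ]
  den <- component$denoised_trace
  raw0 <- component$raw_trace - component$background_at_mask
  raw0 <- raw0 - as.numeric(quantile(raw0, 0.08, type = 7))
  resid <- raw0 - den
  pos <- resid[resid > 0]
  peak <- max(den)
  if (length(pos) < 10L || var(pos) == 0) {
    component$snr <- if (peak > 0) Inf else 0
    attr(component, "degenerate_residual") <- TRUE
  } else {
    m1 <- mean(pos); v1 <- var(pos)
    shape <- m1^2 / v1; scale <- v1 / m1
    p <- pgamma(peak, shape = shape, scale = scale, lower.tail = FALSE)
    component$snr <- min(max(qnorm((1 - p)^length(den)), 0), 100)
  }
  # spatial consistency over the most-active frames
  thr <- as.numeric(quantile(den, active_quantile, type = 7))
  active <- which(den >= thr)
  if (length(active) < min_active_frames)
    active <- order(den, decreasing = TRUE)[seq_len(min(min_active_frames, length(den)))]
  px <- component$mask$pixels
  rr <- range(px[, 1]); cc <- range(px[, 2])
  box_img <- apply(movie[rr[1]:rr[2], cc[1]:cc[2], active, drop = FALSE],
                   c(1, 2), mean)
  foot <- matrix(0, diff(rr) + 1L, diff(cc) + 1L)
  foot[cbind(px[, 1] - rr[1] + 1L, px[, 2] - cc[1] + 1L)] <- 1
  component$rvalue <- if (sd(box_img) == 0 || sd(foot) == 0) 0
                      else cor(as.vector(foot), as.vector(box_img))
  component
}

#' Classify components by SNR and r-value
#'
#' Applies the screening rule: components are first *rejected* if their SNR
#' or r-value falls below the rejection thresholds, regardless of the other
#' metric; surviving components are accepted if either metric exceeds its
#' acceptance threshold; all others remain undecided.
#'
#' @param metrics Data frame or matrix with columns `snr` and `rvalue` (or
#'   a list of evaluated `component`s).
#' @param accept_snr,accept_r Acceptance thresholds (exceed either).
#' @param reject_snr,reject_r Rejection thresholds (fall below either).
#' @return Character vector (or, for component input, the components with
#'   `decision` set): `"accepted"`, `"rejected"`, or `"undecided"`.
#' @export
classify_components <- function(metrics, accept_snr = 1.2, accept_r = 0.85,
                                reject_snr = 0.5, reject_r = 0.1) {
  if (reject_snr >= accept_snr || reject_r >= accept_r)
    stop("rejection thresholds must lie below acceptance thresholds")
  if (is.list(metrics) && length(metrics) && inherits(metrics[[1]], "component")) {
    snr <- vapply(metrics, `[[`, numeric(1), "snr")
    rv <- vapply(metrics, `[[`, numeric(1), "rvalue")
    dec <- classify_components(data.frame(snr = snr, rvalue = rv),
                               accept_snr, accept_r, reject_snr, reject_r)
    for (i in seq_along(metrics)) metrics[[i]]$decision <- dec[i]
    return(metrics)
  }
  metrics <- as.data.frame(metrics)
  stopifnot(all(c("snr", "rvalue") %in% names(metrics)))
  decision <- rep("undecided", nrow(metrics))
  rejected <- metrics$snr < reject_snr | metrics$rvalue < reject_r
  accepted <- !rejected & (metrics$snr > accept_snr | metrics$rvalue > accept_r)
  decision[accepted] <- "accepted"
  decision[rejected] <- "rejected"
  decision
}

#' @export
print.component <- function(x, ...) {
  cat(sprintf("<component> %d px @ plane %d, gamma=%.3f, snr=%s, r=%s, %s\n",
              x$mask$area_px2, x$mask$plane_index, x$gamma,
              format(x$snr, digits = 3), format(x$rvalue, digits = 3),
              x$decision))
  invisible(x)
}
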