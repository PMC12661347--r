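#' Brightness-correct an image
#'
#' Divides an image by its low-frequency brightness map, obtained by median
#' filtering with a uniform square kernel (default 25 x 25 pixels). Used on
#' mean projections before mask detection and piecewise-rigid mapping so
#' that uneven illumination and expression density do not bias thresholds
#' or correlations.
#'
#' @param image Nonnegative numeric matrix.
#' @param kernel_px Side of the square median-filter kernel; odd, >= 3.
#' @param eps Floor applied to the brightness map to guard division.
#' @return Matrix of the same size, approximately flat-field.
#' @export
brightness_correct <- function(image, kernel_px = 25L, eps = 1e-6) {
  stopifnot(is.matrix(image))
  if (kernel_px %% 2 != 1 || kernel_px < 3) stop("kernel_px must be odd and >= 3")
  if (kernel_px > min(dim(image))) stop("kernel larger than image")
  if (any(image < 0)) stop("image must be nonnegative")
  mx <- max(image)
  if (mx <= 0) return(image)
  bmap <- as_plain_matrix(
    EBImage::medianFilter(image / mx, size = (kernel_px - 1L) / 2L)) * mx
  image / pmax(bmap, eps)
}

# Zero-mean normalized circular cross-correlation surface between two
# equal-sized matrices, computed with FFTs. Entry [i, j] is the correlation
# after rolling `image` by the shift (dy, dx) indexed at [i, j] of the
# returned shift grids.
zncc_surface <- function(image, reference) {
  stopifnot(all(dim(image) == dim(reference)))
  a <- image - mean(image)
  b <- reference - mean(reference)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("degenerate correlation: zero-variance input")
  cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE)) /
    length(a)
  cc / (na * nb)
}

# Index of circular-correlation surface for a given shift.
shift_index <- function(s, n) ((s %% n) + n) %% n + 1L

#' Rigid XY shift between two images
#'
#' Finds the in-plane translation maximizing the zero-mean normalized
#' cross-correlation between `image` and `reference`, searched over a
#' bounded window of shifts, with optional parabolic sub-pixel refinement.
#' The returned shift is the one to *apply to `image`* so that it best
#' matches `reference`.
#'
#' @param image,reference Equal-sized numeric matrices.
#' @param pixel_size_um Pixel size `c(x, y)` used to report the shift in
#'   micrometres.
#' @param max_shift_px Half-width of the shift search window (pixels).
#' @param subpixel Parabolic interpolation around the integer peak.
#' @param corr_floor Peak correlations below this value set the
#'   `low_confidence` flag.
#' @return Object of class `shift_xy`: `dx_px`, `dy_px`, `dx_um`, `dy_um`,
#'   `peak_corr`, `source_plane` (filled by [best_xy_over_stack()]),
#'   `low_confidence`.
#' @export
rigid_shift_xy <- function(image, reference, pixel_size_um = c(1, 1),
                           max_shift_px = 20L, subpixel = TRUE,
                           corr_floor = 0.2) {
  cc <- zncc_surface(image, reference)
  nr <- nrow(cc); nc <- ncol(cc)
  sy <- -max_shift_px:max_shift_px
  sx <- -max_shift_px:max_shift_px
  sub <- cc[shift_index(sy, nr), shift_index(sx, nc)]
  best <- which(sub == max(sub), arr.ind = TRUE)
  # tie between equal peaks: smallest-magnitude shift
  if (nrow(best) > 1) {
    mag <- sy[best[, 1]]^2 + sx[best[, 2]]^2
    best <- best[order(mag, best[, 1], best[, 2])[1], , drop = FALSE]
  }
  dy <- sy[best[1, 1]]; dx <- sx[best[1, 2]]
  peak <- sub[best[1, 1], best[1, 2]]
  if (subpixel) {
    gy <- cc[shift_index(dy + (-1:1), nr), shift_index(dx, nc)]
    gx <- cc[shift_index(dy, nr), shift_index(dx + (-1:1), nc)]
    dy <- dy + parabolic_offset(gy)
    dx <- dx + parabolic_offset(gx)
  }
  structure(list(dx_px = dx, dy_px = dy,
                 dx_um = dx * pixel_size_um[1], dy_um = dy * pixel_size_um[2],
                 peak_corr = peak, source_plane = NA_integer_,
                 low_confidence = peak < corr_floor),
            class = "shift_xy")
}

parabolic_offset <- function(tri) {
  den <- tri[1] - 2 * tri[2] + tri[3]
  if (!is.finite(den) || den >= 0) return(0)
  off <- 0.5 * (tri[1] - tri[3]) / den
  max(min(off, 0.5), -0.5)
}

#' Best XY shift over a structural stack
#'
#' Cross-correlates the top plane of `stack` at each objective Z position
#' against the reference top plane, and returns the shift from the Z
#' position with the highest correlation peak (`source_plane` records that
#' Z index).
#'
#' @param stack A `structural_stack` acquired at the current position.
#' @param reference A `structural_stack` serving as the cross-day reference;
#'   its top plane at the Z = 0 grid point is the reference image.
#' @param ... Passed to [rigid_shift_xy()].
#' @return A `shift_xy` with `source_plane` set, plus attribute
#'   `per_z_corr`.
#' @export
best_xy_over_stack <- function(stack, reference, ...) {
  stopifnot(inherits(stack, "structural_stack"))
  nz <- length(stack$z_offsets_um)
  if (nz == 0) stop("empty stack")
  ref_top <- reference_top_plane(reference)
  shifts <- vector("list", nz)
  for (iz in seq_len(nz))
    shifts[[iz]] <- rigid_shift_xy(stack$images[, , iz, 1], ref_top,
                                   pixel_size_um = stack$pixel_size_um, ...)
  corrs <- vapply(shifts, `[[`, numeric(1), "peak_corr")
  best <- which.max(corrs)
  out <- shifts[[best]]
  out$source_plane <- best
  attr(out, "per_z_corr") <- corrs
  out
}

reference_top_plane <- function(reference) {
  if (inherits(reference, "structural_stack")) {
    iz0 <- which.min(abs(reference$z_offsets_um))
    reference$images[, , iz0, 1]
  } else if (is.matrix(reference)) reference
  else stop("reference must be a structural_stack or a matrix")
}

#' Fit a linear-offset Gaussian to an axial correlation profile
#'
#' Least-squares fit of `c(z) = a * exp(-(z - mu)^2 / (2 sigma^2)) + b` to
#' correlation values sampled along the objective Z grid. The center `mu`
#' is the axial shift estimate. Initialization: `b = min`, `a = max - min`,
#' `mu = z` at the maximum, `sigma` = twice the grid step; `sigma` is
#' bounded to `[step / 2, z-range]` and `mu` to the sampled range plus one
#' step.
#'
#' @param z Strictly monotone numeric vector of Z positions (micrometres).
#' @param corr Correlation values, same length (>= 4).
#' @return Object of class `z_fit`: `mu_um`, `sigma_um`, `amplitude`,
#'   `offset`, `rss`, `n_points`, `fitted`.
#' @export
fit_linear_offset_gaussian <- function(z, corr) {
  if (length(z) < 4L) stop("need at least 4 points for a 4-parameter fit")
  dz <- diff(z)
  if (!(all(dz > 0) || all(dz < 0))) stop("z must be strictly monotone")
  if (length(z) != length(corr)) stop("z and corr lengths differ")
  step <- min(abs(dz)); zrange <- diff(range(z))
  a0 <- max(corr) - min(corr)
  if (a0 <= 1e-12) stop("no axial peak: flat correlation profile")
  model <- function(p) p[1] * exp(-(z - p[3])^2 / (2 * p[4]^2)) + p[2]
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(a = a0, b = min(corr), mu = z[which.max(corr)], s = 2 * step),
      lower = c(1e-8, -2, min(z) - step, step / 2),
      upper = c(4, 2, max(z) + step, zrange),
      fn = function(p) corr - model(p),
      control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                           maxiter = 200)),
    error = function(e) stop("no axial peak: ", conditionMessage(e)))
  cf <- fit$par
  if (cf[["a"]] <= 1e-6) stop("no axial peak: vanishing amplitude")
  structure(list(mu_um = unname(cf[["mu"]]), sigma_um = unname(cf[["s"]]),
                 amplitude = unname(cf[["a"]]), offset = unname(cf[["b"]]),
                 rss = fit$deviance, n_points = length(z),
                 fitted = model(cf)),
            class = "z_fit")
}

#' Estimate the axial (Z) shift of a stack against a reference image
#'
#' Applies the XY shift to the stack's top-plane image at each Z position,
#' correlates each with the reference image, and fits a linear-offset
#' Gaussian to the correlation-versus-Z profile; the Gaussian center is the
#' axial shift estimate.
#'
#' @param stack A `structural_stack`.
#' @param reference_image Reference top-plane image (matrix), or a
#'   `structural_stack` from which it is taken at Z = 0.
#' @param xy_shift A `shift_xy` to apply to the stack images first (or NULL).
#' @return List: `dz_um`, `zfit` (a `z_fit`), and `corr_by_z`.
#' @export
estimate_z_shift <- function(stack, reference_image, xy_shift = NULL) {
  stopifnot(inherits(stack, "structural_stack"))
  ref <- reference_top_plane(reference_image)
  nz <- length(stack$z_offsets_um)
  corrs <- numeric(nz)
  for (iz in seq_len(nz)) {
    img <- stack$images[, , iz, 1]
    if (!is.null(xy_shift))
      img <- shift_image(img, dx = xy_shift$dx_px, dy = xy_shift$dy_px)
    corrs[iz] <- stats::cor(as.vector(img), as.vector(ref))
  }
  zf <- fit_linear_offset_gaussian(stack$z_offsets_um, corrs)
  if (zf$mu_um < min(stack$z_offsets_um) || zf$mu_um > max(stack$z_offsets_um))
    warning("axial estimate at the edge of the sampled Z range")
  list(dz_um = zf$mu_um, zfit = zf, corr_by_z = corrs)
}

#' Iterative closed-loop 3-D alignment
#'
#' Emulates the cross-day alignment loop: acquire a structural stack at the
#' current objective position, estimate the XY shift from the best plane,
#' estimate the Z shift from the Gaussian fit, move the objective by the
#' estimated residual, and repeat until every computed shift is smaller
#' than `tol_um` (default 5 micrometres) or `max_iter` is reached.
#'
#' @param acquire Function of one argument `position_um = c(x, y, z)`
#'   returning a `structural_stack` acquired with the objective moved by
#'   that amount (in tests, a simulator-backed closure).
#' @param reference Reference `structural_stack`.
#' @param max_iter Maximum iterations.
#' @param tol_um Convergence threshold on each axis (micrometres).
#' @param ... Passed to [rigid_shift_xy()] via [best_xy_over_stack()].
#' @return Object of class `alignment_result`: `iterations` (data frame of
#'   per-iteration `dx_um, dy_um, dz_um, peak_corr`), `zfits`, `converged`,
#'   `n_iter`, and `total_shift_um` (the accumulated objective correction,
#'   which estimates the field drift).
#' @export
align_iterative <- function(acquire, reference, max_iter = 10L, tol_um = 5,
                            ...) {
  ref_top <- reference_top_plane(reference)
  pos <- c(0, 0, 0)
  iters <- list(); zfits <- list()
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    stack <- acquire(pos)
    sxy <- best_xy_over_stack(stack, reference, ...)
    step_xy <- c(-sxy$dx_um, -sxy$dy_um)  # estimated residual field shift
    ez <- tryCatch(estimate_z_shift(stack, ref_top, sxy), error = function(e) NULL)
    step_z <- if (is.null(ez)) 0 else ez$dz_um
    iters[[it]] <- data.frame(iter = it, dx_um = step_xy[1], dy_um = step_xy[2],
                              dz_um = step_z, peak_corr = sxy$peak_corr,
                              source_plane = sxy$source_plane)
    zfits[[it]] <- if (is.null(ez)) NULL else ez$zfit
    pos <- pos + c(step_xy, step_z)
    if (all(abs(c(step_xy, step_z)) < tol_um)) {
      converged <- TRUE
      break
    }
  }
  structure(list(iterations = do.call(rbind, iters), zfits = zfits,
                 converged = converged, n_iter = length(iters),
                 total_shift_um = pos),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %s in %d iteration(s); total shift (%.2f, %.2f, %.2f) um\n",
              if (x$converged) "converged" else "NOT converged", x$n_iter,
              x$total_shift_um[1], x$total_shift_um[2], x$total_shift_um[3]))
  invisible(x)
}

#' Piecewise-rigid mapping between two images
#'
#' Splits the image into a grid of patches, estimates a rigid shift per
#' patch by windowed cross-correlation (after an optional initial shift),
#' and returns a shift field that interpolates bilinearly between patch
#' centers. A 1 x 1 grid reduces exactly to [rigid_shift_xy()]. Used to map
#' cell masks between recordings on different days.
#'
#' @param image,reference Equal-sized matrices (brightness-corrected mean
#'   projections in the cross-day use case).
#' @param patch_grid Grid `c(rows, cols)` of patches.
#' @param init_shift Initial shift `c(dx, dy)` in pixels applied to `image`
#'   before patchwise estimation (stands in for a manual pre-shift).
#' @param max_shift_px Patchwise search half-window (pixels).
#' @param min_patch_px Minimum allowed patch side (pixels).
#' @param subpixel Sub-pixel refinement per patch.
#' @return Object of class `shift_field`: patch grid, patch centers, per
#'   patch `dx_px` / `dy_px` matrices (including `init_shift`), the image
#'   dimensions, and `init_shift`.
#' @export
piecewise_rigid_map <- function(image, reference, patch_grid = c(4, 4),
                                init_shift = c(0, 0), max_shift_px = 20L,
                                min_patch_px = 16L, subpixel = TRUE) {
  stopifnot(all(dim(image) == dim(reference)))
  nr <- nrow(image); nc <- ncol(image)
  gr <- patch_grid[1]; gc <- patch_grid[2]
  if (floor(nr / gr) < min_patch_px || floor(nc / gc) < min_patch_px)
    stop("patch smaller than minimum of ", min_patch_px, " px")
  if (any(init_shift != 0))
    image <- shift_image(image, dx = init_shift[1], dy = init_shift[2])
  row_edges <- round(seq(0, nr, length.out = gr + 1))
  col_edges <- round(seq(0, nc, length.out = gc + 1))
  dx <- matrix(0, gr, gc); dy <- matrix(0, gr, gc)
  cy <- matrix(0, gr, gc); cx <- matrix(0, gr, gc)
  for (i in seq_len(gr)) {
    for (j in seq_len(gc)) {
      rows <- (row_edges[i] + 1):row_edges[i + 1]
      cols <- (col_edges[j] + 1):col_edges[j + 1]
      cy[i, j] <- mean(range(rows)); cx[i, j] <- mean(range(cols))
      s <- tryCatch(
        rigid_shift_xy(image[rows, cols], reference[rows, cols],
                       max_shift_px = min(max_shift_px,
                                          floor(min(length(rows), length(cols)) / 2) - 1L),
                       subpixel = subpixel),
        error = function(e) NULL)  # flat patch: keep zero residual shift
      if (!is.null(s)) { dx[i, j] <- s$dx_px; dy[i, j] <- s$dy_px }
    }
  }
  structure(list(patch_grid = c(gr, gc),
                 center_row = cy, center_col = cx,
                 dx_px = dx + init_shift[1], dy_px = dy + init_shift[2],
                 dim = c(nr, nc), init_shift = init_shift),
            class = "shift_field")
}

# Dense per-pixel shift components from a shift_field by bilinear
# interpolation between patch centers (constant beyond the outer centers).
dense_shift_field <- function(field, rows = NULL, cols = NULL) {
  nr <- field$dim[1]; nc <- field$dim[2]
  if (is.null(rows)) rows <- seq_len(nr)
  if (is.null(cols)) cols <- seq_len(nc)
  gy <- field$center_row[, 1]; gx <- field$center_col[1, ]
  interp_axis <- function(pos, grid) {
    if (length(grid) == 1L) return(list(i0 = rep(1L, length(pos)),
                                        i1 = rep(1L, length(pos)),
                                        w = rep(0, length(pos))))
    i1 <- findInterval(pos, grid, all.inside = TRUE)
    i2 <- i1 + 1L
    w <- (pos - grid[i1]) / (grid[i2] - grid[i1])
    w <- pmin(pmax(w, 0), 1)
    list(i0 = i1, i1 = i2, w = w)
  }
  ay <- interp_axis(rows, gy)
  ax <- interp_axis(cols, gx)
  interp2 <- function(m) {
    m00 <- m[cbind(rep(ay$i0, length(cols)), rep(ax$i0, each = length(rows)))]
    m10 <- m[cbind(rep(ay$i1, length(cols)), rep(ax$i0, each = length(rows)))]
    m01 <- m[cbind(rep(ay$i0, length(cols)), rep(ax$i1, each = length(rows)))]
    m11 <- m[cbind(rep(ay$i1, length(cols)), rep(ax$i1, each = length(rows)))]
    wy <- rep(ay$w, length(cols)); wx <- rep(ax$w, each = length(rows))
    matrix((1 - wy) * (1 - wx) * m00 + wy * (1 - wx) * m10 +
             (1 - wy) * wx * m01 + wy * wx * m11,
           length(rows), length(cols))
  }
  list(dx = interp2(field$dx_px), dy = interp2(field$dy_px))
}

#' Apply a shift field to an image or to cell masks
#'
#' Images are warped by bilinear interpolation (inverse mapping); binary
#' cell masks are mapped forward pixel-by-pixel with nearest-neighbor
#' rounding so they stay binary. A mask warped entirely outside the frame
#' comes back empty with attribute `empty = TRUE` and a warning.
#'
#' @param x A numeric matrix, a `cell_mask`, or a list of `cell_mask`s.
#' @param field A `shift_field`.
#' @return The warped image or mask(s).
#' @export
apply_shift_field <- function(x, field) {
  stopifnot(inherits(field, "shift_field"))
  if (is.matrix(x) && !inherits(x, "cell_mask")) {
    nr <- nrow(x); nc <- ncol(x)
    d <- dense_shift_field(field)
    rr <- matrix(seq_len(nr), nr, nc) - d$dy
    cc <- matrix(rep(seq_len(nc), each = nr), nr, nc) - d$dx
    out <- matrix(bilinear_sample(x, as.vector(rr), as.vector(cc)), nr, nc)
    out[is.na(out)] <- 0
    return(out)
  }
  if (inherits(x, "cell_mask")) return(warp_mask(x, field))
  if (is.list(x)) return(lapply(x, warp_mask, field = field))
  stop("cannot apply a shift field to ", class(x)[1])
}

warp_mask <- function(mask, field) {
  stopifnot(inherits(mask, "cell_mask"))
  px <- mask$pixels
  d <- dense_shift_field(field)
  idx <- cbind(px[, 1], px[, 2])
  nr <- round(px[, 1] + d$dy[idx])
  nc <- round(px[, 2] + d$dx[idx])
  keep <- nr >= 1 & nc >= 1 & nr <= field$dim[1] & nc <= field$dim[2]
  pts <- unique(cbind(nr[keep], nc[keep]))
  clipped <- sum(keep) < nrow(px)
  if (nrow(pts) == 0) {
    warning("mask warped entirely outside the frame")
    out <- cell_mask(matrix(integer(0), ncol = 2), plane_index = mask$plane_index,
                     check = FALSE)
    attr(out, "empty") <- TRUE
    return(out)
  }
  out <- cell_mask(pts, plane_index = mask$plane_index, check = FALSE)
  attr(out, "clipped") <- clipped
  out
}

#' Construct a rigid (1 x 1) shift field
#'
#' Convenience constructor for a spatially constant shift field, e.g. from
#' a known stage displacement or a manual alignment, usable everywhere a
#' [piecewise_rigid_map()] result is.
#'
#' @param dx_px,dy_px Constant shift in pixels.
#' @param dim Image dimensions `c(rows, cols)` the field covers.
#' @return A `shift_field` with a single patch.
#' @export
rigid_shift_field <- function(dx_px, dy_px, dim) {
  structure(list(patch_grid = c(1L, 1L),
                 center_row = matrix((dim[1] + 1) / 2, 1, 1),
                 center_col = matrix((dim[2] + 1) / 2, 1, 1),
                 dx_px = matrix(dx_px, 1, 1),
                 dy_px = matrix(dy_px, 1, 1),
                 dim = dim, init_shift = c(0, 0)),
            class = "shift_field")
}
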