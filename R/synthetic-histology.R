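#' Construct histology ground truth
#'
#' Ground truth for a synthetic immunostained section: a number of labelled
#' cells of given areas placed inside a region-of-interest polygon.
#'
#' @param true_count Number of labelled cells (>= 0).
#' @param roi_polygon Two-column matrix of polygon vertices `(x, y)` in
#'   pixels. Default: a rectangle inset from a 256 x 256 image.
#' @param per_cell_area_px2 Cell areas in square pixels (recycled).
#' @param seed Integer seed (placement is drawn when rendering).
#' @return Object of class `histology_truth`.
#' @export
histology_truth <- function(true_count,
                            roi_polygon = cbind(c(20, 236, 236, 20),
                                                c(20, 20, 236, 236)),
                            per_cell_area_px2 = 20,
                            seed = 1L) {
  stopifnot(true_count >= 0, ncol(roi_polygon) == 2, nrow(roi_polygon) >= 3)
  structure(list(
    true_count = as.integer(true_count),
    roi_polygon = roi_polygon,
    per_cell_area_px2 = rep_len(per_cell_area_px2, max(true_count, 1L)),
    seed = as.integer(seed)
  ), class = "histology_truth")
}

# Even-odd ray-casting point-in-polygon test.
point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi + .Machine$double.eps) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Render a synthetic histology image
#'
#' Draws each true cell as a bright disk of the requested area at a random
#' non-touching location inside the ROI polygon, over a dim background with
#' gamma-distributed (shot-like) and Gaussian noise. Suitable as a fixture
#' for threshold / watershed / particle-counting pipelines.
#'
#' @param truth A `histology_truth`.
#' @param image_dim Image size `c(rows, cols)` in pixels.
#' @param cell_intensity,background_intensity Mean intensities (arbitrary
#'   units in \[0, 1\]).
#' @param noise_sd Gaussian noise SD; `shot_scale` scales the gamma noise
#'   (shape 2); set both to 0 for a noiseless image.
#' @param shot_scale Scale of the gamma-distributed noise component.
#' @param min_gap_px Minimum gap between cell borders (pixels).
#' @param seed Optional override of `truth$seed`.
#' @return List of class `histology_image`: `image` (matrix in \[0, 1\]),
#'   `centers` (x, y), `radii_px`, and the `truth`.
#' @export
render_histology <- function(truth, image_dim = c(256, 256),
                             cell_intensity = 0.8,
                             background_intensity = 0.12,
                             noise_sd = 0.02, shot_scale = 0.015,
                             min_gap_px = 3, seed = NULL) {
  stopifnot(inherits(truth, "histology_truth"), all(image_dim > 0))
  seed <- if (is.null(seed)) truth$seed else seed
  with_seed(seed, {
    H <- image_dim[1]; W <- image_dim[2]
    n <- truth$true_count
    radii <- sqrt(truth$per_cell_area_px2 / pi)
    centers <- matrix(numeric(0), ncol = 2)
    if (n > 0) {
      for (i in seq_len(n)) {
        r <- radii[min(i, length(radii))]
        ok <- FALSE
        for (try in 1:2000) {
          cand <- c(runif(1, 1 + r, W - r), runif(1, 1 + r, H - r))
          if (!point_in_polygon(cand[1], cand[2], truth$roi_polygon)) next
          if (nrow(centers) > 0) {
            gaps <- sqrt(colSums((t(centers) - cand)^2)) -
              (radii[pmin(seq_len(nrow(centers)), length(radii))] + r)
            if (min(gaps) < min_gap_px) next
          }
          centers <- rbind(centers, cand)
          ok <- TRUE
          break
        }
        if (!ok) stop("could not place ", n, " non-touching cells in ROI")
      }
    }
    img <- matrix(background_intensity, H, W)
    for (i in seq_len(n)) {
      r <- radii[min(i, length(radii))]
      cx <- centers[i, 1]; cy <- centers[i, 2]
      rows <- max(1, floor(cy - r - 1)):min(H, ceiling(cy + r + 1))
      cols <- max(1, floor(cx - r - 1)):min(W, ceiling(cx + r + 1))
      d2 <- outer((rows - cy)^2, (cols - cx)^2, "+")
      img[rows, cols][d2 <= r^2] <- cell_intensity
    }
    if (shot_scale > 0)
      img <- img + matrix(rgamma(H * W, shape = 2, scale = shot_scale), H, W)
    if (noise_sd > 0)
      img <- img + matrix(rnorm(H * W, 0, noise_sd), H, W)
    img <- pmin(pmax(img, 0), 1)
    structure(list(image = img,
                   centers = centers,
                   radii_px = radii[pmin(seq_len(max(n, 0)), length(radii))],
                   truth = truth),
              class = "histology_image")
  })
}
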