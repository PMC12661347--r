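#' Intensity profile along a fixed-length line
#'
#' Samples an image at unit-pixel spacing along a straight line (the
#' fixed-length line placed over the AAV-expressing region in each coronal
#' section), using bilinear interpolation.
#'
#' @param image Numeric matrix.
#' @param start_px Start point `c(x, y)` in pixels (x = column, y = row).
#' @param angle_deg Line direction in degrees (0 = +x, counterclockwise).
#' @param length_px Number of samples (> 0) at unit spacing.
#' @return Object of class `line_profile`: data frame with `position_px`
#'   and `intensity`.
#' @export
line_profile <- function(image, start_px, angle_deg, length_px) {
  stopifnot(is.matrix(image))
  if (length_px <= 0) stop("length_px must be positive")
  t <- seq_len(length_px) - 1
  x <- start_px[1] + t * cos(angle_deg * pi / 180)
  y <- start_px[2] + t * sin(angle_deg * pi / 180)
  v <- bilinear_sample(image, r = y, c = x)
  if (anyNA(v)) stop("line exits the image")
  structure(data.frame(position_px = t, intensity = v),
            class = c("line_profile", "data.frame"))
}

#' Count labelled cells by threshold / watershed particle analysis
#'
#' Binarizes the section at a threshold (Otsu's method by default, standing
#' in for manual thresholding), splits touching cells with a watershed on
#' the distance transform, discards particles below the minimum area, and
#' counts the rest. Minimum sizes of 5 and 10 square pixels are the
#' conventional choices for Iba1 and GFAP staining respectively.
#'
#' @param image Numeric matrix (bright cells on dark background).
#' @param threshold Intensity threshold; `NULL` for automatic (Otsu).
#' @param min_size_px2 Minimum particle area kept (area >= min kept).
#' @param watershed_tolerance Minimum object-height tolerance of the
#'   watershed on the distance transform.
#' @param watershed_ext Neighborhood radius for watershed peak detection
#'   (pixels).
#' @return Object of class `particle_result`: `count`, `labels` (label
#'   matrix), `per_particle_area_px2`, `threshold_used`, `min_size_px2`.
#' @export
count_particles <- function(image, threshold = NULL, min_size_px2 = 5,
                            watershed_tolerance = 0.5, watershed_ext = 2) {
  stopifnot(is.matrix(image))
  rng <- range(image)
  if (is.null(threshold)) {
    if (diff(rng) == 0) {
      threshold <- rng[1] + 1  # blank image: nothing above threshold
    } else {
      norm <- (image - rng[1]) / diff(rng)
      threshold <- rng[1] + EBImage::otsu(EBImage::Image(norm)) * diff(rng)
    }
  }
  bw <- matrix(as.numeric(image >= threshold), nrow(image), ncol(image))
  if (sum(bw) == 0)
    return(structure(list(count = 0L, labels = bw,
                          per_particle_area_px2 = numeric(0),
                          threshold_used = threshold,
                          min_size_px2 = min_size_px2),
                     class = "particle_result"))
  dm <- EBImage::distmap(bw)
  lab <- as_plain_matrix(EBImage::watershed(dm, tolerance = watershed_tolerance,
                                            ext = watershed_ext))
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(sizes >= min_size_px2)
  out <- matrix(0L, nrow(lab), ncol(lab))
  areas <- numeric(0)
  for (new_id in seq_along(keep)) {
    out[lab == keep[new_id]] <- new_id
    areas <- c(areas, sizes[keep[new_id]])
  }
  structure(list(count = length(keep), labels = out,
                 per_particle_area_px2 = areas,
                 threshold_used = threshold,
                 min_size_px2 = min_size_px2),
            class = "particle_result")
}

#' Glial expression index
#'
#' Positive-cell count in a region of interest divided by the ROI area,
#' scaled by 10,000.
#'
#' @param count Number of positive cells (>= 0).
#' @param area_px2 ROI area in square pixels (> 0).
#' @return `count / area_px2 * 10000`.
#' @export
expression_index <- function(count, area_px2) {
  if (any(area_px2 <= 0)) stop("area must be positive")
  if (any(count < 0)) stop("count must be nonnegative")
  count / area_px2 * 10000
}

#' Polygon area in square pixels (shoelace formula)
#'
#' @param roi_polygon Two-column matrix of vertices `(x, y)`.
#' @return Area in px^2.
#' @export
roi_area_px2 <- function(roi_polygon) {
  x <- roi_polygon[, 1]; y <- roi_polygon[, 2]
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Per-animal average over sections
#'
#' Arithmetic mean of per-section measurements (intensity or expression
#' index); conventionally four coronal sections per animal.
#'
#' @param values Numeric vector, one value per section (nonempty).
#' @return List with `mean` and `n_sections`.
#' @export
animal_average <- function(values) {
  if (length(values) == 0) stop("no sections")
  list(mean = mean(values), n_sections = length(values))
}

#' Pairwise co-expression correlation across cells
#'
#' Z-scores each channel's per-cell intensity across cells and returns the
#' Pearson correlation matrix between channels (symmetric, unit diagonal).
#'
#' @param per_cell_intensities Matrix `[cells, channels]` with at least 3
#'   cells and 2 channels.
#' @return Channel x channel correlation matrix.
#' @export
coexpression_correlation <- function(per_cell_intensities) {
  m <- as.matrix(per_cell_intensities)
  if (nrow(m) < 3) stop("need at least 3 cells")
  if (ncol(m) < 2) stop("need at least 2 channels")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) stop("zero-variance channel")
  z <- scale(m)
  r <- cor(z)
  dimnames(r) <- list(colnames(m), colnames(m))
  r
}
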