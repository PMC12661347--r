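#' Generate a ground-truthed imaging field
#'
#' Places cells uniformly at random in a multi-plane field of view with a
#' minimum pairwise centroid separation, mimicking a sparsely labelled
#' cortical volume imaged through an electrically tunable lens that cycles
#' between equally spaced planes. Each cell carries a functional
#' (calcium-indicator) brightness and, for a configurable fraction of cells,
#' a structural (nuclear marker) brightness used for cross-day registration.
#'
#' @param n_cells Number of cells to place (0 gives an empty field).
#' @param fov_um Field of view extent, `c(x, y)` in micrometres.
#' @param n_planes Number of imaging planes cycled per volume.
#' @param plane_spacing_um Axial spacing between planes (micrometres).
#' @param pixel_size_um Pixel size, `c(x, y)` micrometres per pixel.
#' @param min_sep_um Minimum pairwise centroid separation (micrometres,
#'   within-plane 3-D distance).
#' @param radius_um_range Range of cell radii (micrometres).
#' @param brightness_range Range of functional-channel peak brightness
#'   (arbitrary units).
#' @param frac_structural Fraction of functional cells that also express the
#'   nuclear structural marker.
#' @param n_nuclei Number of structural-only nuclei (no calcium indicator),
#'   scattered continuously across the imaged depth range so that the
#'   structural image content turns over with axial position — the property
#'   the axial-alignment correlation profile relies on. Defaults to
#'   `n_cells`.
#' @param nucleus_radius_um_range Radius range of the structural nuclei
#'   (micrometres; nuclei are smaller than somata).
#' @param nucleus_z_margin_um Axial extent of the nuclei population beyond
#'   the outermost imaging planes. Tissue is continuous in depth, so nuclei
#'   must exist above and below the probed range for the axial correlation
#'   profile to fall off symmetrically.
#' @param z_jitter_um Axial scatter of somata about their plane (micrometres).
#' @param max_tries Rejection-sampling attempts per cell before the density
#'   is declared infeasible.
#' @param seed Integer seed; the field is a pure function of the arguments.
#'
#' @return An object of class `field_truth`: a list with `cells` (data frame
#'   of per-cell ground truth), `fov_um`, `n_planes`, `plane_spacing_um`,
#'   `pixel_size_um`, `dim_px` (rows, cols) and `seed`.
#' @export
generate_field <- function(n_cells,
                           fov_um = c(120, 120),
                           n_planes = 3L,
                           plane_spacing_um = 30,
                           pixel_size_um = c(1.25, 1.25),
                           min_sep_um = 12,
                           radius_um_range = c(3, 5),
                           brightness_range = c(80, 200),
                           frac_structural = 0.3,
                           n_nuclei = n_cells,
                           nucleus_radius_um_range = c(2, 3),
                           nucleus_z_margin_um = 40,
                           z_jitter_um = 3,
                           max_tries = 200L,
                           seed = 1L) {
  stopifnot(n_cells >= 0, n_nuclei >= 0, all(fov_um > 0), n_planes >= 1L,
            plane_spacing_um > 0, all(pixel_size_um > 0), min_sep_um >= 0)
  z_span <- c(-nucleus_z_margin_um,
              (n_planes - 1L) * plane_spacing_um + nucleus_z_margin_um)
  cells <- with_seed(seed, {
    placed <- matrix(numeric(0), ncol = 3)
    n_total <- n_cells + n_nuclei
    is_nucleus <- rep(c(FALSE, TRUE), c(n_cells, n_nuclei))
    if (n_total > 0) {
      margin <- max(radius_um_range)
      for (i in seq_len(n_total)) {
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          z <- if (is_nucleus[i]) runif(1, z_span[1], z_span[2])
          else (sample.int(n_planes, 1L) - 1L) * plane_spacing_um +
            runif(1, -z_jitter_um, z_jitter_um)
          cand <- c(runif(1, margin, fov_um[1] - margin),
                    runif(1, margin, fov_um[2] - margin), z)
          if (nrow(placed) == 0 ||
              min(sqrt(colSums((t(placed) - cand)^2))) >= min_sep_um) {
            placed <- rbind(placed, cand)
            ok <- TRUE
            break
          }
        }
        if (!ok)
          stop("cell density infeasible at min_sep_um = ", min_sep_um,
               " after ", max_tries, " attempts")
      }
    }
    n <- nrow(placed)
    radius <- ifelse(is_nucleus,
                     runif(n, nucleus_radius_um_range[1], nucleus_radius_um_range[2]),
                     runif(n, radius_um_range[1], radius_um_range[2]))
    bright <- runif(n, brightness_range[1], brightness_range[2])
    data.frame(
      cell_id = seq_len(n),
      x_um = if (n) placed[, 1] else numeric(0),
      y_um = if (n) placed[, 2] else numeric(0),
      z_um = if (n) placed[, 3] else numeric(0),
      radius_um = radius,
      brightness_functional = ifelse(is_nucleus, 0, bright),
      brightness_structural = ifelse(
        is_nucleus | runif(n) < frac_structural,
        runif(n, brightness_range[1], brightness_range[2]), 0),
      is_nucleus = is_nucleus,
      row.names = NULL
    )
  })
  cells$plane_index <- if (nrow(cells))
    pmin(pmax(round(cells$z_um / plane_spacing_um), 0), n_planes - 1L) + 1L
  else integer(0)
  structure(list(
    cells = cells,
    fov_um = fov_um,
    n_planes = as.integer(n_planes),
    plane_spacing_um = plane_spacing_um,
    pixel_size_um = pixel_size_um,
    dim_px = c(round(fov_um[2] / pixel_size_um[2]),
               round(fov_um[1] / pixel_size_um[1])),
    seed = as.integer(seed)
  ), class = "field_truth")
}

#' @export
print.field_truth <- function(x, ...) {
  cat(sprintf("<field_truth> %d cells, %d plane(s) @ %g um, FOV %g x %g um (%d x %d px)\n",
              nrow(x$cells), x$n_planes, x$plane_spacing_um,
              x$fov_um[1], x$fov_um[2], x$dim_px[1], x$dim_px[2]))
  invisible(x)
}

# Render the footprint of every cell visible in one plane at an axial
# objective offset, as a (pixels x cells) sparse-in-effect dense matrix plus
# the per-cell defocus attenuation. Footprints are isotropic 2-D Gaussians
# truncated at 2.5 sigma; axial defocus inflates sigma and attenuates
# brightness as exp(-(dz/sigma_z)^2). `shift_um` displaces the field (the
# cells) in all three axes; `z_offset_um` displaces the imaged plane (the
# objective).
field_footprints <- function(field, plane = 1L, z_offset_um = 0,
                             shift_um = c(0, 0, 0), sigma_z_um = 12,
                             channel = c("functional", "structural")) {
  channel <- match.arg(channel)
  if (length(shift_um) == 2L) shift_um <- c(shift_um, 0)
  H <- field$dim_px[1]; W <- field$dim_px[2]
  psx <- field$pixel_size_um[1]; psy <- field$pixel_size_um[2]
  plane_z <- (plane - 1L) * field$plane_spacing_um + z_offset_um
  cells <- field$cells
  bright <- if (channel == "functional") cells$brightness_functional
            else cells$brightness_structural
  A <- matrix(0, H * W, nrow(cells))
  atten <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    if (bright[i] <= 0) next
    dz <- cells$z_um[i] + shift_um[3] - plane_z
    att <- exp(-(dz / sigma_z_um)^2)
    if (att < 1e-4) next
    sigma_um <- cells$radius_um[i] / 2
    sigma_px <- sigma_um * sqrt(1 + (dz / sigma_z_um)^2) / psx
    cx <- (cells$x_um[i] + shift_um[1]) / psx + 0.5
    cy <- (cells$y_um[i] + shift_um[2]) / psy + 0.5
    rad <- ceiling(2.5 * sigma_px)
    if (cy + rad < 1 || cy - rad > H || cx + rad < 1 || cx - rad > W) next
    rows <- max(1L, floor(cy - rad)):min(H, ceiling(cy + rad))
    cols <- max(1L, floor(cx - rad)):min(W, ceiling(cx + rad))
    d2 <- outer((rows - cy)^2, (cols - cx)^2, "+")
    w <- exp(-d2 / (2 * sigma_px^2))
    w[d2 > (2.5 * sigma_px)^2] <- 0
    idx <- as.vector(outer(rows, (cols - 1L) * H, "+"))
    A[idx, i] <- A[idx, i] + att * as.vector(w)
    atten[i] <- att
  }
  list(A = A, attenuation = atten, dim = c(H, W))
}

#' Perturb a field to emulate session-to-session cell turnover
#'
#' Keeps a random subset of the field's functional cells and replaces the
#' rest with newly placed cells (respecting the minimum separation),
#' emulating cells lost and gained between imaging sessions weeks apart.
#' Nuclei are kept unchanged. The returned field records the
#' correspondence between persistent cells.
#'
#' @param field A `field_truth`.
#' @param turnover_frac Fraction of functional cells replaced.
#' @param min_sep_um Minimum centroid separation for replacements (defaults
#'   to 12 um, matching [generate_field()]).
#' @param max_tries Placement attempts per replacement cell.
#' @param seed Integer seed.
#' @return A `field_truth` with an added `correspondence` element: a data
#'   frame with `id_a` (row index in the original field's functional cells)
#'   and `id_b` (row index in the new field) for persistent cells.
#' @export
perturb_field <- function(field, turnover_frac = 0.2, min_sep_um = 12,
                          max_tries = 2000L, seed = 1L) {
  stopifnot(inherits(field, "field_truth"),
            turnover_frac >= 0, turnover_frac <= 1)
  cells <- field$cells
  fun_idx <- which(!cells$is_nucleus)
  n_rep <- round(length(fun_idx) * turnover_frac)
  out <- with_seed(seed, {
    replaced <- if (n_rep > 0) sort(sample(fun_idx, n_rep)) else integer(0)
    new_cells <- cells
    margin <- max(cells$radius_um[fun_idx], 5)
    for (i in replaced) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        # keep clear of both the new layout and every original position, so
        # a gained cell never sits where a lost cell used to be
        keep_xyz <- rbind(as.matrix(new_cells[-i, c("x_um", "y_um", "z_um")]),
                          as.matrix(cells[, c("x_um", "y_um", "z_um")]))
        cand <- c(runif(1, margin, field$fov_um[1] - margin),
                  runif(1, margin, field$fov_um[2] - margin),
                  cells$z_um[i])
        if (min(sqrt(rowSums(sweep(keep_xyz, 2, cand)^2))) >= min_sep_um) {
          new_cells$x_um[i] <- cand[1]
          new_cells$y_um[i] <- cand[2]
          new_cells$brightness_functional[i] <-
            runif(1, min(cells$brightness_functional[fun_idx]),
                  max(cells$brightness_functional[fun_idx]))
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place replacement cell")
    }
    list(cells = new_cells, replaced = replaced)
  })
  persistent <- setdiff(fun_idx, out$replaced)
  new_field <- field
  new_field$cells <- out$cells
  new_field$correspondence <- data.frame(
    id_a = match(persistent, fun_idx),
    id_b = match(persistent, fun_idx))
  new_field$replaced <- out$replaced
  new_field
}

#' Ground-truth cell masks from a field's footprints
#'
#' Thresholds each functional cell's rendered footprint at a fraction of
#' its peak to produce the reference `cell_mask` set for a plane, e.g. to
#' validate detection or to drive cross-session matching with known
#' correspondence.
#'
#' @param field A `field_truth`.
#' @param plane Imaging plane.
#' @param shift_um Rigid field displacement applied before rendering.
#' @param threshold Fraction of each cell's footprint peak kept.
#' @return Named list of `cell_mask`s (names = functional-cell row index);
#'   cells without support in the plane are omitted.
#' @export
true_masks <- function(field, plane = 1L, shift_um = c(0, 0, 0),
                       threshold = 0.3) {
  fp <- field_footprints(field, plane = plane, shift_um = shift_um,
                         channel = "functional")
  fun_idx <- which(!field$cells$is_nucleus)
  H <- fp$dim[1]
  masks <- list()
  for (k in seq_along(fun_idx)) {
    i <- fun_idx[k]
    col_i <- fp$A[, i]
    # only cells actually in focus in this plane, not defocused bleed-through
    if (max(col_i) <= 0 || fp$attenuation[i] < 0.5) next
    sel <- which(col_i >= threshold * max(col_i))
    px <- cbind((sel - 1L) %% H + 1L, (sel - 1L) %/% H + 1L)
    lab <- as_plain_matrix(EBImage::bwlabel(mask_to_matrix(
      list(pixels = px), c(fp$dim[1], fp$dim[2]))))
    main <- which.max(tabulate(lab[lab > 0]))
    px <- which(lab == main, arr.ind = TRUE)
    masks[[as.character(k)]] <- cell_mask(px, plane_index = plane,
                                          check = FALSE)
  }
  masks
}
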