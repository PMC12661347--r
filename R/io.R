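#' Write an imaging session as a plane-interleaved multi-page TIFF
#'
#' Pages cycle through planes within each volume (frame 1 plane 1, frame 1
#' plane 2, ...), matching an ETL acquisition that switches planes every
#' frame. Pixel values are stored as 32-bit float after division by a
#' global scale recorded in a JSON sidecar (`<path>.json`) together with
#' the geometry, rate, and page order.
#'
#' @param session An `imaging_session`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_session_tiff <- function(session, path) {
  stopifnot(inherits(session, "imaging_session"))
  d <- dim(session$movie)
  offset <- min(session$movie, 0)
  scale <- max(session$movie - offset, 1e-12)
  pages <- vector("list", d[3] * d[4])
  k <- 1L
  for (f in seq_len(d[4])) for (p in seq_len(d[3])) {
    pages[[k]] <- (session$movie[, , p, f] - offset) / scale
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(kind = "imaging_session", scale = scale, offset = offset,
               dim = d, page_order = "plane-interleaved (plane fastest)",
               frame_rate_hz = session$frame_rate_hz,
               plane_spacing_um = session$plane_spacing_um,
               pixel_size_um = session$pixel_size_um,
               n_planes = session$n_planes,
               channels = session$channels)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an imaging session written by [write_session_tiff()]
#'
#' @param path TIFF path (the `<path>.json` sidecar must be present).
#' @return An `imaging_session` (without ground truth).
#' @export
read_session_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- meta$dim
  movie <- array(0, d)
  k <- 1L
  for (f in seq_len(d[4])) for (p in seq_len(d[3])) {
    movie[, , p, f] <- pages[[k]] * meta$scale + meta$offset
    k <- k + 1L
  }
  structure(list(movie = movie, frame_rate_hz = meta$frame_rate_hz,
                 plane_spacing_um = meta$plane_spacing_um,
                 pixel_size_um = meta$pixel_size_um,
                 n_planes = meta$n_planes, channels = meta$channels,
                 truth = NULL),
            class = "imaging_session")
}

#' Write a structural stack as a multi-page TIFF (Z-major page order)
#'
#' @param stack A `structural_stack`.
#' @param path Output TIFF path; a JSON sidecar records scale and grid.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "structural_stack"))
  d <- dim(stack$images)
  offset <- min(stack$images, 0)
  scale <- max(stack$images - offset, 1e-12)
  pages <- vector("list", d[3] * d[4])
  k <- 1L
  for (iz in seq_len(d[3])) for (p in seq_len(d[4])) {
    pages[[k]] <- (stack$images[, , iz, p] - offset) / scale
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(kind = "structural_stack", scale = scale, offset = offset,
               dim = d,
               page_order = "z-major (plane fastest)",
               z_offsets_um = stack$z_offsets_um,
               pixel_size_um = stack$pixel_size_um,
               plane_spacing_um = stack$plane_spacing_um,
               n_planes = stack$n_planes)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a structural stack written by [write_stack_tiff()]
#'
#' @param path TIFF path with JSON sidecar.
#' @return A `structural_stack`.
#' @export
read_stack_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- meta$dim
  images <- array(0, d)
  k <- 1L
  for (iz in seq_len(d[3])) for (p in seq_len(d[4])) {
    images[, , iz, p] <- pages[[k]] * meta$scale + meta$offset
    k <- k + 1L
  }
  structure(list(images = images, z_offsets_um = meta$z_offsets_um,
                 pixel_size_um = meta$pixel_size_um,
                 plane_spacing_um = meta$plane_spacing_um,
                 n_planes = meta$n_planes),
            class = "structural_stack")
}

#' Write a behavior log as CSV tables
#'
#' One row per trial in `<stem>_trials.csv`, plus a per-frame velocity
#' table in `<stem>_velocity.csv`.
#'
#' @param log A `behavior_log`.
#' @param stem Output path stem.
#' @return The two file paths, invisibly.
#' @export
write_behavior_csv <- function(log, stem) {
  stopifnot(inherits(log, "behavior_log"))
  p1 <- paste0(stem, "_trials.csv")
  p2 <- paste0(stem, "_velocity.csv")
  write.csv(log$trials, p1, row.names = FALSE)
  write.csv(log$velocity, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Read a behavior log written by [write_behavior_csv()]
#'
#' @param stem Path stem used at write time.
#' @param frame_rate_hz Velocity-frame rate to record in the log.
#' @return A `behavior_log` (without task parameters).
#' @export
read_behavior_csv <- function(stem, frame_rate_hz = 10.4) {
  trials <- read.csv(paste0(stem, "_trials.csv"), stringsAsFactors = FALSE)
  velocity <- read.csv(paste0(stem, "_velocity.csv"))
  structure(list(trials = trials, velocity = velocity,
                 frame_rate_hz = frame_rate_hz, task = NULL, seed = NA_integer_),
            class = "behavior_log")
}

#' Serialize an alignment result to JSON
#'
#' Per-iteration shifts, Gaussian-fit parameters, and the convergence flag.
#'
#' @param result An `alignment_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
alignment_to_json <- function(result, path) {
  stopifnot(inherits(result, "alignment_result"))
  zf <- lapply(result$zfits, function(z) {
    if (is.null(z)) return(NULL)
    z$fitted <- NULL
    unclass(z)
  })
  jsonlite::write_json(list(iterations = result$iterations, zfits = zf,
                            converged = result$converged,
                            n_iter = result$n_iter,
                            total_shift_um = result$total_shift_um),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a match result as a CSV pair table
#'
#' @param match A `match_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
match_to_csv <- function(match, path) {
  stopifnot(inherits(match, "match_result"))
  write.csv(match$pairs, path, row.names = FALSE)
  invisible(path)
}
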