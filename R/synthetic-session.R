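#' Simulate an AR(1) calcium trace from a spike train
#'
#' The calcium transient evoked by each spike decays exponentially, so the
#' trace follows the first-order autoregressive recursion
#' `c(t) = gamma * c(t-1) + s(t)`, to which a constant resting baseline is
#' added. The impulse response of the recursion is exactly `gamma^t`.
#'
#' @param spikes Nonnegative numeric vector of spike amplitudes per frame.
#' @param gamma AR(1) coefficient in (0, 1); per-frame calcium decay.
#' @param baseline Constant resting fluorescence added to the trace.
#' @return Numeric vector, same length as `spikes`.
#' @export
simulate_calcium <- function(spikes, gamma, baseline = 0) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0 || gamma >= 1)
    stop("gamma must be a scalar in (0, 1)")
  if (any(spikes < 0)) stop("spikes must be nonnegative")
  as.numeric(stats::filter(spikes, gamma, method = "recursive")) + baseline
}

#' Simulate per-session ground truth for rendering
#'
#' Draws sparse spike trains, a slowly varying global background trace with a
#' smooth rank-1 spatial profile, and records the rigid 3-D drift and noise
#' parameters applied when the session is rendered.
#'
#' @param field A `field_truth`.
#' @param n_frames Number of volumes to simulate.
#' @param frame_rate_hz Volume rate (default mirrors a 10.4 vol/s ETL cycle).
#' @param gamma AR(1) calcium decay per volume.
#' @param firing_rate_hz Mean spike rate per cell.
#' @param spike_amp_range Range of spike amplitudes, expressed relative to
#'   the resting calcium level (an amplitude of 1 doubles the resting
#'   fluorescence at the transient peak).
#' @param drift_um Rigid field drift `c(dx, dy, dz)` in micrometres applied
#'   to this session relative to the field's reference position.
#' @param background_strength Peak amplitude of the global background in the
#'   functional channel, arbitrary units (0 disables it).
#' @param noise_gain Scale of the multiplicative, gamma-distributed shot-like
#'   noise (0 disables); `gamma_shape` sets its skewness.
#' @param gamma_shape Shape parameter of the shot-noise gamma distribution.
#' @param read_noise_sd Standard deviation of additive Gaussian read noise.
#' @param seed Integer seed.
#' @return An object of class `session_truth`.
#' @export
simulate_session_truth <- function(field, n_frames,
                                   frame_rate_hz = 10.4,
                                   gamma = 0.85,
                                   firing_rate_hz = 0.05,
                                   spike_amp_range = c(0.5, 1.5),
                                   drift_um = c(0, 0, 0),
                                   background_strength = 5,
                                   noise_gain = 1,
                                   gamma_shape = 2,
                                   read_noise_sd = 0.5,
                                   seed = 1L) {
  stopifnot(inherits(field, "field_truth"), n_frames >= 1)
  if (gamma <= 0 || gamma >= 1) stop("gamma must be in (0, 1)")
  n_cells <- nrow(field$cells)
  out <- with_seed(seed, {
    p_spike <- min(1, firing_rate_hz / frame_rate_hz)
    spikes <- matrix(0, n_cells, n_frames)
    if (n_cells > 0 && p_spike > 0) {
      hit <- matrix(runif(n_cells * n_frames) < p_spike, n_cells, n_frames)
      spikes[hit] <- runif(sum(hit), spike_amp_range[1], spike_amp_range[2])
    }
    tt <- seq_len(n_frames) / frame_rate_hz
    background_trace <- 1 + 0.25 * sin(2 * pi * tt / 47) +
      0.15 * sin(2 * pi * tt / 11 + 1)
    H <- field$dim_px[1]; W <- field$dim_px[2]
    ry <- (seq_len(H) - H / 2) / H; rx <- (seq_len(W) - W / 2) / W
    background_map <- outer(exp(-ry^2 / 0.5), exp(-rx^2 / 0.5))
    background_map <- background_map / max(background_map)
    list(spikes = spikes, background_trace = background_trace,
         background_map = background_map)
  })
  structure(list(
    drift_um = drift_um,
    spikes = out$spikes,
    gamma = gamma,
    frame_rate_hz = frame_rate_hz,
    background_trace = out$background_trace,
    background_map = out$background_map,
    background_strength = background_strength,
    noise_params = list(gain = noise_gain, gamma_shape = gamma_shape,
                        read_noise_sd = read_noise_sd),
    seed = as.integer(seed)
  ), class = "session_truth")
}

#' Render a multi-plane functional imaging session
#'
#' Composes, frame by frame, the fluorescence movie implied by a field and a
#' session ground truth: per-cell Gaussian footprints (with axial defocus
#' attenuation) times their AR(1) calcium traces, a rank-1 global background,
#' gamma-distributed shot-like noise and Gaussian read noise. The per-cell
#' noiseless fluorescence traces are returned alongside the movie as ground
#' truth.
#'
#' @param field A `field_truth`.
#' @param truth A `session_truth` (its `drift_um` is applied to the field).
#' @param n_frames Number of volumes; must not exceed the spike train length.
#' @param sigma_z_um Axial defocus length scale (micrometres).
#' @return An object of class `imaging_session`: list with `movie` (array
#'   `[rows, cols, plane, frame]`), acquisition metadata, and a `truth`
#'   element holding per-cell traces (`baseline + calcium`, attenuated by
#'   defocus for the cell's own plane), spikes, and flags.
#' @export
render_session <- function(field, truth, n_frames = ncol(truth$spikes),
                           sigma_z_um = 12) {
  stopifnot(inherits(field, "field_truth"), inherits(truth, "session_truth"),
            n_frames >= 1, n_frames <= ncol(truth$spikes))
  n_cells <- nrow(field$cells)
  H <- field$dim_px[1]; W <- field$dim_px[2]
  calcium <- matrix(0, n_cells, n_frames)
  for (i in seq_len(n_cells))
    calcium[i, ] <- simulate_calcium(truth$spikes[i, seq_len(n_frames)],
                                     truth$gamma, baseline = 1)
  fluor <- sweep(calcium, 1, field$cells$brightness_functional, "*")
  movie <- array(0, c(H, W, field$n_planes, n_frames))
  atten <- numeric(n_cells)
  with_seed(truth$seed, for (p in seq_len(field$n_planes)) {
    fp <- field_footprints(field, plane = p, shift_um = truth$drift_um,
                           sigma_z_um = sigma_z_um, channel = "functional")
    own <- which(field$cells$plane_index == p)
    atten[own] <- fp$attenuation[own]
    plane_px <- fp$A %*% fluor
    bg <- as.vector(truth$background_map) %o%
      (truth$background_strength * truth$background_trace[seq_len(n_frames)])
    plane_px <- plane_px + bg
    np <- truth$noise_params
    if (np$gain > 0)
      plane_px <- plane_px + matrix(
        rgamma(H * W * n_frames, shape = np$gamma_shape, scale = np$gain),
        H * W, n_frames)
    if (np$read_noise_sd > 0)
      plane_px <- plane_px + matrix(rnorm(H * W * n_frames, 0, np$read_noise_sd),
                                    H * W, n_frames)
    movie[, , p, ] <- array(plane_px, c(H, W, n_frames))
  })
  all_out <- n_cells > 0 && all(atten < 1e-4)
  structure(list(
    movie = movie,
    frame_rate_hz = truth$frame_rate_hz,
    plane_spacing_um = field$plane_spacing_um,
    pixel_size_um = field$pixel_size_um,
    n_planes = field$n_planes,
    channels = "functional",
    all_cells_out_of_fov = all_out,
    truth = list(
      traces = fluor * atten,
      calcium = calcium,
      spikes = truth$spikes[, seq_len(n_frames), drop = FALSE],
      attenuation = atten,
      drift_um = truth$drift_um,
      field = field
    )
  ), class = "imaging_session")
}

#' Render a structural (nuclear channel) Z-stack
#'
#' Emulates the structural-stack acquisition used for cross-day alignment:
#' the nuclear channel is recorded at each relative objective Z position
#' (default +30 to -30 micrometres in 5-micrometre steps) for a number of
#' frames per position, and mean-projected across time per (Z, plane).
#'
#' @param field A `field_truth`.
#' @param z_offsets_um Objective Z grid (micrometres), default `seq(30, -30, -5)`.
#' @param frames_per_z Frames averaged at each Z position (>= 1).
#' @param shift_um Residual rigid displacement `c(dx, dy, dz)` of the field
#'   relative to the objective (drift minus any stage compensation).
#' @param noise_gain,gamma_shape,read_noise_sd Noise model, as in
#'   [simulate_session_truth()] (defaults are mild; set gains to 0 for a
#'   noiseless stack).
#' @param sigma_z_um Axial defocus length scale (micrometres).
#' @param seed Integer seed.
#' @return Object of class `structural_stack`: list with `images` (array
#'   `[rows, cols, z, plane]`), `z_offsets_um`, and geometry metadata.
#' @export
render_structural_stack <- function(field,
                                    z_offsets_um = seq(30, -30, by = -5),
                                    frames_per_z = 5L,
                                    shift_um = c(0, 0, 0),
                                    noise_gain = 0.3,
                                    gamma_shape = 2,
                                    read_noise_sd = 0.2,
                                    sigma_z_um = 12,
                                    seed = 1L) {
  stopifnot(inherits(field, "field_truth"))
  if (length(z_offsets_um) == 0) stop("z_offsets_um must be nonempty")
  if (frames_per_z < 1) stop("frames_per_z must be >= 1")
  H <- field$dim_px[1]; W <- field$dim_px[2]
  nz <- length(z_offsets_um)
  images <- array(0, c(H, W, nz, field$n_planes))
  bright <- field$cells$brightness_structural
  with_seed(seed, {
    for (iz in seq_len(nz)) {
      for (p in seq_len(field$n_planes)) {
        fp <- field_footprints(field, plane = p,
                               z_offset_um = z_offsets_um[iz],
                               shift_um = shift_um,
                               sigma_z_um = sigma_z_um,
                               channel = "structural")
        clean <- matrix(fp$A %*% bright, H, W)
        acc <- matrix(0, H, W)
        for (f in seq_len(frames_per_z)) {
          fr <- clean
          if (noise_gain > 0)
            fr <- fr + matrix(rgamma(H * W, shape = gamma_shape,
                                     scale = noise_gain), H, W)
          if (read_noise_sd > 0)
            fr <- fr + matrix(rnorm(H * W, 0, read_noise_sd), H, W)
          acc <- acc + fr
        }
        images[, , iz, p] <- acc / frames_per_z
      }
    }
  })
  structure(list(
    images = images,
    z_offsets_um = z_offsets_um,
    pixel_size_um = field$pixel_size_um,
    plane_spacing_um = field$plane_spacing_um,
    n_planes = field$n_planes
  ), class = "structural_stack")
}
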