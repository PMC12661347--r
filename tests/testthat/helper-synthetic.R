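# Shared helpers for building small ground-truthed fixtures in code.

# Exhaustive-permutation linear-sum-assignment oracle (n <= 7).
brute_force_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  k <- min(n, m)
  if (n <= m) {
    perms <- all_permutations(seq_len(m))
    best <- Inf
    for (p in perms) {
      s <- sum(cost[cbind(seq_len(n), p[seq_len(n)])])
      if (s < best) best <- s
    }
  } else {
    perms <- all_permutations(seq_len(n))
    best <- Inf
    for (p in perms) {
      s <- sum(cost[cbind(p[seq_len(m)], seq_len(m))])
      if (s < best) best <- s
    }
  }
  best
}

all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_permutations(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
  out
}

mask_touches_border <- function(mask, dim) {
  min(mask$pixels) <= 1 ||
    max(mask$pixels[, 1]) >= dim[1] || max(mask$pixels[, 2]) >= dim[2]
}

# A component with a Gaussian footprint and a movie equal to footprint x
# trace, deconvolved and ready for evaluate_component().
make_footprint_component <- function(trace, gamma = 0.85, H = 9L) {
  foot <- exp(-((row(matrix(0, H, H)) - (H + 1) / 2)^2 +
                  (col(matrix(0, H, H)) - (H + 1) / 2)^2) / 8)
  movie <- array(as.vector(foot) %o% trace, c(H, H, length(trace)))
  px <- which(foot >= 0.3 * max(foot), arr.ind = TRUE)
  m <- cell_mask(px, check = FALSE)
  base <- as.numeric(quantile(trace, 0.08, type = 7))
  lam <- 2 * stats::mad(diff(trace)) / sqrt(2)
  dec <- deconvolve_ar1(trace - base, gamma, lambda = lam)
  comp <- structure(list(mask = m, raw_trace = trace,
                         background_at_mask = rep(0, length(trace)),
                         denoised_trace = dec$denoised, spikes = dec$spikes,
                         gamma = gamma, snr = NA_real_, rvalue = NA_real_,
                         decision = "undecided"),
                    class = "component")
  list(component = comp, movie = movie, footprint = foot)
}

# Single-plane field + session with one planted transient per cell, plus
# the physically expected peak dF/F for each cell, for pipeline fidelity
# tests. Returns NULL expectation for cells whose detected mask is missing.
planted_dff_session <- function(seed, n_cells = 8L, n_frames = 1200L) {
  f <- generate_field(n_cells, fov_um = c(80, 80), n_planes = 1,
                      min_sep_um = 20, n_nuclei = 0, frac_structural = 0,
                      seed = seed)
  tr <- simulate_session_truth(f, n_frames = n_frames, firing_rate_hz = 0.03,
                               background_strength = 2, seed = seed + 50L)
  amps <- with_test_seed(seed + 500L, runif(n_cells, 0.8, 2.0))
  plant_t <- 200L + 100L * seq_len(n_cells)
  for (i in seq_len(n_cells)) tr$spikes[i, plant_t[i]] <- amps[i]
  ses <- render_session(f, tr)
  list(field = f, truth = tr, session = ses, amps = amps, plant_t = plant_t)
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Measure per-session mean absolute relative dF/F error against the
# ground-truth expectation (resting fluorescence, background light and
# superposed true calcium all from the generator's ground truth).
dff_session_error <- function(ps) {
  f <- ps$field; tr <- ps$truth; ses <- ps$session
  img <- brightness_correct(apply(ses$movie[, , 1, ], c(1, 2), mean))
  masks <- detect_masks(img)
  ex <- extract_components(ses$movie[, , 1, ], masks)
  truth_px <- cbind(f$cells$y_um / f$pixel_size_um[2] + 0.5,
                    f$cells$x_um / f$pixel_size_um[1] + 0.5)
  fp <- longca:::field_footprints(f, plane = 1, channel = "functional")
  bg8 <- quantile(tr$background_trace, 0.08, type = 7)
  noise_mean <- tr$noise_params$gamma_shape * tr$noise_params$gain
  cents <- t(vapply(ex$components, function(co) co$mask$centroid_px, numeric(2)))
  errs <- c()
  for (i in seq_len(nrow(f$cells))) {
    d <- sqrt(rowSums((cents - matrix(truth_px[i, ], nrow(cents), 2,
                                      byrow = TRUE))^2))
    ci <- which.min(d)
    if (d[ci] > 3) next
    comp <- ex$components[[ci]]
    win <- (ps$plant_t[i] - 2):(ps$plant_t[i] + 6)
    lin <- (comp$mask$pixels[, 2] - 1L) * f$dim_px[1] + comp$mask$pixels[, 1]
    f_rest <- mean(fp$A[lin, i]) * f$cells$brightness_functional[i]
    bgm <- mean(tr$background_map[comp$mask$pixels]) * tr$background_strength * bg8
    expected <- (max(ses$truth$calcium[i, win]) - 1) * f_rest /
      (f_rest + bgm + noise_mean)
    dff <- component_dff(comp, ex$background, ses$frame_rate_hz)
    errs <- c(errs, abs(max(dff$dff[win]) / expected - 1))
  }
  list(errors = errs, n_found = length(errs))
}
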