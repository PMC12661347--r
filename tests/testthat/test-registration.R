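test_that("brightness correction flattens smooth structure and keeps impulses", {
  expect_equal(brightness_correct(matrix(3, 40, 40)),
               matrix(1, 40, 40))

  ramp <- matrix(seq(1, 2, length.out = 64), 64, 64)
  out <- brightness_correct(ramp)
  expect_lt(max(abs(out[20:44, 20:44] - 1)), 0.05)

  imp <- matrix(2, 40, 40); imp[20, 20] <- 50
  out2 <- brightness_correct(imp)
  expect_gt(out2[20, 20], 10)            # impulse preserved
  expect_lt(max(abs(out2[1:10, 1:10] - 1)), 1e-3)  # surround flat

  expect_error(brightness_correct(matrix(1, 10, 10), kernel_px = 25),
               "larger than image")
  expect_error(brightness_correct(matrix(1, 40, 40), kernel_px = 24), "odd")
  expect_error(brightness_correct(matrix(-1, 40, 40)), "nonnegative")
})

test_that("rigid XY shift is exact for periodic integer translations", {
  set.seed(10)
  ref <- matrix(rnorm(64 * 64), 64, 64)
  s0 <- rigid_shift_xy(ref, ref)
  expect_equal(c(s0$dx_px, s0$dy_px), c(0, 0))
  expect_equal(s0$peak_corr, 1, tolerance = 1e-12)

  # reference translated by (+3, -2): recover (-3, +2) exactly
  img <- longca:::roll_matrix(ref, dy = -2, dx = 3)
  s <- rigid_shift_xy(img, ref, subpixel = FALSE)
  expect_equal(c(s$dx_px, s$dy_px), c(-3, 2))
  expect_equal(s$peak_corr, 1, tolerance = 1e-12)

  # equivariance over random integer shifts
  for (k in 1:10) {
    t_xy <- sample(-15:15, 2)
    img_k <- longca:::roll_matrix(ref, dy = t_xy[2], dx = t_xy[1])
    sk <- rigid_shift_xy(img_k, ref, subpixel = FALSE)
    expect_equal(c(sk$dx_px, sk$dy_px), -t_xy)
  }

  expect_error(rigid_shift_xy(matrix(1, 16, 16), matrix(1, 16, 16)),
               "degenerate")
  set.seed(11)
  noisy <- rigid_shift_xy(matrix(rnorm(900), 30), matrix(rnorm(900), 30))
  expect_true(noisy$low_confidence)
})

test_that("best XY shift over a stack picks the in-focus plane", {
  f <- generate_field(20, fov_um = c(100, 100), n_planes = 1, n_nuclei = 40,
                      seed = 21)
  ref <- render_structural_stack(f, frames_per_z = 2, seed = 22)
  same <- best_xy_over_stack(ref, ref)
  expect_equal(c(same$dx_px, same$dy_px), c(0, 0), tolerance = 1e-9)
  expect_equal(same$source_plane, which(ref$z_offsets_um == 0))
  corrs <- attr(same, "per_z_corr")
  expect_equal(same$source_plane, which.max(corrs))
  empty <- ref; empty$z_offsets_um <- numeric(0)
  expect_error(best_xy_over_stack(empty, ref), "empty")
})

test_that("linear-offset Gaussian fit recovers noiseless parameters", {
  z <- seq(30, -30, by = -5)
  truth <- c(a = 0.5, b = 0.2, mu = 7.5, s = 10)
  y <- truth["a"] * exp(-(z - truth["mu"])^2 / (2 * truth["s"]^2)) + truth["b"]
  fit <- fit_linear_offset_gaussian(z, y)
  expect_equal(fit$amplitude, 0.5, tolerance = 1e-6)
  expect_equal(fit$offset, 0.2, tolerance = 1e-6)
  expect_equal(fit$mu_um, 7.5, tolerance = 1e-6)
  expect_equal(fit$sigma_um, 10, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)

  sym <- 0.4 * exp(-z^2 / 128) + 0.1
  expect_equal(fit_linear_offset_gaussian(z, sym)$mu_um, 0, tolerance = 1e-6)

  expect_error(fit_linear_offset_gaussian(z, rep(0.3, 13)), "no axial peak")
  expect_error(fit_linear_offset_gaussian(z[1:3], y[1:3]), "4")
  expect_error(fit_linear_offset_gaussian(c(0, 1, 1, 2), c(1, 2, 3, 4)),
               "monotone")
})

test_that("noisy Gaussian fits recover the center within 2.5 um in >= 95% of trials", {
  z <- seq(30, -30, by = -5)
  hits <- 0L
  set.seed(42)
  for (k in 1:200) {
    mu <- runif(1, -15, 15)
    y <- 0.6 * exp(-(z - mu)^2 / (2 * 12^2)) + 0.15 + rnorm(13, 0, 0.02)
    fit <- tryCatch(fit_linear_offset_gaussian(z, y), error = function(e) NULL)
    if (!is.null(fit) && abs(fit$mu_um - mu) <= 2.5) hits <- hits + 1L
  }
  expect_gte(hits, 190L)
})

test_that("axial shift estimation lands within half a Z-step of the truth", {
  f <- generate_field(20, fov_um = c(100, 100), n_planes = 1, n_nuclei = 60,
                      seed = 23)
  ref <- render_structural_stack(f, frames_per_z = 4, seed = 24)
  st0 <- render_structural_stack(f, frames_per_z = 4, shift_um = c(0, 0, 0),
                                 seed = 25)
  e0 <- estimate_z_shift(st0, ref)
  expect_lt(abs(e0$dz_um), 1.5)

  st10 <- render_structural_stack(f, frames_per_z = 4, shift_um = c(0, 0, 10),
                                  seed = 26)
  e10 <- estimate_z_shift(st10, ref)
  expect_lt(abs(e10$dz_um - 10), 2.5)

  # drift far outside the +/-30 um capture range: no usable peak
  st50 <- render_structural_stack(f, frames_per_z = 4, shift_um = c(0, 0, 55),
                                  seed = 27)
  res <- tryCatch(suppressWarnings(estimate_z_shift(st50, ref)),
                  error = function(e) "no_peak")
  if (!identical(res, "no_peak"))
    expect_gt(abs(res$dz_um), 25)  # pinned at the grid edge
})

test_that("closed-loop alignment converges immediately at zero drift and fails gracefully", {
  f <- generate_field(20, fov_um = c(100, 100), n_planes = 1, n_nuclei = 60,
                      seed = 31)
  ref <- render_structural_stack(f, frames_per_z = 3, seed = 32)
  acquire0 <- function(pos) render_structural_stack(
    f, frames_per_z = 3, shift_um = c(0, 0, 0) - pos, seed = 33)
  r0 <- align_iterative(acquire0, ref)
  expect_true(r0$converged)
  expect_equal(r0$n_iter, 1L)
  expect_lt(max(abs(r0$total_shift_um)), 2)

  # XY drift beyond the search window is unreachable
  big <- c(60, 0, 0)
  rbig <- align_iterative(function(pos) render_structural_stack(
    f, frames_per_z = 3, shift_um = big - pos, seed = 34), ref,
    max_iter = 3)
  expect_false(abs(rbig$total_shift_um[1] - 60) < 5 && rbig$converged &&
                 rbig$n_iter == 1)
})

test_that("closed-loop residual shift magnitude is non-increasing within capture range", {
  f <- generate_field(25, fov_um = c(120, 120), n_planes = 1, n_nuclei = 70,
                      seed = 35)
  ref <- render_structural_stack(f, frames_per_z = 3, seed = 36)
  drift <- c(12, -8, 10)
  r <- align_iterative(function(pos) render_structural_stack(
    f, frames_per_z = 3, shift_um = drift - pos, seed = 37), ref)
  expect_true(r$converged)
  expect_lte(r$n_iter, 3L)
  steps <- sqrt(rowSums(as.matrix(
    r$iterations[, c("dx_um", "dy_um", "dz_um")])^2))
  expect_true(all(diff(steps) <= 1e-9))
  expect_lt(max(abs(r$total_shift_um - drift)), 5)
})

test_that("piecewise-rigid mapping reduces to rigid and tracks global translations", {
  set.seed(50)
  # tile a 32 px periodic texture so a global roll is also a within-patch
  # roll for every 32 px patch
  block <- as.matrix(EBImage::gblur(matrix(rnorm(32 * 32), 32, 32), 1.5))
  ref <- rbind(cbind(block, block, block), cbind(block, block, block),
               cbind(block, block, block)) + 2

  zero <- piecewise_rigid_map(ref, ref, patch_grid = c(3, 3))
  expect_equal(max(abs(zero$dx_px)), 0, tolerance = 1e-9)
  expect_equal(max(abs(zero$dy_px)), 0, tolerance = 1e-9)

  img <- longca:::roll_matrix(ref, dy = 4, dx = -3)
  pw <- piecewise_rigid_map(img, ref, patch_grid = c(3, 3), subpixel = FALSE)
  expect_true(all(pw$dx_px == 3))
  expect_true(all(pw$dy_px == -4))

  one <- piecewise_rigid_map(img, ref, patch_grid = c(1, 1))
  rig <- rigid_shift_xy(img, ref)
  expect_equal(one$dx_px[1, 1], rig$dx_px)
  expect_equal(one$dy_px[1, 1], rig$dy_px)

  expect_error(piecewise_rigid_map(ref, ref, patch_grid = c(10, 10)),
               "patch smaller")
})

test_that("shift fields warp images and masks correctly", {
  set.seed(60)
  img <- matrix(runif(48 * 48), 48, 48)
  zero <- rigid_shift_field(0, 0, c(48, 48))
  expect_equal(apply_shift_field(img, zero), img)

  m <- cell_mask(cbind(20:24, rep(20:24, each = 5)))
  tr <- rigid_shift_field(3, -2, c(48, 48))
  wm <- apply_shift_field(m, tr)
  expect_setequal(paste(wm$pixels[, 1], wm$pixels[, 2]),
                  paste(m$pixels[, 1] - 2, m$pixels[, 2] + 3))

  # outward shift at the border clips the mask and flags it
  edge <- cell_mask(cbind(2:4, rep(2:4, each = 3)))
  out <- rigid_shift_field(-3, -3, c(48, 48))
  we <- apply_shift_field(edge, out)
  expect_lt(we$area_px2, edge$area_px2)
  expect_true(isTRUE(attr(we, "clipped")))
  gone <- suppressWarnings(apply_shift_field(edge, rigid_shift_field(-100, 0, c(48, 48))))
  expect_true(isTRUE(attr(gone, "empty")))
  expect_equal(nrow(gone$pixels), 0L)
})

test_that("rendering a drifted field and registering recovers the negated drift", {
  f <- generate_field(15, fov_um = c(100, 100), n_planes = 1, n_nuclei = 20,
                      frac_structural = 0, seed = 70)
  t0 <- simulate_session_truth(f, 2, background_strength = 0, noise_gain = 0.2,
                               read_noise_sd = 0.1, seed = 71)
  t0$spikes[] <- 0
  d_px <- c(6, -4)
  t1 <- t0; t1$drift_um <- c(d_px * 1.25, 0)
  i0 <- apply(render_session(f, t0)$movie[, , 1, ], c(1, 2), mean)
  i1 <- apply(render_session(f, t1)$movie[, , 1, ], c(1, 2), mean)
  s <- rigid_shift_xy(i1, i0, pixel_size_um = c(1.25, 1.25))
  expect_equal(c(s$dx_px, s$dy_px), -d_px, tolerance = 0.15)
})
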