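test_that("field generation respects density, separation, and determinism", {
  expect_equal(nrow(generate_field(0, n_nuclei = 0, seed = 1)$cells), 0L)

  f1 <- generate_field(20, seed = 1)
  f2 <- generate_field(20, seed = 1)
  expect_identical(f1, f2)

  # 50 cells at >= 15 px separation: verify every pair directly
  sep_px <- 15
  f <- generate_field(50, fov_um = c(320, 320), n_planes = 1,
                      min_sep_um = sep_px * 1.25, n_nuclei = 0, seed = 3)
  xy <- as.matrix(f$cells[, c("x_um", "y_um", "z_um")]) / 1.25
  d <- as.matrix(dist(xy))
  expect_true(all(d[upper.tri(d)] >= sep_px))

  expect_error(generate_field(500, fov_um = c(50, 50), n_planes = 1,
                              min_sep_um = 20, n_nuclei = 0, seed = 1),
               "infeasible")
})

test_that("field invariants hold: centroids in FOV, radii positive, planes valid", {
  f <- generate_field(30, seed = 7)
  expect_true(all(f$cells$x_um >= 0 & f$cells$x_um <= f$fov_um[1]))
  expect_true(all(f$cells$y_um >= 0 & f$cells$y_um <= f$fov_um[2]))
  expect_true(all(f$cells$radius_um > 0))
  expect_true(all(f$cells$plane_index %in% seq_len(f$n_planes)))
})

test_that("AR(1) calcium simulation matches its closed form and is linear", {
  sp <- numeric(10); sp[1] <- 1
  expect_equal(simulate_calcium(sp, 0.5), 0.5^(0:9))
  expect_equal(simulate_calcium(numeric(5), 0.9, baseline = 2), rep(2, 5))
  s1 <- c(0, 1, 0, 0, 0.3, 0); s2 <- c(0.5, 0, 0, 0.2, 0, 0)
  expect_equal(simulate_calcium(s1 + s2, 0.8, 1),
               simulate_calcium(s1, 0.8, 1) + simulate_calcium(s2, 0.8, 1) - 1)
  expect_error(simulate_calcium(sp, 1.2), "gamma")
  expect_error(simulate_calcium(sp, 0), "gamma")
  expect_error(simulate_calcium(-sp, 0.5), "nonnegative")
})

test_that("a noiseless one-cell session is the footprint times its trace", {
  f <- generate_field(1, fov_um = c(40, 40), n_planes = 1, n_nuclei = 0,
                      frac_structural = 0, z_jitter_um = 0, seed = 2)
  tr <- simulate_session_truth(f, n_frames = 5, background_strength = 0,
                               noise_gain = 0, read_noise_sd = 0, seed = 2)
  tr$spikes[] <- 0
  ses <- render_session(f, tr)
  # no spikes: every frame identical, equal to footprint x resting level
  for (fr in 2:5)
    expect_equal(ses$movie[, , 1, fr], ses$movie[, , 1, 1])
  fp <- longca:::field_footprints(f, plane = 1, channel = "functional")
  expected <- matrix(fp$A %*% f$cells$brightness_functional, 40 / 1.25)
  expect_equal(ses$movie[, , 1, 1], expected)
})

test_that("rendering with XY drift translates the frame within interpolation tolerance", {
  f <- generate_field(6, fov_um = c(80, 80), n_planes = 1, n_nuclei = 0,
                      frac_structural = 0, seed = 4)
  base <- simulate_session_truth(f, n_frames = 3, background_strength = 0,
                                 noise_gain = 0, read_noise_sd = 0, seed = 4)
  base$spikes[] <- 0
  drift <- base
  drift$drift_um <- c(5, -3.75, 0)  # 4 px right, 3 px up at 1.25 um/px
  s0 <- render_session(f, base)
  s1 <- render_session(f, drift)
  shifted <- longca:::roll_matrix(s0$movie[, , 1, 1], dy = -3, dx = 4)
  interior <- 10:54
  expect_lt(max(abs(s1$movie[interior, interior, 1, 1] -
                      shifted[interior, interior])), 0.35)
  expect_gt(cor(as.vector(s1$movie[interior, interior, 1, 1]),
                as.vector(shifted[interior, interior])), 0.995)
})

test_that("session rendering is deterministic down to the TIFF payload", {
  f <- generate_field(4, fov_um = c(40, 40), n_planes = 2, seed = 5)
  tr <- simulate_session_truth(f, n_frames = 4, seed = 6)
  s1 <- render_session(f, tr)
  s2 <- render_session(f, tr)
  expect_identical(s1$movie, s2$movie)
  p1 <- tempfile(fileext = ".tif"); p2 <- tempfile(fileext = ".tif")
  write_session_tiff(s1, p1); write_session_tiff(s2, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("drift pushing all cells out of the FOV raises the metadata flag", {
  f <- generate_field(3, fov_um = c(40, 40), n_planes = 1, n_nuclei = 0,
                      frac_structural = 0, seed = 8)
  tr <- simulate_session_truth(f, n_frames = 2, seed = 8)
  tr$drift_um <- c(500, 500, 0)
  ses <- render_session(f, tr)
  expect_true(ses$all_cells_out_of_fov)
})

test_that("structural stacks use the +30..-30 um grid and only nuclear cells", {
  f <- generate_field(5, fov_um = c(60, 60), n_planes = 1, n_nuclei = 5,
                      frac_structural = 0, z_jitter_um = 0, seed = 9)
  st <- render_structural_stack(f, frames_per_z = 1, noise_gain = 0,
                                read_noise_sd = 0, seed = 9)
  expect_equal(length(st$z_offsets_um), 13L)
  expect_equal(st$z_offsets_um, seq(30, -30, by = -5))
  expect_error(render_structural_stack(f, frames_per_z = 0), "frames_per_z")
  expect_error(render_structural_stack(f, z_offsets_um = numeric(0)),
               "nonempty")

  # functional-only cells must leave no trace in the structural channel
  img <- st$images[, , which(st$z_offsets_um == 0), 1]
  fp_fun <- longca:::field_footprints(f, plane = 1, channel = "functional")
  fp_str <- longca:::field_footprints(f, plane = 1, channel = "structural")
  fun_only <- which(f$cells$brightness_structural == 0 &
                      f$cells$brightness_functional > 0)
  expect_gt(length(fun_only), 0)
  for (i in fun_only) {
    on_px <- which(fp_fun$A[, i] > 0.5 * max(fp_fun$A[, i]))
    str_support <- rowSums(fp_str$A) > 0
    clean <- on_px[!str_support[on_px]]
    if (length(clean)) expect_equal(max(abs(as.vector(img)[clean])), 0)
  }

  # frames_per_z = 1 with zero noise equals a single rendered frame
  st2 <- render_structural_stack(f, frames_per_z = 5, noise_gain = 0,
                                 read_noise_sd = 0, seed = 10)
  expect_equal(st$images, st2$images)
})

test_that("behavior simulation implements timeouts, rewards, and cue sampling", {
  frozen <- simulate_behavior(5, agent = list(speed_cm_s = 1, speed_sd = 0,
                                              accuracy = 0.8), seed = 1)
  expect_true(all(frozen$trials$outcome == "timeout"))
  expect_true(all(is.na(frozen$trials$t_choice)))
  expect_equal(frozen$trials$t_outcome - frozen$trials$t_start, rep(120, 5))

  perfect <- simulate_behavior(50, agent = list(speed_cm_s = 25, speed_sd = 0,
                                                accuracy = 1), seed = 2)
  expect_true(all(perfect$trials$outcome == "correct"))
  expect_true(all(perfect$trials$t_start < perfect$trials$t_choice))
  expect_true(all(perfect$trials$t_choice <= perfect$trials$t_outcome))

  b <- simulate_behavior(400, seed = 3)
  mem <- b$trials[b$trials$trial_type == "memory", ]
  expect_true(all(mem$cue_pos_cm >= 8.5 & mem$cue_pos_cm <= 153.8))
  expect_true(all(b$trials$outcome[!is.na(b$trials$chosen_side)] ==
                    ifelse(b$trials$chosen_side[!is.na(b$trials$chosen_side)] ==
                             b$trials$cue_side[!is.na(b$trials$chosen_side)],
                           "correct", "incorrect")))
  expect_error(simulate_behavior(5, agent = list(speed_cm_s = -1)), "speed")
})

test_that("the side-bias rule presents the failed side more often", {
  b <- simulate_behavior(500, agent = list(speed_cm_s = 20, speed_sd = 2,
                                           accuracy = 0.55, guess_right = 1),
                         seed = 4)
  late <- b$trials[200:500, ]
  expect_gt(mean(late$cue_side == "L"), 0.5)
  # and the probability used is clipped to the configured band
  expect_true(all(b$trials$p_right_cue >= 0.2 & b$trials$p_right_cue <= 0.8))
})

test_that("histology rendering matches its ground truth", {
  empty <- render_histology(histology_truth(0, seed = 1), noise_sd = 0,
                            shot_scale = 0)
  expect_equal(length(unique(as.vector(empty$image))), 1L)

  hi <- render_histology(histology_truth(10, per_cell_area_px2 = 20, seed = 2),
                         noise_sd = 0, shot_scale = 0)
  lab <- EBImage::bwlabel(hi$image > 0.5)
  expect_equal(max(lab), 10)

  h1 <- render_histology(histology_truth(7, seed = 5))
  h2 <- render_histology(histology_truth(7, seed = 5))
  expect_identical(h1$image, h2$image)
})

test_that("perturb_field keeps correspondence and respects separation", {
  fA <- generate_field(30, fov_um = c(240, 240), n_planes = 1,
                       min_sep_um = 18, n_nuclei = 0, seed = 11)
  fB <- perturb_field(fA, turnover_frac = 0.2, min_sep_um = 18, seed = 12)
  expect_equal(nrow(fB$correspondence), 24L)
  pers <- fB$correspondence$id_a
  expect_equal(fA$cells$x_um[pers], fB$cells$x_um[pers])
  d <- as.matrix(dist(as.matrix(fB$cells[, c("x_um", "y_um", "z_um")])))
  expect_true(all(d[upper.tri(d)] >= 18))
})
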