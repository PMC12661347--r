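test_that("mask detection finds well-separated blobs and nothing in blanks", {
  expect_equal(detect_masks(matrix(0, 64, 64)), list())
  expect_equal(detect_masks(matrix(5, 64, 64)), list())

  f <- generate_field(20, fov_um = c(160, 160), n_planes = 1, min_sep_um = 20,
                      n_nuclei = 0, frac_structural = 0, seed = 13)
  fp <- longca:::field_footprints(f, plane = 1, channel = "functional")
  img <- matrix(fp$A %*% f$cells$brightness_functional, f$dim_px[1])
  set.seed(14)
  img <- img + matrix(rgamma(length(img), 2, scale = 0.5), nrow(img))
  masks <- detect_masks(brightness_correct(img))
  expect_equal(length(masks), 20L)
  truth_px <- cbind(f$cells$y_um / 1.25 + 0.5, f$cells$x_um / 1.25 + 0.5)
  cents <- t(vapply(masks, `[[`, numeric(2), "centroid_px"))
  for (i in 1:20) {
    d <- sqrt(rowSums((cents - matrix(truth_px[i, ], 20, 2, byrow = TRUE))^2))
    expect_lt(min(d), 1)
  }

  # each mask is a valid 4-connected component
  for (m in masks) expect_true(longca:::is_4connected(m$pixels))
})

test_that("detection drops components below min_size and is monotone in it", {
  img <- matrix(0, 64, 64)
  img[10:12, 10:12] <- 10       # 9 px
  img[30, 30:32] <- 10          # 3 px
  m5 <- detect_masks(img, offset = 1, min_size_px2 = 5)
  expect_equal(length(m5), 1L)
  counts <- vapply(c(1, 4, 8, 10, 20), function(ms)
    length(detect_masks(img, offset = 1, min_size_px2 = ms)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("cell counting is stable across renders of the same field", {
  f <- generate_field(12, fov_um = c(120, 120), n_planes = 1, min_sep_um = 18,
                      n_nuclei = 0, frac_structural = 0, seed = 15)
  t1 <- simulate_session_truth(f, 40, seed = 16)
  t2 <- simulate_session_truth(f, 40, seed = 17)
  c1 <- count_cells(render_session(f, t1))
  c2 <- count_cells(render_session(f, t2))
  expect_equal(c1, 12L)
  expect_equal(c1, c2)
  expect_equal(count_cells(matrix(0, 64, 64)), 0L)
})

test_that("seeded extraction reproduces traces on clean movies", {
  H <- 32
  foot <- matrix(0, H, H)
  foot[10:14, 10:14] <- exp(-(outer((-2:2)^2, (-2:2)^2, "+")) / 4)
  trace <- 5 + simulate_calcium(replace(numeric(200), 50, 2), 0.85)
  movie <- array(as.vector(foot) %o% trace, c(H, H, 200))
  m <- cell_mask(which(foot > 0, arr.ind = TRUE))
  ex <- extract_components(movie, list(m), lambda_sd = 0)
  raw <- ex$components[[1]]$raw_trace
  # raw trace proportional to the true trace
  expect_lt(max(abs(raw / mean(raw) - trace / mean(trace))), 1e-6)
})

test_that("the rank-1 background model recovers a pure background movie", {
  H <- 24; Tn <- 150
  map <- outer(seq(0.5, 1, length.out = H), seq(1, 0.4, length.out = H))
  btr <- 10 + 3 * sin(seq_len(Tn) / 7)
  movie <- array(as.vector(map) %o% btr, c(H, H, Tn))
  m <- cell_mask(cbind(rep(10:13, each = 4), rep(10:13, 4)))
  ex <- extract_components(movie, list(m), lambda_sd = 0)
  bg <- ex$background
  # temporal trace recovered up to scale
  expect_gt(cor(bg$temporal_trace, btr), 0.99999)
  expect_equal(max(bg$spatial_map), 1)
  # explained variance of the reconstruction >= 99%
  rec <- as.vector(bg$spatial_map) %o% bg$temporal_trace
  ev <- 1 - sum((as.vector(movie) - as.vector(rec))^2) / sum(movie^2)
  expect_gt(ev, 0.99)
  # component trace proportional to the background trace
  expect_gt(cor(ex$components[[1]]$raw_trace, btr), 0.99999)
})

test_that("traces of disjoint cells stay independent through extraction", {
  f <- generate_field(2, fov_um = c(60, 60), n_planes = 1, min_sep_um = 25,
                      n_nuclei = 0, frac_structural = 0, seed = 19)
  tr <- simulate_session_truth(f, 600, firing_rate_hz = 0.3, seed = 20)
  ses <- render_session(f, tr)
  masks <- true_masks(f, 1)
  ex <- extract_components(ses$movie[, , 1, ], masks)
  true_cor <- cor(ses$truth$traces[1, ], ses$truth$traces[2, ])
  got_cor <- cor(ex$components[[1]]$raw_trace, ex$components[[2]]$raw_trace)
  expect_lt(abs(got_cor - true_cor), 0.05)
})

test_that("AR(1) deconvolution inverts noiseless traces exactly at lambda 0", {
  g <- 0.9
  spikes <- numeric(300); spikes[c(11, 51)] <- c(1, 0.5)
  trace <- simulate_calcium(spikes, g)
  out <- deconvolve_ar1(trace, g, lambda = 0)
  expect_lt(max(abs(out$spikes - spikes)), 1e-8)
  expect_lt(max(abs(out$denoised - trace)), 1e-8)

  imp <- simulate_calcium(replace(numeric(50), 1, 1), 0.5)
  oi <- deconvolve_ar1(imp, 0.5, 0)
  expect_equal(which(oi$spikes > 0), 1L)
  expect_equal(oi$spikes[1], 1)

  expect_equal(deconvolve_ar1(numeric(100), 0.8)$spikes, numeric(100))
  expect_error(deconvolve_ar1(trace, 1.1), "gamma")
  expect_error(deconvolve_ar1(trace, 0.5, lambda = -1), "lambda")
})

test_that("deconvolution recovers spike times under mild noise", {
  g <- 0.9
  found <- 0L
  for (k in 1:10) {
    spikes <- numeric(400); spikes[c(10, 50)] <- c(1, 0.5)
    trace <- simulate_calcium(spikes, g) +
      with_test_seed(100 + k, rnorm(400, 0, 0.01))
    out <- deconvolve_ar1(trace, g, lambda = 0.02)
    top2 <- order(out$spikes, decreasing = TRUE)[1:2]
    if (setequal(top2, c(10, 50)) &&
        abs(out$spikes[10] - 1) < 0.1 && abs(out$spikes[50] - 0.5) < 0.1)
      found <- found + 1L
  }
  expect_equal(found, 10L)
})

test_that("denoised traces always satisfy the AR(1) recursion over spikes", {
  for (k in 1:5) {
    y <- with_test_seed(k, rgamma(300, 2, scale = 0.1) +
                          simulate_calcium(rbinom(300, 1, 0.02) * runif(300, 0.5, 2), 0.8))
    out <- deconvolve_ar1(y - quantile(y, 0.08), 0.8, lambda = 0.1)
    recon <- simulate_calcium(out$spikes, 0.8)
    expect_lt(max(abs(recon - out$denoised)), 1e-8)
    expect_true(all(out$spikes >= 0))
  }
})

test_that("gamma estimation recovers the decay rate from spiking traces", {
  g_true <- 0.85
  ests <- vapply(1:10, function(k) {
    tr <- with_test_seed(k, simulate_calcium(
      rbinom(3000, 1, 0.01) * runif(3000, 0.5, 1.5), g_true) +
        rnorm(3000, 0, 0.05))
    longca:::estimate_gamma(tr)
  }, numeric(1))
  expect_lt(abs(mean(ests) - g_true), 0.05)
})

test_that("SNR separates gamma-noise components from planted transients", {
  null_snr <- vapply(1:200, function(k) {
    trace <- with_test_seed(1000 + k, rgamma(800, 2, scale = 0.05))
    mc <- make_footprint_component(trace)
    evaluate_component(mc$component, mc$movie)$snr
  }, numeric(1))
  expect_gte(mean(null_snr < 0.5), 0.95)

  planted_snr <- vapply(1:30, function(k) {
    trace <- with_test_seed(2000 + k, {
      y <- rgamma(800, 2, scale = 0.05)
      y + simulate_calcium(replace(numeric(800), 400, 10 * sd(y)), 0.85)
    })
    mc <- make_footprint_component(trace)
    evaluate_component(mc$component, mc$movie)$snr
  }, numeric(1))
  expect_true(all(planted_snr > 1.2))
})

test_that("rvalue is 1 when the footprint equals the active-frame image", {
  trace <- simulate_calcium(replace(numeric(100), 30, 2), 0.8) + 1
  mc <- make_footprint_component(trace)
  # movie is footprint x trace, so the active-frame mean is the footprint
  comp <- evaluate_component(mc$component, mc$movie)
  px <- comp$mask$pixels
  rr <- range(px[, 1]); cc <- range(px[, 2])
  foot_box <- mc$footprint[rr[1]:rr[2], cc[1]:cc[2]]
  mask_box <- matrix(0, diff(rr) + 1, diff(cc) + 1)
  mask_box[cbind(px[, 1] - rr[1] + 1, px[, 2] - cc[1] + 1)] <- 1
  # correlation between binary mask and Gaussian blob is high but < 1;
  # replace the footprint by the mask itself to get exactly 1
  movie2 <- array(as.vector(mask_box) %o% trace,
                  c(nrow(mask_box), ncol(mask_box), length(trace)))
  comp2 <- mc$component
  comp2$mask <- cell_mask(which(mask_box > 0, arr.ind = TRUE), check = FALSE)
  comp2 <- evaluate_component(comp2, movie2)
  expect_equal(comp2$rvalue, 1)
  expect_gt(comp$rvalue, 0.5)
})

test_that("component screening applies rejection before acceptance", {
  tab <- data.frame(snr = c(1.3, 0.4, 0.9), rvalue = c(0.2, 0.9, 0.5))
  expect_equal(classify_components(tab),
               c("accepted", "rejected", "undecided"))
  expect_error(classify_components(tab, accept_snr = 0.4, reject_snr = 0.5),
               "thresholds")
})

test_that("decision regions partition the plane and rejection dominates", {
  grid <- expand.grid(snr = seq(0, 2, length.out = 100),
                      rvalue = seq(-0.5, 1, length.out = 100))
  dec <- classify_components(grid)
  expect_true(all(dec %in% c("accepted", "rejected", "undecided")))
  rej <- grid$snr < 0.5 | grid$rvalue < 0.1
  expect_true(all(dec[rej] == "rejected"))
  acc <- !rej & (grid$snr > 1.2 | grid$rvalue > 0.85)
  expect_true(all(dec[acc] == "accepted"))
  expect_true(all(dec[!rej & !acc] == "undecided"))
})
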