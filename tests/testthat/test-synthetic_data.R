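geom_small <- acquisition_geometry(fov_x = 100, fov_y = 100, z_range = 50,
                                   n_x = 64, n_y = 64, n_planes = 5,
                                   frame_rate = 5)

test_that("generate_brain places cells with the minimum-distance guarantee", {
  expect_equal(nrow(generate_brain(geom_small, 0, seed = 1)$cell_positions), 0)

  gt <- generate_brain(acquisition_geometry(), 2000, seed = 1)
  pos <- gt$cell_positions
  expect_equal(nrow(pos), 2000)
  # brute-force all-pairs distance check
  expect_gte(min(stats::dist(pos)), 6)
  expect_true(all(pos[, 1] >= 0 & pos[, 1] <= 800))
  expect_true(all(pos[, 2] >= 0 & pos[, 2] <= 400))
  expect_true(all(pos[, 3] >= 0 & pos[, 3] <= 180))

  gt2 <- generate_brain(acquisition_geometry(), 2000, seed = 1)
  expect_identical(gt, gt2)                     # determinism

  # motif labels and amplitudes only where responsive
  expect_true(all(is.na(gt$motif[!gt$responsive])))
  expect_true(all(!is.na(gt$motif[gt$responsive])))
  expect_true(all(gt$amplitude[gt$responsive] > 0))
})

test_that("generate_brain reports unplaceable densities", {
  tiny <- acquisition_geometry(fov_x = 10, fov_y = 10, z_range = 10,
                               n_x = 8, n_y = 8, n_planes = 2, frame_rate = 2)
  expect_error(generate_brain(tiny, 500, seed = 1), "achieved")
})

test_that("a single clean event decays with the reporter time constant", {
  gt <- generate_brain(geom_small, 1, seed = 2, responsive_fraction = 1)
  prot <- stimulus_protocol(onsets = 10, stim_duration = 1e-3)
  model <- activity_model(noise = "none", baseline_rate = 0,
                          stim_response_prob = 1, tau_decay = 3.5,
                          photon_gain = 100, baseline_F0 = 20)
  motif1 <- list(one = list(offsets_frac = 0, rel_amp = 1, habituation = 1))
  gt$amplitude[1] <- 1
  tr <- generate_activity(gt, prot, model, duration = 60, rate = 10,
                          seed = 3, motifs = motif1)
  v <- as.numeric(tr[1, ])
  peak <- which.max(v)
  expect_equal((peak - 1) / 10, 10, tolerance = 0.11)   # peaks at t = 10 s
  # e-folding: one tau later the transient has decayed by 1/e
  tau_samples <- 3.5 * 10
  expect_equal(v[peak + tau_samples] - 20, (v[peak] - 20) * exp(-1),
               tolerance = 0.02 * (v[peak] - 20))
})

test_that("a responsive cell with unit probability follows every presentation", {
  gt <- generate_brain(geom_small, 1, seed = 4, responsive_fraction = 1)
  prot <- looming_protocol()                     # 10 presentations, 150 s apart
  model <- activity_model(noise = "none", baseline_rate = 0,
                          stim_response_prob = 1)
  tr <- generate_activity(gt, prot, model, duration = 1800, rate = 1, seed = 5)
  ev <- attr(tr, "events")[[1]]
  m <- default_motifs()[[gt$motif[1]]]
  expect_equal(nrow(ev), 10 * length(m$offsets_frac))
  # every event lies inside a presentation epoch
  inside <- vapply(ev$time, function(t)
    any(t >= prot$presentations$onset - 1e-9 &
        t <= prot$presentations$offset + 1e-9), logical(1))
  expect_true(all(inside))
  # event-count conservation across many cells
  gt10 <- generate_brain(geom_small, 10, seed = 6, responsive_fraction = 1)
  tr10 <- generate_activity(gt10, prot, model, duration = 1800, rate = 1,
                            seed = 7)
  evs <- attr(tr10, "events")
  per_cell <- vapply(seq_len(10), function(i) {
    m <- default_motifs()[[gt10$motif[i]]]
    nrow(evs[[i]]) / length(m$offsets_frac)
  }, numeric(1))
  expect_equal(per_cell, rep(10, 10))            # presentations x cells
})

test_that("gaussian noise model has the stated sample SD", {
  gt <- generate_brain(geom_small, 1, seed = 8, responsive_fraction = 0)
  prot <- stimulus_protocol(numeric(0), numeric(0))
  model <- activity_model(noise = "gaussian", gaussian_sd = 1,
                          baseline_rate = 0)
  tr <- generate_activity(gt, prot, model, duration = 2000, rate = 1, seed = 9)
  expect_equal(stats::sd(tr[1, ]), 1, tolerance = 0.1)
})

test_that("rendering an empty brain yields only background and noise", {
  gt <- generate_brain(geom_small, 0, seed = 1)
  tr <- trace_matrix(matrix(numeric(0), nrow = 0, ncol = 10), rate = 1)
  st <- render_acquisition(gt, geom_small, tr,
                           optics = list(sigma_xy = 1.5, sigma_z = 4),
                           background = 2)
  expect_true(all(st$frames == 2))
  st_noisy <- render_acquisition(gt, geom_small, tr,
                                 optics = list(sigma_xy = 1.5, sigma_z = 4),
                                 background = 2, poisson_noise = TRUE,
                                 seed = 2)
  expect_equal(mean(st_noisy$frames), 2, tolerance = 0.1)
  expect_error(render_acquisition(gt, geom_small, tr,
                                  optics = list(sigma_xy = 0, sigma_z = 4)),
               "positive")
})

test_that("a cell is brightest in the plane whose row-z is nearest its depth", {
  geom <- acquisition_geometry(fov_x = 60, fov_y = 60, z_range = 180,
                               n_x = 32, n_y = 32, n_planes = 30,
                               frame_rate = 30)
  gt <- generate_brain(geom, 1, seed = 3, responsive_fraction = 0)
  gt$cell_positions[1, ] <- c(30, 30, 91)
  tr <- trace_matrix(matrix(100, nrow = 1, ncol = 2), rate = 1)
  st <- render_acquisition(gt, geom, tr,
                           optics = list(sigma_xy = 2, sigma_z = 5),
                           n_volumes = 1)
  plane_sum <- apply(st$frames, 3, sum)
  row_idx <- round(30 / geom$pixel_pitch_y + 0.5)
  z_focus <- vapply(0:29, function(p) row_z(geom, p, row_idx - 1), numeric(1))
  expect_equal(which.max(plane_sum), which.min(abs(z_focus - 91)))
})

test_that("planted motion shows up at the cross-correlation peak", {
  sc <- make_small_scene(n_cells = 15, seed = 11)
  n_frames <- 6 * 3
  motion <- matrix(0, n_frames, 2)
  motion[13:18, ] <- matrix(rep(c(3, -2), each = 6), ncol = 2)  # volume 3
  st <- render_acquisition(sc$gt, sc$geom,
                           trace_matrix(matrix(100, nrow = 15, ncol = 3),
                                        rate = 1),
                           optics = list(sigma_xy = 2, sigma_z = 4),
                           n_volumes = 3, motion = motion)
  # same plane, shifted volume vs unshifted volume
  f0 <- st$frames[, , 1]
  fk <- st$frames[, , 13]
  expect_equal(oracle_xcorr_shift(f0, fk), c(3, -2))
})

test_that("bead stacks render at the planted position and recover sigma", {
  beads <- generate_bead_stack(sigma_xy = 0.54, sigma_z = 3,
                               voxel_size = c(0.1, 0.1, 0.3),
                               extent = c(12, 12, 48), n_beads = 1, seed = 1)
  tr <- beads$truth
  pk <- arrayInd(which.max(beads$stack), dim(beads$stack))
  expect_equal((pk[2] - 0.5) * 0.1, tr$x, tolerance = 0.1)
  expect_equal((pk[1] - 0.5) * 0.1, tr$y, tolerance = 0.1)
  expect_equal((pk[3] - 0.5) * 0.3, tr$z, tolerance = 0.3)
  # lateral FWHM recovers 2 sqrt(2 ln 2) * 0.54 ~ 1.27 um within 5%
  m <- measure_beads(beads, axis = "x")
  expect_equal(m$fwhm, 2 * sqrt(2 * log(2)) * 0.54, tolerance = 0.05)
  # seed repeatability
  beads2 <- generate_bead_stack(sigma_xy = 0.54, sigma_z = 3,
                                voxel_size = c(0.1, 0.1, 0.3),
                                extent = c(12, 12, 48), n_beads = 1, seed = 1)
  expect_identical(beads$stack, beads2$stack)
})

test_that("generate_lut_points covers the range and feeds an exact fit", {
  pts <- generate_lut_points(n_points = 8, seed = 1)
  expect_equal(nrow(pts), 8)
  expect_equal(range(pts$z), c(0, 233))
  expect_error(generate_lut_points(n_points = 5), ">= 7")
  # noise-free points on a degree <= 5 curve: downstream fit is exact
  curve5 <- function(z) 30 + 0.5 * z + 1e-3 * z^2
  pts0 <- generate_lut_points(curve5, n_points = 9, noise_sd = 0, seed = 2)
  cal <- fit_lut(pts0)
  rel <- abs(current_at(cal, pts0$z / 233) - pts0$I) / abs(pts0$I)
  expect_lt(max(rel), 1e-9)
})

test_that("rendered single-cell trace round-trips with the input trace", {
  geom <- acquisition_geometry(fov_x = 40, fov_y = 40, z_range = 12,
                               n_x = 32, n_y = 32, n_planes = 2,
                               frame_rate = 2)
  gt <- generate_brain(geom, 1, seed = 21, responsive_fraction = 1)
  gt$cell_positions[1, ] <- c(20, 20, 3)
  prot <- stimulus_protocol(onsets = c(5, 15, 25), stim_duration = 2)
  model <- activity_model(noise = "none", baseline_rate = 0.1,
                          stim_response_prob = 1, photon_gain = 100)
  tr <- generate_activity(gt, prot, model, duration = 40, rate = 1, seed = 22)
  st <- render_acquisition(gt, geom, tr,
                           optics = list(sigma_xy = 2, sigma_z = 4),
                           poisson_noise = TRUE, seed = 23)
  planes <- deinterleave(st)
  # ROI around the cell in plane 0 (nearest its z)
  px <- round(20 / geom$pixel_pitch_x + 0.5)
  sub <- planes[[1]]$frames[(px - 2):(px + 2), (px - 2):(px + 2), ]
  roi_trace <- apply(sub, 3, mean)
  expect_gte(stats::cor(roi_trace, as.numeric(tr[1, seq_along(roi_trace)])),
             0.95)
})

test_that("generators are deterministic under a fixed seed", {
  a <- generate_activity(generate_brain(geom_small, 5, seed = 1),
                         looming_protocol(), activity_model(),
                         duration = 1800, rate = 1, seed = 2)
  b <- generate_activity(generate_brain(geom_small, 5, seed = 1),
                         looming_protocol(), activity_model(),
                         duration = 1800, rate = 1, seed = 2)
  expect_identical(unclass(a), unclass(b))
  m1 <- generate_motion(50, seed = 9)
  m2 <- generate_motion(50, seed = 9)
  expect_identical(m1, m2)
  expect_equal(m1[1, ], c(0, 0))
  expect_true(all(abs(m1) <= 3))
})
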