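make_stream <- function(n_frames, ny = 16, nx = 20, seed = 1) {
  set.seed(seed)
  array(stats::runif(ny * nx * n_frames), dim = c(ny, nx, n_frames))
}

test_that("deinterleave assigns frames to planes and drops stragglers", {
  s <- make_stream(90)
  planes <- deinterleave(s, n_planes = 30)
  expect_length(planes, 30)
  expect_true(all(vapply(planes, function(p) dim(p$frames)[3], numeric(1)) == 3))
  expect_equal(attr(planes, "dropped_frames"), 0)

  s2 <- make_stream(95)
  planes2 <- deinterleave(s2, n_planes = 30)
  expect_equal(attr(planes2, "dropped_frames"), 5)
  expect_true(all(vapply(planes2, function(p) dim(p$frames)[3], numeric(1)) == 3))

  expect_error(deinterleave(s, n_planes = 0), "positive")
  expect_error(deinterleave(make_stream(10), n_planes = 30), "shorter")
})

test_that("re-interleaving reproduces the retained input exactly", {
  s <- make_stream(95)
  planes <- deinterleave(s, n_planes = 30)
  expect_identical(reinterleave(planes), s[, , 1:90])
})

test_that("deinterleave discards the initial thermal-drift window", {
  s <- make_stream(150)
  planes <- deinterleave(s, n_planes = 30, discard_initial = 2,
                         frame_rate = 30)   # 2 s at 30 Hz = 2 volumes
  expect_equal(attr(planes, "dropped_volumes"), 2)
  expect_equal(dim(planes[[1]]$frames)[3], 3)
  expect_identical(planes[[1]]$frames[, , 1], s[, , 61])
  expect_error(deinterleave(s, n_planes = 30, discard_initial = 10,
                            frame_rate = 30), "no complete volume")
})

test_that("plane timestamps step by n_planes / frame_rate", {
  st <- render_acquisition(
    generate_brain(acquisition_geometry(fov_x = 20, fov_y = 20, z_range = 10,
                                        n_x = 8, n_y = 8, n_planes = 2,
                                        frame_rate = 2), 0, seed = 1),
    acquisition_geometry(fov_x = 20, fov_y = 20, z_range = 10, n_x = 8,
                         n_y = 8, n_planes = 2, frame_rate = 2),
    trace_matrix(matrix(numeric(0), 0, 5), rate = 1),
    optics = list(sigma_xy = 1, sigma_z = 2))
  planes <- deinterleave(st)
  expect_equal(diff(planes[[1]]$timestamps), rep(1, 4))
  expect_equal(planes[[2]]$timestamps[1] - planes[[1]]$timestamps[1], 0.5)
})

test_that("motion correction recovers planted integer shifts exactly", {
  base <- make_small_scene(n_cells = 10, seed = 31)
  st <- render_acquisition(base$gt, base$geom,
                           trace_matrix(matrix(100, 10, 1), rate = 1),
                           optics = list(sigma_xy = 2, sigma_z = 4),
                           n_volumes = 1)
  ref <- st$frames[, , 1]
  set.seed(42)
  n_cases <- 100
  shifts <- cbind(sample(-10:10, n_cases, TRUE), sample(-10:10, n_cases, TRUE))
  ok <- vapply(seq_len(n_cases), function(i) {
    frames <- array(c(ref, shift_image(ref, c(shifts[i, 2], shifts[i, 1]))),
                    dim = c(dim(ref), 2))
    mc <- motion_correct(frames, reference = "first")
    all(attr(mc, "applied_shifts")[2, ] == shifts[i, ]) &&
      max(abs(mc[, , 2] - ref)) < 1e-8
  }, logical(1))
  expect_equal(mean(ok), 1)                      # 100% exact recovery
})

test_that("zero motion and subpixel motion are estimated within tolerance", {
  base <- make_small_scene(n_cells = 10, seed = 33)
  st <- render_acquisition(base$gt, base$geom,
                           trace_matrix(matrix(100, 10, 1), rate = 1),
                           optics = list(sigma_xy = 2, sigma_z = 4),
                           n_volumes = 1)
  ref <- st$frames[, , 1]
  frames <- array(c(ref, ref), dim = c(dim(ref), 2))
  mc <- motion_correct(frames, reference = "first")
  expect_lt(max(abs(attr(mc, "applied_shifts"))), 0.1)

  sub <- shift_image(ref, c(0.5, 0.5))
  frames2 <- array(c(ref, sub), dim = c(dim(ref), 2))
  mc2 <- motion_correct(frames2, reference = "first")
  expect_lt(max(abs(attr(mc2, "applied_shifts")[2, ] - c(0.5, 0.5))), 0.2)

  expect_error(motion_correct(array(1, c(4, 4, 1))), "at least 2")
  bad <- array(NaN, c(4, 4, 2))
  expect_error(motion_correct(bad), "non-finite")
})

test_that("running average matches its filter definition", {
  expect_equal(running_average(rep(5, 10), 3), rep(5, 10))  # constant
  imp <- c(0, 0, 0, 1, 0, 0, 0)
  expect_equal(running_average(imp, 3),
               c(0, 0, 1 / 3, 1 / 3, 1 / 3, 0, 0))
  x <- stats::rnorm(20)
  expect_identical(running_average(x, 1), x)                # identity
  expect_error(running_average(x, 2), "odd")
  # edges use shrunken windows
  expect_equal(running_average(c(1, 2, 3), 3), c(1.5, 2, 2.5))
  # smoothing conserves the mean up to the shrunken-edge correction, an
  # O(window / n) term with a closed form for window 3
  y <- c(2, stats::rnorm(30), 3)
  n <- length(y)
  edge_term <- ((y[2] - y[1]) + (y[n - 1] - y[n])) / (6 * n)
  expect_equal(mean(running_average(y, 3)), mean(y) + edge_term,
               tolerance = 1e-12)
  # and exactly for flat edges
  yf <- c(1, 1, stats::rnorm(30), 2, 2)
  expect_equal(mean(running_average(yf, 3)), mean(yf), tolerance = 1e-12)
  # matrix form smooths each row
  m <- rbind(imp, imp)
  sm <- running_average(trace_matrix(m, rate = 1), 3)
  expect_equal(as.numeric(sm[1, ]), running_average(imp, 3))
})

test_that("noise floor averages per-segment SDs", {
  segs <- split(1:320, rep(1:16, each = 20))
  expect_equal(noise_floor(rep(7, 400), segs), 0)
  set.seed(5)
  tr <- stats::rnorm(2000)
  expect_equal(noise_floor(tr, segs), 1, tolerance = 0.15)
  expect_error(noise_floor(tr, list()), "non-empty")
  expect_error(noise_floor(tr, list(5L)), ">= 2 samples")
  expect_error(noise_floor(tr, list(1999:2001)), "outside")
})

test_that("pre_stimulus_segments builds 16 pre-onset windows by default", {
  prot <- looming_protocol(n_presentations = 20, first_onset = 100)
  segs <- pre_stimulus_segments(prot, rate = 1, segment_length = 20)
  expect_length(segs, 16)
  expect_length(segs[[1]], 20)
  expect_equal(max(segs[[1]]), 100)   # ends right at the first onset
})
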