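drift_track <- function(n, x0 = 10, y0 = 32, dx = 2, dy = 0)
  data.frame(frame = 1:n, x = x0 + dx * (0:(n - 1)), y = y0 + dy * (0:(n - 1)))

test_that("the temporal median recovers a particle-free background", {
  # static scene: background equals any frame
  static <- image_stack(array(rep(matrix(runif(64), 8, 8), 5), c(8, 8, 5)))
  expect_equal(median_background(static), static$frames[, , 1])
  # a fast-moving blob is near any given pixel in a minority of frames
  stack <- render_stack(list(drift_track(12, x0 = 5, dx = 5)),
                        dims = c(64, 64), amplitude = 1, sigma = 2,
                        background_level = 0.2, noise_sd = 0)
  bg <- median_background(stack)
  expect_equal(bg, matrix(0.2, 64, 64), tolerance = 1e-6)
  # randomized stack agrees with a per-pixel sort-based oracle
  set.seed(6)
  arr <- array(runif(5 * 4 * 7), c(5, 4, 7))
  got <- median_background(image_stack(arr))
  for (i in 1:5) for (j in 1:4) {
    v <- sort(arr[i, j, ])
    expect_identical(got[i, j], v[4])
  }
  expect_error(median_background(image_stack(arr[, , 1:2])), "at least 3")
})

test_that("connected-component labelling is 8-connected", {
  m <- matrix(FALSE, 6, 6)
  m[cbind(1:4, 1:4)] <- TRUE           # a diagonal line: one 8-conn component
  lab <- depspring:::label_components(m)
  expect_identical(max(lab), 1L)
  m[6, 6] <- TRUE                      # an isolated pixel two steps away
  expect_identical(max(depspring:::label_components(m)), 2L)
})

test_that("thresholded detection finds blob centroids", {
  bg <- matrix(0.2, 64, 64)
  stack <- render_stack(list(data.frame(frame = 1, x = 20.5, y = 40.5)),
                        dims = c(64, 64), amplitude = 1, sigma = 2,
                        background_level = 0.2, noise_sd = 0)
  det <- detect_particles(stack$frames[, , 1], bg, threshold = 0.1)
  expect_identical(nrow(det), 1L)
  # a symmetric blob at a half-integer position: centroid is exact
  expect_lt(abs(det$x - 20.5), 0.05)
  expect_lt(abs(det$y - 40.5), 0.05)
  # identical frame and background: nothing to detect
  expect_identical(nrow(detect_particles(bg, bg, threshold = 0.05)), 0L)
  # two blobs 50 px apart resolve separately
  two <- render_stack(list(data.frame(frame = 1, x = 7, y = 10),
                           data.frame(frame = 1, x = 57, y = 10)),
                      dims = c(64, 64), amplitude = 1, sigma = 2,
                      background_level = 0.2, noise_sd = 0)
  expect_identical(nrow(detect_particles(two$frames[, , 1], bg, 0.1)), 2L)
  # detection count is monotone non-increasing in the threshold
  set.seed(15)
  noisy <- two$frames[, , 1] + rnorm(64 * 64, sd = 0.05)
  counts <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), function(th)
    nrow(detect_particles(pmax(noisy, 0), bg, th, min_area = 1)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("greedy nearest-neighbor linking builds and separates tracks", {
  # one drifting blob: a single full-length track
  det <- drift_track(10)
  tracks <- link_tracks(det, max_displacement = 5)
  expect_identical(length(tracks), 1L)
  expect_identical(nrow(tracks[[1]]), 10L)
  expect_equal(tracks[[1]]$x, det$x)
  # crossing paths separated beyond the limit at the crossing: no swap
  a <- data.frame(frame = rep(1:5, 2),
                  x = c(1:5, 5:1) * 10,
                  y = rep(c(10, 40), each = 5))
  tracks2 <- link_tracks(a, max_displacement = 15)
  expect_identical(length(tracks2), 2L)
  expect_equal(tracks2[[1]]$y, rep(10, 5))
  expect_equal(tracks2[[2]]$y, rep(40, 5))
  # empty detections: no tracks
  expect_identical(
    length(link_tracks(data.frame(frame = integer(0), x = numeric(0),
                                  y = numeric(0)), 5)), 0L)
  # pixel/time conversion metadata
  expect_equal(tracks[[1]]$x_m, det$x * 1e-6)
  expect_equal(tracks[[1]]$t_s, det$frame * 0.05)
})

test_that("render-detect-link round-trips ground truth at high SNR", {
  truth <- drift_track(100, x0 = 5, y0 = 20, dx = 0.5, dy = 0.3)
  # noise-free: essentially exact
  clean <- render_stack(list(truth), dims = c(64, 64), amplitude = 1,
                        sigma = 2, background_level = 0.1, noise_sd = 0)
  det <- detect_stack(clean, threshold = 0.2)
  tr <- link_tracks(det, max_displacement = 3)
  expect_identical(length(tr), 1L)
  expect_identical(nrow(tr[[1]]), 100L)
  # fractional positions leave a small pixel-grid centroid bias
  expect_lt(max(abs(tr[[1]]$x - truth$x)), 0.25)
  expect_lt(max(abs(tr[[1]]$y - truth$y)), 0.25)
  # SNR 10 (amplitude / noise sd): >= 95% coverage, <= 0.5 px RMSE
  snr10 <- render_stack(list(truth), dims = c(64, 64), amplitude = 1,
                        sigma = 2, background_level = 0.1, noise_sd = 0.1,
                        seed = 8)
  det10 <- detect_stack(snr10, threshold = 0.3)
  tr10 <- link_tracks(det10, max_displacement = 3)
  main <- tr10[[which.max(vapply(tr10, nrow, integer(1)))]]
  expect_gte(nrow(main), 95)
  hit <- merge(main, truth, by = "frame", suffixes = c("", "_true"))
  rmse <- sqrt(mean((hit$x - hit$x_true)^2 + (hit$y - hit$y_true)^2))
  expect_lte(rmse, 0.5)
  # seed determinism of the renderer
  again <- render_stack(list(truth), dims = c(64, 64), amplitude = 1,
                        sigma = 2, background_level = 0.1, noise_sd = 0.1,
                        seed = 8)
  expect_identical(snr10$frames, again$frames)
})

test_that("image stacks read back from multi-page TIFF", {
  stack <- render_stack(list(drift_track(4)), dims = c(32, 32),
                        amplitude = 0.6, sigma = 2, background_level = 0.2,
                        noise_sd = 0)
  path <- withr::local_tempfile(fileext = ".tif")
  frames <- lapply(1:4, function(k) pmin(stack$frames[, , k], 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 16)
  back <- read_stack_tiff(path, frame_interval = 0.05, pixel_size = 1e-6)
  expect_identical(dim(back$frames), c(32L, 32L, 4L))
  expect_equal(back$frames[, , 2], frames[[2]], tolerance = 1e-4)
})
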