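# Movie loading, session container round-trips, ephys alignment/decimation,
# ROI import and translation.

test_that("multipage TIFF round-trips through write_image/load_image", {
  set.seed(11)
  stack <- array(sample(0:4095, 10 * 64 * 64 * 2, replace = TRUE),
                 c(10, 64, 64, 2))
  s <- new_imaging_session(stack, sampling_interval = 0.5,
                           channel_roles = c(green = 1, red = 2))
  f <- withr::local_tempfile(fileext = ".tif")
  write_image(s, f)
  s2 <- load_image(f, n_channels = 2, sampling_interval = 0.5)
  expect_equal(s2$n_frames, 10)
  expect_equal(s2$n_channels, 2)
  expect_equal(s2$stack, stack, ignore_attr = TRUE)

  # single page, single channel
  s1 <- new_imaging_session(array(7, c(1, 8, 8, 1)))
  f1 <- withr::local_tempfile(fileext = ".tif")
  write_image(s1, f1)
  r1 <- load_image(f1)
  expect_equal(r1$n_frames, 1)
  expect_equal(r1$n_channels, 1)
})

test_that("corrupt or unsupported TIFF input fails loudly", {
  s <- new_imaging_session(array(100, c(6, 16, 16, 1)))
  f <- withr::local_tempfile(fileext = ".tif")
  write_image(s, f)
  # truncate mid-file: last page becomes unreadable
  sz <- file.size(f)
  con <- file(f, "r+b")
  truncated <- readBin(con, "raw", n = floor(sz * 0.6))
  close(con)
  f2 <- withr::local_tempfile(fileext = ".tif")
  writeBin(truncated, f2)
  expect_error(load_image(f2), class = "fluopipe_load_error")
  expect_error(load_image(f, n_channels = 3), class = "fluopipe_format_error")
  expect_error(load_image(tempfile()), class = "fluopipe_load_error")
})

test_that("session save/load is the identity on every stored field", {
  st <- small_state(seed = 5)
  st$truth <- NULL
  f <- withr::local_tempfile(fileext = ".rds")
  save_session(st, f)
  st2 <- load_session(f)
  expect_identical(st2$session$stack, st$session$stack)
  expect_identical(st2$rois, st$rois)
  expect_identical(st2$traces, st$traces)
  expect_identical(names(st2), names(st))

  # image-only state
  s <- constant_session()
  f2 <- withr::local_tempfile(fileext = ".rds")
  save_session(list(session = s), f2)
  expect_identical(load_session(f2)$session, s)
})

test_that("wrong magic or schema version raises a versioned error", {
  f <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(magic = "something-else"), f)
  expect_error(load_session(f), class = "fluopipe_version_error")
  saveRDS(list(magic = "fluopipe-session", version = 99L, state = list()), f)
  expect_error(load_session(f), "version", class = "fluopipe_version_error")
  writeLines("not rds", f)
  expect_error(load_session(f), class = "fluopipe_version_error")
})

test_that("ephys loading extracts the aligned segment decimated by 10", {
  fs <- 10000
  t_rec <- seq(0, 70, by = 1 / fs)[-1]
  raw <- structure(list(samples = sin(2 * pi * 5 * t_rec), sampling_rate = fs,
                        t_start = 0, markers = NULL), class = "RawEphys")
  s <- constant_session(nf = 600, dt = 0.1)    # 60 s session
  e <- load_ephys(raw, s)
  expect_length(e$samples, 60000)
  expect_equal(e$sampling_rate, 1000)
  expect_equal(e$native_rate / e$sampling_rate, 10)
  # spectral peak of a sub-Nyquist tone is preserved (periodogram oracle)
  expect_equal(fft_peak_freq(e$samples, e$sampling_rate), 5, tolerance = 0.02)
  expect_equal(fft_peak_freq(raw$samples[1:600000], fs), 5, tolerance = 0.02)

  # session outside the recorded span
  expect_error(load_ephys(raw, s, t_start = 50), class = "fluopipe_alignment_error")
})

test_that("tagged markers delimit segments with start-of-segment semantics", {
  raw <- list(samples = numeric(0), sampling_rate = 1000,
              markers = data.frame(time = c(2, 70), tag = c("s1", "s2")))
  expect_equal(find_segment_by_marker(raw, "s2", 60), c(70, 130))
  expect_error(find_segment_by_marker(raw, "s3", 60),
               class = "fluopipe_marker_error")
  raw$markers <- data.frame(time = c(2, 70), tag = c("s1", "s1"))
  expect_error(find_segment_by_marker(raw, "s1", 60), "2 times",
               class = "fluopipe_marker_error")
})

test_that("plain-text ephys format round-trips samples, rate and markers", {
  eph <- list(samples = round(rnorm(500), 6), sampling_rate = 250,
              t_start = 0,
              markers = data.frame(time = 0.4, tag = "stim on"))
  f <- withr::local_tempfile(fileext = ".txt")
  write_ephys_text(eph, f)
  r <- read_ephys_text(f)
  expect_equal(r$samples, eph$samples, tolerance = 1e-9)
  expect_equal(r$sampling_rate, 250)
  expect_equal(r$markers$time, 0.4)
  expect_equal(r$markers$tag, "stim on")
})

test_that("ROI translation is rigid, reversible and flags clipped ROIs", {
  rs <- roiset_from_pixels(list(blob_px(c(12, 12), 25)), c(40, 40))
  expect_identical(shift_rois(rs, 0, 0)$rois[[1]]$pixels, rs$rois[[1]]$pixels)

  sh <- shift_rois(rs, 2, 3)
  expect_equal(sh$rois[[1]]$area, 25)
  expect_equal(unname(sh$rois[[1]]$centroid - rs$rois[[1]]$centroid), c(2, 3))

  # there-and-back identity for interior ROIs
  back <- shift_rois(shift_rois(rs, 5, -4), -5, 4)
  expect_equal(back$rois[[1]]$pixels, rs$rois[[1]]$pixels)

  # 90% pushed off the field: clipped flag
  clipped <- shift_rois(rs, -10, 0)
  expect_true("clipped" %in% clipped$rois[[1]]$flags)
  expect_lt(clipped$rois[[1]]$area, 25)
})

test_that("ROIs import from a saved session and re-render on the target", {
  st <- small_state(seed = 6)
  f <- withr::local_tempfile(fileext = ".rds")
  save_session(list(session = st$session, rois = st$rois), f)
  imported <- import_rois(st$session, f)
  expect_identical(imported$labels, st$rois$labels)
  expect_equal(n_rois(imported), n_rois(st$rois))
  # a session without ROIs cannot provide them
  f2 <- withr::local_tempfile(fileext = ".rds")
  save_session(list(session = st$session), f2)
  expect_error(import_rois(st$session, f2), class = "fluopipe_import_error")
})
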