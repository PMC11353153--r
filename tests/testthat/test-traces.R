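# Fluorescence trace extraction, dF/F0, dG/R and smoothing.

test_that("F is the pixelwise ROI mean per frame and channel", {
  s <- constant_session(value = 5, nf = 4, h = 16, w = 16, nc = 2)
  rs <- roiset_from_pixels(list(blob_px(c(8, 8), 9)), c(16, 16))
  tr <- compute_F(s, rs)
  expect_true(all(tr$F == 5))

  stack <- array(0, c(1, 8, 8, 1))
  px <- cbind(c(2, 2, 3, 3), c(2, 3, 2, 3))
  stack[1, , , 1][px] <- c(1, 2, 3, 4)
  s2 <- new_imaging_session(stack)
  tr2 <- compute_F(s2, roiset_from_pixels(list(px), c(8, 8)))
  expect_equal(as.numeric(tr2$F[1, 1, 1]), 2.5)
})

test_that("planted sinusoid amplitude is recovered by ROI averaging", {
  mv <- make_movie(n_cells = 4, fov = c(64, 64), fs = 20, duration = 10,
                   freqs = rep(1.5, 4), amp = 0.4, noise_sd = 10, seed = 13)
  ref <- make_reference(mv$session, method = "average", channel = "green")
  rs <- extract_rois(threshold_reference(ref, "otsu"), 30, 2000)
  tr <- compute_F(mv$session, rs)
  tr <- compute_dff(tr, control_range = seq_along(tr$time),
                    background = "none")
  # noise on the ROI mean shrinks by sqrt(area); amplitude ~ 0.4 in dff units
  amp_hat <- apply(tr$dff, 2, function(x) sqrt(2) * sd(x))
  expect_equal(unname(amp_hat), rep(0.4, 4), tolerance = 0.1)
})

test_that("dF/F0 matches its closed-form cases", {
  mk_traces <- function(Fgreen) {
    nt <- length(Fgreen)
    structure(list(F = array(Fgreen, c(nt, 1, 1)), roi_ids = 1L,
                   time = seq_len(nt) - 1, sampling_interval = 1,
                   channel_roles = c(green = 1),
                   background_auto = matrix(0, nt, 1), smoothing_window = 0L),
              class = "TraceSet")
  }
  # constant trace -> identically zero
  tr <- compute_dff(mk_traces(rep(42, 50)), background = "none")
  expect_true(all(tr$dff == 0))
  # doubling from baseline -> 1
  tr <- compute_dff(mk_traces(c(rep(10, 5), rep(20, 5))),
                    control_range = 1:5, background = "none")
  expect_equal(unname(tr$dff[6:10, 1]), rep(1, 5))
  # four-frame worked example
  tr <- compute_dff(mk_traces(c(10, 10, 20, 15)), control_range = 1:2,
                    background = "none")
  expect_equal(unname(tr$dff[, 1]), c(0, 0, 1, 0.5))
  expect_equal(unname(tr$F0), 10)
  # non-positive baseline is flagged, not fatal
  expect_warning(tr <- compute_dff(mk_traces(c(-5, -5, 3, 4)),
                                   control_range = 1:2, background = "none"),
                 "F0")
  expect_true(all(is.na(tr$dff)))
})

test_that("background modes remove additive offsets from dF/F0", {
  nt <- 40
  base <- 100 + 20 * sin(2 * pi * (1:nt) / 20)
  drift <- 30 + 5 * cos(2 * pi * (1:nt) / 40)
  tr0 <- structure(list(F = array(base, c(nt, 1, 1)), roi_ids = 1L,
                        time = 1:nt, sampling_interval = 1,
                        channel_roles = c(green = 1),
                        background_auto = matrix(drift, nt, 1),
                        smoothing_window = 0L), class = "TraceSet")
  trd <- tr0; trd$F <- array(base + drift, c(nt, 1, 1))
  clean <- compute_dff(tr0, background = "none")
  corrected <- compute_dff(trd, background = "auto")
  expect_equal(corrected$dff, clean$dff, tolerance = 1e-12)
  manual <- compute_dff(trd, background = "manual", bg_value = drift)
  expect_equal(manual$dff, clean$dff, tolerance = 1e-12)
})

test_that("scaling the stack scales F linearly and leaves dF/F0 unchanged", {
  mv <- make_movie(n_cells = 3, fov = c(48, 48), fs = 10, duration = 4,
                   seed = 14)
  ref <- make_reference(mv$session, method = "average", channel = "green")
  rs <- extract_rois(threshold_reference(ref, "otsu"), 30, 2000)
  tr1 <- compute_dff(compute_F(mv$session, rs), background = "none")
  s2 <- mv$session
  s2$stack <- s2$stack * 3.7
  tr2 <- compute_dff(compute_F(s2, rs), background = "none")
  expect_equal(tr2$F, 3.7 * tr1$F, tolerance = 1e-12)
  expect_equal(tr2$dff, tr1$dff, tolerance = 1e-10)
})

test_that("dG/R matches its closed forms and suppresses shared artefacts", {
  mk2 <- function(G, R) {
    nt <- length(G)
    structure(list(F = array(c(G, R), c(nt, 1, 2)), roi_ids = 1L,
                   time = seq_len(nt) - 1, sampling_interval = 1,
                   channel_roles = c(green = 1, red = 2),
                   background_auto = matrix(0, nt, 2), smoothing_window = 0L),
              class = "TraceSet")
  }
  tr <- compute_dgr(mk2(rep(70, 6), rep(140, 6)))
  expect_true(all(tr$dgr == 0))
  tr <- compute_dgr(mk2(c(50, 60), c(100, 100)))
  expect_equal(unname(tr$dgr[, 1]), c(0, 0.1))
  expect_warning(compute_dgr(mk2(c(50, 60), c(100, 0))), "red")

  # multiplicative artefact s(t) scaling both channels with constant true G:
  # dgr's artefact term shrinks by the red brightness, var(dff)/var(dgr)
  # ~ (R/G)^2, so with a bright red marker (as with SR-101) the artefact is
  # strongly suppressed in dG/R while dff shows s(t) at full size
  nt <- 200
  st <- 1 + 0.1 * sin(2 * pi * (1:nt) / 50)
  G <- 100 * st; R <- 400 * st
  tr <- compute_dgr(compute_dff(mk2(G, R), background = "none"))
  ratio <- var(tr$dff[, 1]) / var(tr$dgr[, 1])
  expect_gt(ratio, 10)
  expect_equal(ratio, (400 / 100)^2, tolerance = 0.25)
})

test_that("moving-average smoothing behaves at the edges and reduces noise", {
  mk <- function(x, cr = seq_along(x)) {
    nt <- length(x)
    tr <- structure(list(F = array(x, c(nt, 1, 1)), roi_ids = 1L,
                         time = seq_len(nt) - 1, sampling_interval = 1,
                         channel_roles = c(green = 1),
                         background_auto = matrix(0, nt, 1),
                         smoothing_window = 0L), class = "TraceSet")
    compute_dff(tr, control_range = cr, background = "none")
  }
  tr <- mk(rnorm(50) + 10)
  expect_equal(smooth_traces(tr, 1)$dff, tr$dff)
  expect_error(smooth_traces(tr, 4), class = "fluopipe_argument_error")
  expect_error(smooth_traces(tr, 51), class = "fluopipe_argument_error")

  imp <- mk(c(5, 5, 6, 5, 5), cr = 1:2)   # unit impulse on a flat baseline
  sm <- smooth_traces(imp, 3)
  expect_equal(unname(sm$dff[, 1]), c(0, 1, 1, 1, 0) / (3 * 5), tolerance = 1e-12)

  # white noise variance drops ~window-fold (Monte Carlo over seeds)
  ratios <- vapply(1:20, function(sd0) {
    set.seed(sd0)
    x <- rnorm(2000)
    tr <- mk(10 + x)
    sm <- smooth_traces(tr, 5)
    var(tr$dff[, 1]) / var(sm$dff[, 1])
  }, 0)
  expect_equal(mean(ratios), 5, tolerance = 0.2)

  # interior-dominated traces keep their mean
  long <- mk(10 + rnorm(1000))
  expect_equal(mean(smooth_traces(long, 7)$dff), mean(long$dff),
               tolerance = 1e-3)
})

test_that("traces export to long-format CSV", {
  st <- small_state(seed = 15)
  f <- withr::local_tempfile(fileext = ".csv")
  export_traces_csv(st$traces, f)
  d <- read.csv(f)
  expect_setequal(names(d), c("time", "roi_id", "channel", "F", "dff", "dgr"))
  expect_equal(nrow(d), length(st$traces$time) * length(st$traces$roi_ids) * 2)
})
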