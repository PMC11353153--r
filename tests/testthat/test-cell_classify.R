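# Cell validation rules (area/eccentricity/contrast), astrocyte-neuron
# classification, manual override precedence, annotation round-trip.

# ROI on a uniform field: ROI pixels get `inside`, everything else `around`
contrast_fixture <- function(px, shape, inside, around) {
  rs <- roiset_from_pixels(list(px), shape)
  ref <- matrix(around, shape[1], shape[2])
  ref[px] <- inside
  list(rs = rs, ref = ref)
}

test_that("validation applies the area, eccentricity and contrast rules", {
  shape <- c(60, 60)
  # all three criteria met
  fx <- contrast_fixture(blob_px(c(30, 30), 120), shape, 200, 50)
  v <- validate_roi(fx$rs$rois[[1]], fx$ref, fx$rs)
  expect_true(v$is_cell)
  expect_length(v$reasons, 0)

  # area of exactly 100 px fails: the rule is strictly "higher than"
  fx <- contrast_fixture(blob_px(c(30, 30), 100), shape, 200, 50)
  v <- validate_roi(fx$rs$rois[[1]], fx$ref, fx$rs)
  expect_false(v$is_cell)
  expect_equal(v$reasons, "area")
  expect_equal(fx$rs$rois[[1]]$area, 100)

  # elongated ellipse beyond the 0.85 eccentricity cutoff
  px <- ellipse_px(c(30, 30), 22, 9)       # e = sqrt(1-(9/22)^2) ~ 0.91
  fx <- contrast_fixture(px, shape, 200, 50)
  expect_gt(fx$rs$rois[[1]]$eccentricity, 0.85)
  v <- validate_roi(fx$rs$rois[[1]], fx$ref, fx$rs)
  expect_false(v$is_cell)
  expect_equal(v$reasons, "eccentricity")

  # contrast ratio 1.98 < 2 fails; exactly 2 passes ("at least two times")
  fx <- contrast_fixture(blob_px(c(30, 30), 120), shape, 99, 50)
  v <- validate_roi(fx$rs$rois[[1]], fx$ref, fx$rs)
  expect_false(v$is_cell)
  expect_equal(v$reasons, "contrast")
  fx <- contrast_fixture(blob_px(c(30, 30), 120), shape, 100, 50)
  expect_true(validate_roi(fx$rs$rois[[1]], fx$ref, fx$rs)$is_cell)
})

test_that("the vicinity ring excludes neighbouring ROIs", {
  shape <- c(40, 60)
  a <- blob_px(c(20, 20), 120)
  b <- blob_px(c(20, 34), 120)   # bright neighbour within the ring radius
  rs <- roiset_from_pixels(list(a, b), shape)
  ref <- matrix(50, shape[1], shape[2])
  ref[a] <- 120; ref[b] <- 5000
  v <- validate_roi(rs$rois[[1]], ref, rs)
  expect_true(v$is_cell)                 # neighbour must not inflate background
  expect_equal(v$vicinity_mean, 50)
})

test_that("red/green ratio splits valid cells into astrocytes and neurons", {
  shape <- c(60, 60)
  px <- list(blob_px(c(15, 15), 120), blob_px(c(15, 45), 120),
             blob_px(c(45, 15), 50))      # third fails validation (area)
  rs <- roiset_from_pixels(px, shape)
  g <- matrix(50, shape[1], shape[2])
  for (p in px) g[p] <- 200
  r <- matrix(10, shape[1], shape[2])
  r[px[[1]]] <- 600    # ratio 3.0 -> astrocyte
  r[px[[2]]] <- 20     # ratio 0.1 -> neuron
  r[px[[3]]] <- 600    # invalid -> not_cell regardless of ratio
  s <- new_imaging_session(array(rep(1, 2 * 60 * 60 * 2), c(2, 60, 60, 2)),
                           channel_roles = c(green = 1, red = 2))
  rs <- classify_cells(s, rs, g, r)
  expect_equal(rs$labels$label, c("astrocyte", "neuron", "not_cell"))
  expect_error(classify_cells(s, rs, g, NULL),
               class = "fluopipe_argument_error")

  # single-channel session: valid cells stay unclassified
  s1 <- new_imaging_session(array(1, c(2, 60, 60, 1)))
  rs1 <- classify_cells(s1, roiset_from_pixels(px[1:2], shape), g)
  expect_equal(rs1$labels$label, c("unclassified", "unclassified"))
})

test_that("manual overrides take precedence and survive re-classification", {
  st <- small_state(seed = 8)
  rs <- st$rois
  id <- rs$labels$roi_id[rs$labels$label == "astrocyte"][1]
  rs <- override_label(rs, id, "neuron")
  refG <- make_reference(st$session, method = "average", channel = "green")
  refR <- make_reference(st$session, method = "average", channel = "red")
  rs <- classify_cells(st$session, rs, refG, refR)
  i <- which(rs$labels$roi_id == id)
  expect_equal(rs$labels$label[i], "neuron")
  expect_equal(rs$labels$origin[i], "manual")
  expect_error(override_label(rs, 9999, "neuron"), class = "fluopipe_key_error")

  # not_cell override drops the ROI from recomputed traces
  rs2 <- override_label(rs, id, "not_cell")
  tr <- compute_F(st$session, rs2)
  expect_false(id %in% tr$roi_ids)

  # manual origin survives the session container round-trip
  f <- withr::local_tempfile(fileext = ".rds")
  save_session(list(rois = rs), f)
  expect_equal(load_session(f)$rois$labels$origin[i], "manual")
})

test_that("raising the area threshold never turns a non-cell into a cell", {
  st <- small_state(seed = 9)
  refG <- make_reference(st$session, method = "average", channel = "green")
  areas <- c(60, 100, 113, 150)
  was_cell <- rep(TRUE, n_rois(st$rois))
  for (a in areas) {
    p <- classification_params(min_area = a)
    now <- vapply(st$rois$rois, function(r)
      validate_roi(r, refG, st$rois, p)$is_cell, TRUE)
    expect_false(any(now & !was_cell))
    was_cell <- now
  }
})

test_that("cell crops export with a manifest and annotations import back", {
  st <- small_state(seed = 10)
  d <- withr::local_tempdir()
  mf <- export_cell_images(st$session, st$rois, d)
  manifest <- read.csv(mf)
  expect_equal(nrow(manifest), n_rois(st$rois))
  expect_true(all(file.exists(file.path(d, manifest$file))))

  # annotate 2 of 3; the third keeps its auto label
  ann <- withr::local_tempfile(fileext = ".csv")
  ids <- manifest$roi_id
  write.csv(data.frame(roi_id = ids[1:2], label = c("neuron", "astrocyte")),
            ann, row.names = FALSE)
  before <- st$rois$labels$label
  rs <- import_annotations(st$rois, ann)
  expect_equal(rs$labels$label[rs$labels$roi_id == ids[1]], "neuron")
  expect_equal(rs$labels$origin[rs$labels$roi_id %in% ids[1:2]],
               rep("imported", 2))
  expect_equal(rs$labels$label[rs$labels$roi_id == ids[3]],
               before[rs$labels$roi_id == ids[3]])

  # unknown id aborts and is named
  write.csv(data.frame(roi_id = 777, label = "neuron"), ann, row.names = FALSE)
  expect_error(import_annotations(st$rois, ann), "777",
               class = "fluopipe_import_error")
})
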