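test_that("measure_segments reports calibrated geometry per object", {
  m <- matrix(0L, 20, 20)
  m[5:14, 3:12] <- 1L                          # 10x10 square
  m[18, 18] <- 2L                              # single pixel
  img <- section_image(matrix(200, 20, 20), pixel_size = 1)
  segs <- measure_segments(m, img)
  expect_equal(nrow(segs), 2L)
  sq <- segs[segs$label == 1L, ]
  expect_equal(sq$area_um2, 100)
  expect_equal(sq$diameter_um, 2 * sqrt(100 / pi), tolerance = 1e-12)
  expect_equal(c(sq$x, sq$y), c(mean(2:11), mean(4:13)))  # 0-based centroid
  px <- segs[segs$label == 2L, ]
  expect_equal(px$pixel_count, 1L)
  expect_equal(c(px$x, px$y), c(17, 17))

  ## calibration scales area by pixel_size^2
  segs2 <- measure_segments(m, img, pixel_size = 0.5)
  expect_equal(segs2$area_um2[1], 25)

  expect_error(measure_segments(m, section_image(matrix(0, 5, 5))), "dimensions")
})

test_that("per-object areas match the generator's ground truth exactly", {
  sc <- generate_scene(scene_spec(n_neurons = 20, seed = 5))
  img <- prepare_image(sc$image, pixel_size = sc$spec$pixel_size)
  segs <- measure_segments(sc$mask, img)
  m <- merge(segs, sc$truth, by = "label")
  expect_equal(m$pixel_count, m$area_px)
})

test_that("grey threshold is the midpoint of object and background means", {
  img <- matrix(10, 10, 10)
  msk <- matrix(0L, 10, 10)
  msk[3:5, 3:5] <- 1L
  img[msk == 1L] <- 200
  expect_equal(grey_threshold(img, msk), 105)

  ## degenerate constant image: threshold equals that value, nothing can
  ## fall strictly below it
  img2 <- matrix(50, 10, 10)
  thr <- grey_threshold(img2, msk)
  expect_equal(thr, 50)
  segs <- measure_segments(msk, section_image(img2))
  fr <- apply_filters(segs, filter_config(), thr)
  expect_equal(nrow(fr$excluded), 0L)

  expect_error(grey_threshold(img, matrix(0L, 10, 10)), "no segmented")
  expect_error(grey_threshold(img, matrix(1L, 10, 10)), "background")
})

make_segments <- function(diam, area = NULL, grey = 200) {
  n <- length(diam)
  if (is.null(area)) area <- rep(100, n)
  data.frame(label = seq_len(n), pixel_count = 1L, area_um2 = area,
             diameter_um = diam, x = 0, y = 0, mean_grey = rep_len(grey, n))
}

test_that("size thresholds follow mean +/- multiplier*SD with boundaries kept", {
  ## diameters {8,10,12}: mean 10, SD 2 -> cutoffs 10 - 0.75*2 = 8.5 and
  ## 10 + 1.75*2 = 13.5
  fr <- apply_filters(make_segments(c(8, 10, 12)), filter_config(grey_rule = "off"))
  expect_equal(fr$thresholds_used$diam_lower, 8.5)
  expect_equal(fr$thresholds_used$diam_upper, 13.5)
  expect_equal(fr$excluded$reason, "too_small") # 8 < 8.5, the others within

  ## probes sitting exactly on a cutoff are kept (dyadic-exact sets: both
  ## have mean 20 and SD exactly 4, so the cutoffs 20 - 0.75*4 = 17 and
  ## 20 + 1.75*4 = 27 are float-exact)
  lo_set <- c(17, 14.5, 22.5, 22.5, 23.5)
  fr <- apply_filters(make_segments(lo_set), filter_config(grey_rule = "off"))
  expect_equal(fr$thresholds_used$diam_sd, 4)
  expect_equal(fr$thresholds_used$diam_lower, 17)
  expect_false(1L %in% fr$excluded$label)       # exactly at lower cutoff

  hi_set <- c(27, 17.5, 17.5, 18.5, 19.5)
  fr <- apply_filters(make_segments(hi_set), filter_config(grey_rule = "off"))
  expect_equal(fr$thresholds_used$diam_upper, 27)
  expect_false(1L %in% fr$excluded$label)       # exactly at upper cutoff

  ## strictly beyond a cutoff is excluded with the matching reason
  fr <- apply_filters(make_segments(c(16, 14.5, 22.5, 22.5, 23.5, 17)),
                      filter_config(grey_rule = "off"))
  expect_equal(fr$excluded$reason[fr$excluded$diameter_um ==
                                    min(fr$excluded$diameter_um)], "too_small")
})

test_that("exclusion reasons are single, first-hit, and partition the input", {
  ## speckle-grey object must be extracellular even though it is also tiny
  segs <- make_segments(c(2, 10, 11, 12), grey = c(20, 200, 200, 200))
  fr <- apply_filters(segs, filter_config(), threshold = 100)
  expect_equal(fr$excluded$reason[fr$excluded$label == 1L], "extracellular")
  expect_equal(nrow(fr$kept) + nrow(fr$excluded), nrow(segs))

  ## size stats are computed over grey-rule survivors only
  expect_equal(fr$thresholds_used$diam_mean, 11)

  ## area rule catches oversized-by-area objects that pass the diameter rule
  segs <- make_segments(rep(10, 6), area = c(100, 100, 100, 100, 100, 400))
  segs$diameter_um <- c(10, 10, 10, 10, 10, 10)
  fr <- apply_filters(segs, filter_config(grey_rule = "off"))
  expect_equal(fr$excluded$reason, "too_large_area")
})

test_that("filters degrade safely with fewer than two grey survivors", {
  segs <- make_segments(c(10, 11), grey = c(20, 200))
  expect_warning(fr <- apply_filters(segs, filter_config(), threshold = 100),
                 "size rules skipped")
  expect_equal(nrow(fr$kept), 1L)
  expect_equal(fr$excluded$reason, "extracellular")
})

test_that("filtering is monotone in its multipliers and grey rule", {
  sc <- contaminant_scene(seed = 21)
  img <- prepare_image(sc$image, pixel_size = sc$spec$pixel_size)
  segs <- measure_segments(sc$mask, img)
  thr <- grey_threshold(img, sc$mask)

  strict <- apply_filters(segs, filter_config(lower_diam_sd = 0.25,
                                              upper_diam_sd = 1.0,
                                              upper_area_sd = 1.0), thr)
  default <- apply_filters(segs, filter_config(), thr)
  ## decreasing any SD multiplier never grows the kept set
  expect_true(all(strict$kept$label %in% default$kept$label))

  off <- apply_filters(segs, filter_config(grey_rule = "off"))
  expect_false("extracellular" %in% off$excluded$reason)
})

test_that("planted contaminants are excluded with their expected reasons", {
  agree <- list(glia = c(0, 0), doublet = c(0, 0), speckle = c(0, 0),
                neuron = c(0, 0))
  for (seed in c(31, 32, 33)) {
    sc <- contaminant_scene(seed)
    res <- analyze_scene(sc)
    all_tab <- rbind(
      cbind(res$filter$kept, reason = "kept"),
      res$filter$excluded
    )
    m <- merge(all_tab, sc$truth, by = "label")
    expected <- c(neuron = "kept", glia = "too_small",
                  speckle = "extracellular")
    for (cls in names(expected)) {
      sel <- m$class == cls
      agree[[cls]] <- agree[[cls]] +
        c(sum(m$reason[sel] == expected[[cls]]), sum(sel))
    }
    sel <- m$class == "doublet"
    agree$doublet <- agree$doublet +
      c(sum(m$reason[sel] %in% c("too_large_diameter", "too_large_area")),
        sum(sel))
  }
  for (cls in names(agree))
    expect_gte(agree[[cls]][1] / agree[[cls]][2], 0.9)
})
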