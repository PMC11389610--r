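test_that("mean angular deviation matches closed forms", {
  expect_equal(mean_angular_deviation(c(90, 90, 90)), 0)
  expect_equal(mean_angular_deviation(c(60, 120)), 30)
  expect_equal(mean_angular_deviation(0), 90)          # axially farthest
  expect_equal(mean_angular_deviation(179), 89)
  expect_error(mean_angular_deviation(numeric()), "empty")

  ## sample-mean reference: symmetric data about 20 -> mean 20, dev 20/3
  expect_equal(axial_circular_mean(c(10, 20, 30)), 20, tolerance = 1e-10)
  expect_equal(mean_angular_deviation(c(10, 20, 30), reference = "sample_mean"),
               20 / 3, tolerance = 1e-10)
  ## axial wrap: {170, 10} straddle 0; axial mean is 0, not 90
  expect_equal(axial_circular_mean(c(170, 10)), 0, tolerance = 1e-10)
})

test_that("circular variance: limits and direct-summation oracle", {
  expect_equal(circular_variance(rep(37.5, 10)), 0)
  ## perfect axial uniformity: doubled {0, 90, 180, 270}
  expect_equal(circular_variance(c(0, 45, 90, 135)), 1, tolerance = 1e-12)
  set.seed(5)
  for (i in 1:10) {
    a <- runif(sample(5:200, 1), 0, 180)
    expect_equal(circular_variance(a), oracle_circular_variance(a),
                 tolerance = 1e-12)
    expect_equal(circular_variance(a, axial = FALSE),
                 oracle_circular_variance(a, axial = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(circular_variance(numeric()), "empty")
})

test_that("dev and var are permutation- and axis-invariant", {
  set.seed(11)
  a <- runif(300, 0, 180)
  p <- sample(a)
  shifted <- (a + 180 * rbinom(300, 1, 0.5)) %% 360   # add 180 to random half
  expect_equal(mean_angular_deviation(a), mean_angular_deviation(p))
  expect_equal(mean_angular_deviation(a), mean_angular_deviation(shifted))
  expect_equal(circular_variance(a), circular_variance(p))
  expect_equal(circular_variance(a), circular_variance(shifted))
  ## dev = 0 iff every angle is 90
  expect_gt(mean_angular_deviation(c(90, 90, 89)), 0)
  expect_identical(mean_angular_deviation(rep(90, 5)), 0)
})

test_that("axial variance decreases with von Mises concentration", {
  vars <- vapply(c(0.5, 2, 8), function(k) {
    circular_variance(generate_angle_sample(2000, mu = 90, kappa = k,
                                            seed = 100 + k))
  }, numeric(1))
  expect_true(all(diff(vars) < 0))
})

test_that("rose histogram counts are exact and half-open", {
  h <- rose_histogram(rep(90, 7), bin_width = 10)
  expect_equal(sum(h$count), 7)
  expect_equal(h$count[h$lo == 90], 7)

  expect_true(all(rose_histogram(numeric(), 10)$count == 0))

  h <- rose_histogram(0:179, bin_width = 10)
  expect_true(all(h$count == 10))

  ## boundary value falls in the bin it opens
  h <- rose_histogram(c(10, 19.999), bin_width = 10)
  expect_equal(h$count[h$lo == 10], 2)

  expect_error(rose_histogram(1:10, bin_width = 7), "divisor")
})

test_that("orientation line sampling takes one neuron per occupied square", {
  rec <- data.frame(label = 1L, x = 10, y = 10, coo_deg = 45)
  seg <- orientation_line_plot_data(rec, pixel_size = 1, grid_size = 220)
  expect_equal(nrow(seg), 1L)

  ## two neurons in one square: exactly one sampled, seed-determined
  rec2 <- data.frame(label = 1:2, x = c(10, 20), y = c(10, 20),
                     coo_deg = c(45, 135))
  s1 <- orientation_line_plot_data(rec2, seed = 5)
  s2 <- orientation_line_plot_data(rec2, seed = 5)
  expect_equal(nrow(s1), 1L)
  expect_identical(s1, s2)

  ## scene-wide: one segment per occupied square
  sc <- generate_scene(scene_spec(n_neurons = 30, seed = 17))
  res <- analyze_scene(sc)
  rec3 <- res$records[!is.na(res$records$coo_deg), ]
  grid <- 100
  seg3 <- orientation_line_plot_data(rec3, pixel_size = sc$spec$pixel_size,
                                     grid_size = grid, seed = 1)
  step <- grid / sc$spec$pixel_size
  occupied <- unique(paste(floor(rec3$x / step), floor(rec3$y / step)))
  expect_equal(nrow(seg3), length(occupied))

  ## segments have the requested display length
  len <- sqrt((seg3$x1 - seg3$x0)^2 + (seg3$y1 - seg3$y0)^2)
  expect_equal(len, rep(40 / sc$spec$pixel_size, nrow(seg3)))
})

test_that("collinearity summaries aggregate by group with both weightings", {
  rec <- data.frame(
    label = 1:6,
    coo_deg = c(90, 80, 100, 90, 50, 130),
    subregion = c("CA1", "CA1", "CA1", "CA2", "CA2", "CA2"),
    partition = c("p1", "p1", "p2", "p3", "p3", "p3")
  )
  s <- summarize_collinearity(rec, by = "subregion")
  expect_equal(s$n, c(3L, 3L))
  expect_equal(s$dev[s$subregion == "CA1"], mean(c(0, 10, 10)))
  expect_equal(s$dev[s$subregion == "CA2"], mean(c(0, 40, 40)))

  p <- pooled_subregion_summary(rec, partition_col = "partition")
  ## CA1: partitions p1 (dev 5) and p2 (dev 10) -> partition-weighted 7.5
  expect_equal(p$dev_partition_weighted[p$subregion == "CA1"], 7.5)
  expect_equal(p$dev_neuron_weighted[p$subregion == "CA1"], 20 / 3)
  expect_equal(p$n_partitions, c(2L, 1L))

  ## NA corrected orientations are dropped from stats but counted in total
  rec$coo_deg[1] <- NA
  s2 <- summarize_collinearity(rec, by = "subregion")
  expect_equal(s2$n[s2$subregion == "CA1"], 2L)
  expect_equal(s2$n_total[s2$subregion == "CA1"], 3L)
})

test_that("rose and orientation-line plots render without error", {
  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp)
  h <- plot_rose(runif(50, 0, 180), bin_width = 15, main = "axial")
  rec <- data.frame(label = 1:3, x = c(10, 300, 600), y = c(10, 200, 400),
                    coo_deg = c(45, 90, 135))
  seg <- orientation_line_plot_data(rec, pixel_size = 1, grid_size = 220,
                                    seed = 1)
  plot_orientation_lines(seg)
  grDevices::dev.off()
  expect_equal(sum(h$count), 50)
  expect_true(file.exists(tmp))
})
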