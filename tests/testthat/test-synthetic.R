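test_that("scenes are deterministic under a fixed seed", {
  spec <- scene_spec(n_neurons = 15, n_glia = 3, n_speckle = 3, seed = 123)
  a <- generate_scene(spec)
  b <- generate_scene(spec)
  expect_identical(a$image, b$image)
  expect_identical(unclass(a$mask)[], unclass(b$mask)[])
  expect_identical(a$truth, b$truth)
  c <- generate_scene(scene_spec(n_neurons = 15, n_glia = 3, n_speckle = 3,
                                 seed = 124))
  expect_false(identical(a$truth, c$truth))
})

test_that("truth table bookkeeping matches the planted class counts", {
  sc <- generate_scene(scene_spec(n_neurons = 40, n_glia = 10, n_doublets = 5,
                                  seed = 2))
  expect_equal(nrow(sc$truth), 55L)
  expect_equal(as.vector(table(sc$truth$class)[c("neuron", "glia", "doublet")]),
               c(40L, 10L, 5L))
  ## label-truth mapping is bijective onto the mask labels
  expect_setequal(sc$truth$label, seq_len(n_objects(sc$mask)))
})

test_that("noise-free orientations equal the local curve normal", {
  sc <- generate_scene(scene_spec(n_neurons = 25, orientation_noise_kappa = Inf,
                                  seed = 31))
  tr <- sc$truth
  v <- sc$centerline$vertices
  for (i in seq_len(nrow(tr))) {
    np <- nearest_point_on_polyline(c(tr$x[i], tr$y[i]), sc$centerline)
    ## the radial direction of an arc is its normal
    radial <- fold_axial(atan2(-(np$q[2] - tr$y[i]), np$q[1] - tr$x[i]) * 180 / pi)
    expect_lt(axial_distance(tr$orientation_deg[i], radial), 0.5)
  }
})

test_that("axial von Mises sampler spans the uniform and concentrated limits", {
  a <- generate_angle_sample(1e5, mu = 40, kappa = 0, seed = 5)
  expect_true(all(a >= 0 & a < 180))
  expect_equal(circular_variance(a), 1, tolerance = 0.01)

  b <- generate_angle_sample(5000, mu = 40, kappa = 100, seed = 6)
  expect_lt(mean(axial_distance(b, 40)), 6)

  expect_length(generate_angle_sample(1, mu = 10, kappa = 2, seed = 1), 1L)
  d1 <- generate_angle_sample(50, 90, 4, seed = 9)
  d2 <- generate_angle_sample(50, 90, 4, seed = 9)
  expect_identical(d1, d2)
})

test_that("overcrowded specs fail with an instructive error", {
  spec <- scene_spec(curve = list(type = "line", length = 60),
                     n_neurons = 60, seed = 1)
  expect_error(generate_scene(spec), "overcrowded")
})

test_that("sine and line curves and triangle somata render correctly", {
  spec <- scene_spec(curve = list(type = "sine", amplitude = 40, period = 200,
                                  length = 500),
                     shape = list(type = "triangle", base = 12, height = 18),
                     n_neurons = 20, seed = 8)
  sc <- generate_scene(spec)
  expect_equal(n_objects(sc$mask), 20L)
  ## triangle axis (apex to base midpoint) is recovered by the ellipse fit
  res <- analyze_scene(sc, config = filter_config(grey_rule = "off"))
  m <- merge(res$records, sc$truth, by = "label")
  m <- m[!is.na(m$unco_deg), ]
  expect_gt(nrow(m), 10)                       # size filter trims tails
  expect_lt(stats::median(axial_distance(m$unco_deg, m$orientation_deg)), 3)

  line_sc <- generate_scene(scene_spec(curve = list(type = "line", length = 600),
                                       n_neurons = 15, seed = 9))
  ## on a straight horizontal lamina every normal is vertical
  expect_true(all(axial_distance(line_sc$truth$orientation_deg, 90) < 1e-6))
})

test_that("multilevel datasets honour their variance components", {
  d0 <- generate_multilevel_dataset(k_subregions = 2, n_cases = 2, n_slides = 2,
                                    effect_sizes = c(0, 0), sigma_case = 0,
                                    sigma_slide = 0, sigma_resid = 0,
                                    baseline = 30, n_per_cell = 5, seed = 1)
  expect_true(all(d0$dev_i == 30))

  d1 <- generate_multilevel_dataset(seed = 7)
  d2 <- generate_multilevel_dataset(seed = 7)
  expect_identical(d1, d2)
  expect_true(all(d1$dev_i >= 0 & d1$dev_i <= 90))
  expect_equal(nlevels(d1$subregion), 8L)
})

test_that("the full pipeline recovers planted orientations (closure)", {
  sc <- generate_scene(scene_spec(n_neurons = 35, orientation_noise_kappa = Inf,
                                  seed = 77))
  res <- analyze_scene(sc)
  m <- merge(res$records, sc$truth[sc$truth$class == "neuron", ], by = "label")
  m <- m[!is.na(m$unco_deg), ]
  expect_gt(nrow(m), 20)                       # size filter trims tails
  rms <- sqrt(mean(axial_distance(m$unco_deg, m$orientation_deg)^2))
  expect_lt(rms, 3)
})

test_that("rotate_scene preserves truth geometry", {
  sc <- generate_scene(scene_spec(n_neurons = 12, seed = 15))
  rot <- rotate_scene(sc, 33)
  expect_equal(nrow(rot$truth), nrow(sc$truth))
  expect_equal(n_objects(rot$mask), n_objects(sc$mask))
  ## pairwise distances between centroids are rotation-invariant
  d0 <- dist(sc$truth[, c("x", "y")])
  d1 <- dist(rot$truth[order(match(rot$truth$label, rot$truth$label)),
                       c("x", "y")])
  ## rows may be reordered by label; compare sorted distance multisets
  expect_equal(sort(as.vector(d0)), sort(as.vector(d1)), tolerance = 1e-6)
})
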