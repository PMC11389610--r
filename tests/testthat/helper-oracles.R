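## internal rasterizer, used by render-and-recover tests
ellipse_pixels <- pyrcollin:::ellipse_pixels

# Independent oracles used by the tests. These deliberately use the most
# direct (often brute-force) computation available, never the package's own
# fast path.

## circular variance by explicit sums of cosines/sines
oracle_circular_variance <- function(deg, axial = TRUE) {
  th <- (if (axial) 2 * deg else deg) * pi / 180
  C <- 0; S <- 0
  for (t in th) { C <- C + cos(t); S <- S + sin(t) }
  1 - sqrt((C / length(th))^2 + (S / length(th))^2)
}

## mean axial deviation from 90 by explicit looping
oracle_mean_dev <- function(deg) {
  tot <- 0
  for (a in deg) {
    d <- abs((a %% 180) - 90)
    tot <- tot + min(d, 180 - d)
  }
  tot / length(deg)
}

## nearest point on a polyline by dense sampling of every segment
oracle_nearest_point <- function(p, vertices, samples_per_segment = 1e4) {
  best <- Inf; bq <- NULL
  for (i in seq_len(nrow(vertices) - 1)) {
    t <- seq(0, 1, length.out = samples_per_segment)
    qx <- vertices[i, 1] + t * (vertices[i + 1, 1] - vertices[i, 1])
    qy <- vertices[i, 2] + t * (vertices[i + 1, 2] - vertices[i, 2])
    d2 <- (p[1] - qx)^2 + (p[2] - qy)^2
    j <- which.min(d2)
    if (d2[j] < best) { best <- d2[j]; bq <- c(qx[j], qy[j]) }
  }
  list(q = bq, distance = sqrt(best))
}

## ray-casting point-in-polygon, independent of mgcv
oracle_point_in_polygon <- function(p, v) {
  n <- nrow(v); inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((v[i, 2] > p[2]) != (v[j, 2] > p[2]) &&
        p[1] < (v[j, 1] - v[i, 1]) * (p[2] - v[i, 2]) / (v[j, 2] - v[i, 2]) + v[i, 1])
      inside <- !inside
    j <- i
  }
  inside
}

## small label mask with two 3x3 square objects, labels 4 and 9
two_object_mask <- function() {
  m <- matrix(0L, 12, 20)
  m[3:5, 3:5] <- 4L
  m[8:10, 14:16] <- 9L
  m
}

## default contaminant scene used by the filtering tests
contaminant_scene <- function(seed, n_neurons = 40, n_glia = 8,
                              n_doublets = 4, n_speckle = 8) {
  generate_scene(scene_spec(n_neurons = n_neurons, n_glia = n_glia,
                            n_doublets = n_doublets, n_speckle = n_speckle,
                            seed = seed))
}

## run one simulated-null mixed-model replicate; returns LRT p and contrasts
null_replicate <- function(seed, effect = 0, n_per_cell = 2,
                           contrasts = FALSE) {
  es <- c(effect, rep(0, 7))
  d <- generate_multilevel_dataset(k_subregions = 8, n_cases = 7, n_slides = 5,
                                   effect_sizes = es, sigma_case = 2,
                                   sigma_slide = 2, sigma_resid = 8,
                                   baseline = 25, n_per_cell = n_per_cell,
                                   seed = seed)
  d <- quantile_normalize_by_slide(d)
  f <- fit_subregion_model(d)
  list(p = f$lrt_p,
       ## suppress mvtnorm integration-precision chatter across 500 reps
       contrasts = if (contrasts)
         suppressWarnings(tukey_adjusted_contrasts(f)) else NULL)
}
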