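#' Specification of a synthetic curved-layer scene
#'
#' Describes a ground-truthed scene emulating a Nissl-stained pyramidal
#' layer: elongated somata placed along a curved lamina, oriented along the
#' local layer normal with axial von Mises angular noise, plus planted
#' contaminant objects (small glia-like discs, merged doublets, faint
#' extracellular speckle). Rendering is hard-masked (no antialiasing) so
#' label masks are exact. Defaults: somata 20 micrometres long with 2:1
#' axis ratio (about the size of human hippocampal pyramidal somata), a
#' 40-micrometre layer band, dark cells (grey 40) on a light background
#' (grey 220) as in an inverted-before-preparation Nissl render, and 0.5
#' micrometres per pixel.
#'
#' @param curve lamina midline: `list(type = "arc", radius, span)` (span in
#'   degrees), `list(type = "sine", amplitude, period, length)`, or
#'   `list(type = "line", length)`; lengths in micrometres.
#' @param layer_width full width of the placement band, micrometres.
#' @param n_neurons number of true somata.
#' @param shape `list(type = "ellipse", axis_ratio, length)` or
#'   `list(type = "triangle", base, height)`, micrometres.
#' @param orientation_noise_kappa axial von Mises concentration of the
#'   orientation noise about the local normal; `Inf` = noise off.
#' @param n_glia,n_doublets,n_speckle planted contaminant counts.
#' @param glia_diameter glia disc diameter, micrometres.
#' @param intensities named list: `neuron`, `background`, `speckle` grey
#'   levels of the raw (dark-on-light) render, plus `noise_sd`.
#' @param pixel_size micrometres per pixel.
#' @param seed RNG seed; fixes the scene deterministically.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(curve = list(type = "arc", radius = 240, span = 150),
                       layer_width = 40,
                       n_neurons = 40,
                       shape = list(type = "ellipse", axis_ratio = 2, length = 20),
                       orientation_noise_kappa = Inf,
                       n_glia = 0, n_doublets = 0, n_speckle = 0,
                       glia_diameter = 6,
                       intensities = list(neuron = 40, background = 220,
                                          speckle = 200, noise_sd = 4),
                       pixel_size = 0.5,
                       seed = 1L) {
  stopifnot(layer_width > 0, n_neurons >= 0, pixel_size > 0,
            orientation_noise_kappa >= 0)
  defaults <- list(neuron = 40, background = 220, speckle = 200, noise_sd = 4)
  intensities <- utils::modifyList(defaults, intensities)
  structure(list(curve = curve, layer_width = layer_width,
                 n_neurons = n_neurons, shape = shape,
                 orientation_noise_kappa = orientation_noise_kappa,
                 n_glia = n_glia, n_doublets = n_doublets,
                 n_speckle = n_speckle, glia_diameter = glia_diameter,
                 intensities = intensities, pixel_size = pixel_size,
                 seed = seed),
            class = "scene_spec")
}

## curve geometry in pixel (screen) coordinates; s in [0, 1] ---------------

curve_functions <- function(curve, pixel_size, margin_px) {
  if (curve$type == "arc") {
    R <- curve$radius / pixel_size
    span <- deg2rad(curve$span)
    t0 <- -pi / 2 - span / 2                    # arc opening upward on screen
    point <- function(s) {
      t <- t0 + s * span
      cbind(R * cos(t), R * sin(t))
    }
    tangent <- function(s) {
      t <- t0 + s * span
      cbind(-sin(t), cos(t))
    }
    arclen <- R * span
  } else if (curve$type == "sine") {
    L <- curve$length / pixel_size
    A <- curve$amplitude / pixel_size
    P <- curve$period / pixel_size
    point <- function(s) cbind(s * L, A * sin(2 * pi * s * L / P))
    tangent <- function(s) {
      d <- A * 2 * pi / P * cos(2 * pi * s * L / P)
      cbind(1, d) / sqrt(1 + d^2)
    }
    arclen <- L                                  # close enough for density checks
  } else if (curve$type == "line") {
    L <- curve$length / pixel_size
    point <- function(s) cbind(s * L, 0 * s)
    tangent <- function(s) cbind(1 + 0 * s, 0 * s)
    arclen <- L
  } else stop("unknown curve type: ", curve$type)

  ## shift into positive canvas coordinates
  ss <- seq(0, 1, length.out = 256)
  pts <- point(ss)
  off <- c(margin_px - min(pts[, 1]), margin_px - min(pts[, 2]))
  size <- c(max(pts[, 1]) - min(pts[, 1]), max(pts[, 2]) - min(pts[, 2])) +
    2 * margin_px
  list(point = function(s) sweep(point(s), 2, -off),
       tangent = tangent,
       width = ceiling(size[1]), height = ceiling(size[2]),
       arclen = arclen)
}

## hard-mask rasterizers; theta is the math-convention axis angle (deg) ----

ellipse_pixels <- function(cx, cy, a, b, theta_deg, W, H) {
  th <- deg2rad(theta_deg)
  x0 <- max(0L, floor(cx - a)); x1 <- min(W - 1L, ceiling(cx + a))
  y0 <- max(0L, floor(cy - a)); y1 <- min(H - 1L, ceiling(cy + a))
  if (x1 < x0 || y1 < y0) return(cbind(x = integer(), y = integer()))
  g <- expand.grid(x = x0:x1, y = y0:y1)
  dx <- g$x - cx
  dy <- -(g$y - cy)
  pu <- (dx * cos(th) + dy * sin(th)) / a
  pv <- (-dx * sin(th) + dy * cos(th)) / b
  inside <- pu^2 + pv^2 <= 1
  cbind(x = g$x[inside], y = g$y[inside])
}

triangle_pixels <- function(cx, cy, base, height, theta_deg, W, H) {
  th <- deg2rad(theta_deg)
  d <- c(cos(th), -sin(th))                     # axis direction, screen coords
  perp <- c(-d[2], d[1])
  apex <- c(cx, cy) + (2 * height / 3) * d
  bm <- c(cx, cy) - (height / 3) * d
  v1 <- bm + (base / 2) * perp
  v2 <- bm - (base / 2) * perp
  r <- ceiling(max(height, base))
  x0 <- max(0L, floor(cx - r)); x1 <- min(W - 1L, ceiling(cx + r))
  y0 <- max(0L, floor(cy - r)); y1 <- min(H - 1L, ceiling(cy + r))
  if (x1 < x0 || y1 < y0) return(cbind(x = integer(), y = integer()))
  g <- expand.grid(x = x0:x1, y = y0:y1)
  sgn <- function(p1, p2) {
    (g$x - p2[1]) * (p1[2] - p2[2]) - (p1[1] - p2[1]) * (g$y - p2[2])
  }
  d1 <- sgn(apex, v1); d2 <- sgn(v1, v2); d3 <- sgn(v2, apex)
  neg <- (d1 < 0) | (d2 < 0) | (d3 < 0)
  pos <- (d1 > 0) | (d2 > 0) | (d3 > 0)
  inside <- !(neg & pos)
  cbind(x = g$x[inside], y = g$y[inside])
}

## von Mises sampler (Best & Fisher 1979 rejection algorithm) -------------

rvm <- function(n, mu, kappa) {
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  if (!is.finite(kappa)) return(rep(mu %% (2 * pi), n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- (mu + sign(u3 - 0.5) * acos(f)) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

#' Sample axial von Mises orientations
#'
#' Draws directional angles at twice the mean with concentration `kappa`
#' (Best-Fisher rejection sampling) and halves them back, yielding axial
#' (period-180) orientations in `[0, 180)` degrees. `kappa = 0` gives the
#' axially uniform distribution, `kappa = Inf` the point mass at `mu`.
#'
#' @param n sample size.
#' @param mu mean axial orientation, degrees.
#' @param kappa concentration (>= 0).
#' @param seed optional RNG seed.
#' @return angles in degrees `[0, 180)`.
#' @export
generate_angle_sample <- function(n, mu = 90, kappa = 8, seed = NULL) {
  stopifnot(n >= 1, kappa >= 0)
  if (!is.null(seed)) set.seed(seed)
  fold_axial(rad2deg(rvm(n, deg2rad(2 * mu), kappa)) / 2)
}

#' Generate a ground-truthed synthetic curved-layer scene
#'
#' Renders the scene described by a [scene_spec()]: a raw dark-on-light
#' image, an exact label mask, the generating-curve centerline, and a truth
#' table (one row per object with its class, true centroid, true axial
#' orientation, pixel area and position along the curve). Somata are placed
#' at uniform positions along the curve, offset uniformly within the layer
#' band, and oriented along the local curve normal plus axial von Mises
#' noise. Doublets are two overlapping somata sharing one label; glia are
#' small discs; speckle are faint 3-pixel-scale blobs near background
#' intensity. Placement retries avoid overlaps; an overcrowded spec raises
#' an error advising a lower density.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (raw grey matrix, 0-255), `mask` (label
#'   matrix), `centerline` ([centerline()]), `truth` (data.frame), and
#'   `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  ps <- spec$pixel_size
  shape <- spec$shape
  obj_len_px <- (if (shape$type == "ellipse") shape$length else shape$height) / ps
  margin <- obj_len_px + spec$layer_width / ps
  geo <- curve_functions(spec$curve, ps, margin)
  W <- geo$width; H <- geo$height
  mask <- matrix(0L, H, W)
  img <- matrix(spec$intensities$background, H, W)

  n_total <- spec$n_neurons + spec$n_glia + spec$n_doublets + spec$n_speckle
  truth <- data.frame(label = integer(n_total), class = character(n_total),
                      x = numeric(n_total), y = numeric(n_total),
                      orientation_deg = numeric(n_total),
                      area_px = integer(n_total), s = numeric(n_total))
  half_w <- spec$layer_width / ps / 2

  ## stratified positions along the curve (cells tile the layer rather than
  ## clustering); retries fall back to uniform draws
  strat_s <- 0.03 + 0.94 * sample((seq_len(max(n_total, 1)) - stats::runif(n_total)) / max(n_total, 1))
  place <- function(render_fn, s_hint = NA) {
    ## returns list(pixels, centroid, s) or NULL after bounded retries
    for (try in 1:120) {
      s <- if (try == 1L && !is.na(s_hint)) s_hint else stats::runif(1, 0.03, 0.97)
      u <- stats::runif(1, -half_w, half_w)
      pt <- geo$point(s)
      tg <- geo$tangent(s)
      nv <- c(-tg[2], tg[1])                      # normal, screen coords
      ctr <- c(pt[1] + u * nv[1], pt[2] + u * nv[2])
      normal_axial <- fold_axial(vector_angle_deg(nv[1], nv[2]))
      r <- render_fn(ctr, normal_axial)
      pix <- r$pixels
      if (nrow(pix) < r$min_px) next              # clipped at border
      if (any(mask[cbind(pix[, 2] + 1L, pix[, 1] + 1L)] > 0L)) next
      return(list(pixels = pix, centroid = ctr, s = s,
                  orientation = r$orientation))
    }
    NULL
  }

  paint <- function(pix, label, intensity) {
    idx <- cbind(pix[, 2] + 1L, pix[, 1] + 1L)
    mask[idx] <<- label
    img[idx] <<- intensity
  }

  lab <- 0L; row <- 0L
  add_object <- function(class, render_fn, intensity) {
    p <- place(render_fn, s_hint = strat_s[row + 1L])
    if (is.null(p))
      stop("overcrowded scene: could not place a '", class,
           "' object without overlap; lower the density or enlarge the curve")
    lab <<- lab + 1L; row <<- row + 1L
    paint(p$pixels, lab, intensity)
    truth[row, ] <<- list(lab, class, p$centroid[1], p$centroid[2],
                          if (is.na(p$orientation)) NA_real_ else p$orientation,
                          nrow(p$pixels), p$s)
  }

  kappa <- spec$orientation_noise_kappa
  noise_angles <- if (spec$n_neurons > 0)
    generate_angle_sample(spec$n_neurons, mu = 0, kappa = kappa) else numeric()
  ## fold noise to signed axial offset in (-90, 90]
  noise_angles <- ifelse(noise_angles > 90, noise_angles - 180, noise_angles)

  render_soma <- function(noise) {
    function(ctr, normal_axial) {
      ang <- fold_axial(normal_axial + noise)
      if (shape$type == "ellipse") {
        a <- shape$length / ps / 2
        b <- a / shape$axis_ratio
        pix <- ellipse_pixels(ctr[1], ctr[2], a, b, ang, W, H)
        list(pixels = pix, orientation = ang, min_px = floor(pi * a * b * 0.9))
      } else {
        bs <- shape$base / ps
        ht <- shape$height / ps
        pix <- triangle_pixels(ctr[1], ctr[2], bs, ht, ang, W, H)
        list(pixels = pix, orientation = ang, min_px = floor(bs * ht / 2 * 0.9))
      }
    }
  }

  for (i in seq_len(spec$n_neurons))
    add_object("neuron", render_soma(noise_angles[i]), spec$intensities$neuron)

  glia_r <- spec$glia_diameter / ps / 2
  for (i in seq_len(spec$n_glia))
    add_object("glia", function(ctr, na) {
      pix <- ellipse_pixels(ctr[1], ctr[2], glia_r, glia_r, 0, W, H)
      list(pixels = pix, orientation = NA_real_,
           min_px = floor(pi * glia_r^2 * 0.9))
    }, spec$intensities$neuron)

  if (shape$type == "ellipse") {
    a <- shape$length / ps / 2; b <- a / shape$axis_ratio
  } else {
    a <- shape$height / ps / 2; b <- shape$base / ps / 2
  }
  for (i in seq_len(spec$n_doublets))
    add_object("doublet", function(ctr, normal_axial) {
      th <- deg2rad(normal_axial)
      perp <- c(sin(th), cos(th))                 # screen offset along minor axis
      off <- b * 0.8
      p1 <- ellipse_pixels(ctr[1] - off * perp[1], ctr[2] - off * perp[2],
                           a, b, normal_axial, W, H)
      p2 <- ellipse_pixels(ctr[1] + off * perp[1], ctr[2] + off * perp[2],
                           a, b, normal_axial, W, H)
      pix <- unique(rbind(p1, p2))
      list(pixels = pix, orientation = NA_real_,
           min_px = floor(1.6 * pi * a * b))
    }, spec$intensities$neuron)

  spk_r <- 1.6
  for (i in seq_len(spec$n_speckle))
    add_object("speckle", function(ctr, na) {
      pix <- ellipse_pixels(ctr[1], ctr[2], spk_r, spk_r, 0, W, H)
      list(pixels = pix, orientation = NA_real_, min_px = 5)
    }, spec$intensities$speckle)

  if (spec$intensities$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(W * H, 0, spec$intensities$noise_sd), H, W)
    img <- pmin(pmax(img, 0), 255)
  }

  cl_s <- seq(0, 1, length.out = 200)
  cl <- centerline(geo$point(cl_s))
  ## normalize to raster-order labels and remap the truth table to match
  out_mask <- as_label_mask(mask, provenance = "pyrcollin synthetic")
  vals <- as.vector(t(mask))
  uniq <- unique(vals[vals > 0L])     # uniq[j] = painted label of raster label j
  truth$label <- match(truth$label, uniq)
  truth <- truth[order(truth$label), ]
  rownames(truth) <- NULL
  list(image = img, mask = out_mask,
       centerline = cl, truth = truth, spec = spec)
}

#' Rigidly rotate a scene's mask, centerline and truth
#'
#' Rotates every labeled pixel and centerline vertex by `phi` degrees
#' (counter-clockwise in the mathematical convention) about the canvas
#' centre onto an enlarged canvas, re-rasterizing pixels to the nearest
#' grid position. Used to probe the rotation invariance of the curvature
#' correction: corrected orientations must not depend on how the section
#' was oriented on the slide.
#'
#' @param scene result of [generate_scene()].
#' @param phi rotation angle, degrees.
#' @return list with rotated `mask`, `centerline`, and `truth` (centroids
#'   rotated exactly, orientations advanced by `phi` and folded).
#' @export
rotate_scene <- function(scene, phi) {
  th <- deg2rad(phi)
  mask <- scene$mask
  H <- nrow(mask); W <- ncol(mask)
  D <- ceiling(sqrt(W^2 + H^2)) + 4L
  c_old <- c((W - 1) / 2, (H - 1) / 2)
  c_new <- c((D - 1) / 2, (D - 1) / 2)
  rot <- function(x, y) {
    dx <- x - c_old[1]; dy <- y - c_old[2]
    cbind(cos(th) * dx + sin(th) * dy + c_new[1],
          -sin(th) * dx + cos(th) * dy + c_new[2])
  }
  ## Inverse mapping with a 3x3 subpixel majority vote: a target pixel gets
  ## a label iff most of its area maps into that object, which preserves
  ## object support without the boundary jitter of plain nearest-neighbour
  ## sampling (a forward map would drop pixels at collisions and punch
  ## holes). Only cells near forward-rotated object pixels are candidates;
  ## objects are disjoint, so all positive votes on a cell share one label.
  ## floor(v + 0.5) avoids round-half-even checkerboarding on the exact .5
  ## coordinates produced by 90/180-degree rotations.
  idx <- which(mask > 0L)
  src_y <- (idx - 1L) %% H
  src_x <- (idx - 1L) %/% H
  fwd <- rot(src_x, src_y)
  fx <- as.integer(floor(fwd[, 1])); fy <- as.integer(floor(fwd[, 2]))
  enc <- unique(as.vector(outer(fx * D + fy,
                                c(-D - 1L, -D, -D + 1L, -1L, 0L, 1L,
                                  D - 1L, D, D + 1L), `+`)))
  tx <- enc %/% D; ty <- enc %% D
  keep <- tx >= 0L & tx < D & ty >= 0L & ty < D
  tx <- tx[keep]; ty <- ty[keep]
  n_pos <- integer(length(tx))
  lab <- integer(length(tx))
  for (ox in c(-1, 0, 1) / 3) for (oy in c(-1, 0, 1) / 3) {
    dx <- tx + ox - c_new[1]; dy <- ty + oy - c_new[2]
    sx <- as.integer(floor(cos(th) * dx - sin(th) * dy + c_old[1] + 0.5))
    sy <- as.integer(floor(sin(th) * dx + cos(th) * dy + c_old[2] + 0.5))
    ok <- sx >= 0L & sx < W & sy >= 0L & sy < H
    v <- integer(length(tx))
    v[ok] <- mask[cbind(sy[ok] + 1L, sx[ok] + 1L)]
    n_pos <- n_pos + (v > 0L)
    lab <- pmax(lab, v)
  }
  new_mask <- matrix(0L, D, D)
  hit <- n_pos >= 5L
  new_mask[cbind(ty[hit] + 1L, tx[hit] + 1L)] <- lab[hit]
  v <- rot(scene$centerline$vertices[, 1], scene$centerline$vertices[, 2])
  truth <- scene$truth
  tp <- rot(truth$x, truth$y)
  truth$x <- tp[, 1]; truth$y <- tp[, 2]
  truth$orientation_deg <- fold_axial(truth$orientation_deg + phi)
  out_mask <- as_label_mask(new_mask, provenance = "rotated")
  vals <- as.vector(t(new_mask))
  uniq <- unique(vals[vals > 0L])
  truth$orig_label <- truth$label
  truth$label <- match(truth$label, uniq)    # original label -> rotated label
  truth <- truth[order(truth$label), ]
  rownames(truth) <- NULL
  list(mask = out_mask, centerline = centerline(v), truth = truth)
}

#' Generate a multilevel neuron-observation dataset
#'
#' Simulates the data structure of the subregion comparison: angular
#' deviations with an additive subregion effect, random case and slide
#' intercepts (crossed), and residual noise, truncated to `[0, 90]`
#' degrees. True parameters are recorded as attribute `"truth"`.
#'
#' @param k_subregions number of subregion levels (`S1..Sk`).
#' @param n_cases,n_slides numbers of random-effect groups; the defaults
#'   mirror the seven-case, five-level sampling design of the tissue study
#'   the simulation emulates.
#' @param effect_sizes length-`k` additive subregion effects, degrees.
#' @param sigma_case,sigma_slide,sigma_resid SDs of the random intercepts
#'   and residual, degrees.
#' @param baseline grand-mean angular deviation, degrees.
#' @param n_per_cell observations per subregion x case x slide cell.
#' @param seed RNG seed.
#' @return data.frame with `subregion`, `case_id`, `slide_id`, `dev_i`.
#' @export
generate_multilevel_dataset <- function(k_subregions = 8, n_cases = 7,
                                        n_slides = 5,
                                        effect_sizes = rep(0, k_subregions),
                                        sigma_case = 2, sigma_slide = 2,
                                        sigma_resid = 8, baseline = 25,
                                        n_per_cell = 2, seed = 1L) {
  stopifnot(k_subregions >= 1, n_cases >= 1, n_slides >= 1, n_per_cell >= 1,
            length(effect_sizes) == k_subregions,
            sigma_case >= 0, sigma_slide >= 0, sigma_resid >= 0)
  set.seed(seed)
  b_case <- stats::rnorm(n_cases, 0, sigma_case)
  b_slide <- stats::rnorm(n_slides, 0, sigma_slide)
  g <- expand.grid(rep_i = seq_len(n_per_cell),
                   subregion = seq_len(k_subregions),
                   case = seq_len(n_cases),
                   slide = seq_len(n_slides))
  dev <- baseline + effect_sizes[g$subregion] + b_case[g$case] +
    b_slide[g$slide] + stats::rnorm(nrow(g), 0, sigma_resid)
  out <- data.frame(subregion = factor(paste0("S", g$subregion),
                                       levels = paste0("S", seq_len(k_subregions))),
                    case_id = paste0("case", g$case),
                    slide_id = paste0("slide", g$slide),
                    dev_i = pmin(pmax(dev, 0), 90))
  attr(out, "truth") <- list(effect_sizes = effect_sizes,
                             sigma_case = sigma_case,
                             sigma_slide = sigma_slide,
                             sigma_resid = sigma_resid, baseline = baseline,
                             b_case = b_case, b_slide = b_slide)
  out
}
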