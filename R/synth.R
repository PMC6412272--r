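#' Synthetic-scene generator configuration
#'
#' Parameters of the MSX-like scene generator. Defaults emulate the
#' statistical structure of warm-palette orchard MSX images: smooth,
#' orange (high-red) elliptical fruit on a rough, cool background, with
#' branch-like occluders and an optional soil patch that shares the fruit
#' palette but carries a rough two-tone speckle texture (the color
#' confounder that motivates texture-based classification).
#'
#' @param image_size (H, W) in pixels; default c(300, 400).
#' @param n_fruit inclusive range of fruit count per scene; default
#'   c(2, 10).
#' @param fruit_axis_px inclusive range of ellipse semi-axes in pixels.
#' @param fruit_color warm mean RGB at the fruit center (high red).
#' @param fruit_shading radial darkening amplitude from center to rim
#'   (red channel intensity units).
#' @param fruit_noise amplitude of the smooth low-frequency shading noise
#'   on fruit surfaces.
#' @param background_color cool mean RGB of the background.
#' @param background_roughness amplitude of the background value noise.
#' @param background_scale correlation length in pixels of the background
#'   value noise (2-4 px range is typical).
#' @param occluder_density probability that a fruit is crossed by a
#'   branch-like occluder.
#' @param occluded_frac_range range of the fraction of a fruit's visible
#'   area covered by its occluder.
#' @param soil_patch list: `enabled`, `color` (warm RGB near the fruit
#'   palette), `tone_delta` (half-distance between the two speckle tones on
#'   the red channel), `axis_px` (semi-axis range).
#' @param noise_sigma standard deviation of the Gaussian pixel noise added
#'   to every channel (clipped to \[0, 255\]).
#' @param edge_prob probability that a fruit may extend past the image
#'   border (exercises border handling).
#' @param contrast_margin required margin between mean fruit red and mean
#'   background red (validated, not fitted).
#' @param seed integer seed; scenes are fully deterministic given the seed.
#' @return an object of class `msx_synth_config`.
#' @export
synth_config <- function(image_size = c(300, 400),
                         n_fruit = c(2, 10),
                         fruit_axis_px = c(12, 30),
                         fruit_color = c(245, 135, 45),
                         fruit_shading = 55,
                         fruit_noise = 8,
                         background_color = c(70, 85, 155),
                         background_roughness = 35,
                         background_scale = 3,
                         occluder_density = 0.45,
                         occluded_frac_range = c(0.08, 0.35),
                         soil_patch = list(enabled = TRUE,
                                           color = c(214, 115, 42),
                                           tone_delta = 44,
                                           axis_px = c(18, 34)),
                         noise_sigma = 5,
                         edge_prob = 0.1,
                         contrast_margin = 60,
                         seed = 1L) {
  cfg <- list(image_size = image_size, n_fruit = n_fruit,
              fruit_axis_px = fruit_axis_px, fruit_color = fruit_color,
              fruit_shading = fruit_shading, fruit_noise = fruit_noise,
              background_color = background_color,
              background_roughness = background_roughness,
              background_scale = background_scale,
              occluder_density = occluder_density,
              occluded_frac_range = occluded_frac_range,
              soil_patch = soil_patch, noise_sigma = noise_sigma,
              edge_prob = edge_prob, contrast_margin = contrast_margin,
              seed = as.integer(seed))
  class(cfg) <- "msx_synth_config"
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  if (length(cfg$image_size) != 2 || any(cfg$image_size < 32))
    msx_stop_validation("image_size must be (H, W) with both >= 32")
  if (cfg$n_fruit[1] < 0 || cfg$n_fruit[2] < cfg$n_fruit[1])
    msx_stop_validation("n_fruit must be a non-decreasing non-negative range")
  if (2 * max(cfg$fruit_axis_px) >= min(cfg$image_size))
    msx_stop_validation("fruit larger than the image: reduce fruit_axis_px")
  if (cfg$fruit_color[1] - cfg$fruit_shading <
      cfg$background_color[1] + cfg$contrast_margin)
    msx_stop_validation("fruit mean red must exceed background red by the contrast margin")
  if (any(c(cfg$fruit_color, cfg$background_color) < 0) ||
      any(c(cfg$fruit_color, cfg$background_color) > 255))
    msx_stop_validation("colors must be valid 8-bit RGB")
  invisible(cfg)
}

# Bilinearly interpolated value noise in [-1, 1] with the given correlation
# length (pixels).
value_noise <- function(h, w, scale) {
  hc <- ceiling(h / scale) + 1L
  wc <- ceiling(w / scale) + 1L
  C <- matrix(stats::runif(hc * wc, -1, 1), hc, wc)
  rx <- (seq_len(h) - 1) / scale + 1
  cx <- (seq_len(w) - 1) / scale + 1
  r0 <- pmin(floor(rx), hc - 1L); fr <- rx - r0
  c0 <- pmin(floor(cx), wc - 1L); fc <- cx - c0
  C[r0, c0] * ((1 - fr) %*% t(1 - fc)) +
    C[r0 + 1L, c0] * (fr %*% t(1 - fc)) +
    C[r0, c0 + 1L] * ((1 - fr) %*% t(fc)) +
    C[r0 + 1L, c0 + 1L] * (fr %*% t(fc))
}

# Squared normalized elliptical radius field for the whole image.
ellipse_radius2 <- function(h, w, cy, cx, a, b, theta) {
  dy <- matrix(seq_len(h) - cy, h, w)
  dx <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2
}

clip8 <- function(x) pmin(pmax(round(x), 0), 255)

#' Generate one synthetic MSX-like scene with ground truth
#'
#' Draws fruit ellipses with smooth radial shading on a rough cool
#' background, paints branch-like occluders over a random subset of fruit,
#' optionally places one soil confounder patch (fruit-colored, rough
#' speckle), and adds clipped Gaussian pixel noise. Fully deterministic
#' given `cfg$seed`.
#'
#' Per-fruit manual masks follow annotation practice: pixels hidden by an
#' overlapping front fruit belong to the front fruit, while pixels hidden
#' by a thin branch remain part of the fruit's manual region (the annotator
#' knows the fruit continues behind the branch).
#'
#' @param cfg an [synth_config()] object.
#' @return an object of class `msx_scene`: `image` (H x W x 3 integer),
#'   `fruit_mask` (union of per-fruit masks), `fruit_masks` (list of
#'   per-fruit binary masks), `occluder_mask`, `confounder_mask` (soil),
#'   `annotations` (data.frame: `fruit_id`, `area`, `occluded_fraction`,
#'   `overlap`, `category`, `target`), and `cfg`.
#' @export
generate_scene <- function(cfg = synth_config()) {
  validate_synth_config(cfg)
  set.seed(cfg$seed)
  h <- cfg$image_size[1]; w <- cfg$image_size[2]

  # rough, cool background: correlated value noise plus fine grain
  coarse <- value_noise(h, w, cfg$background_scale)
  grain <- matrix(stats::runif(h * w, -1, 1), h, w)
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    amp <- cfg$background_roughness * c(1, 0.8, 0.6)[ch]
    img[, , ch] <- cfg$background_color[ch] + amp * coarse + 0.35 * amp * grain
  }

  # fruit ellipses, drawn back to front (later = in front)
  nf <- if (cfg$n_fruit[2] == cfg$n_fruit[1]) cfg$n_fruit[1]
        else sample(cfg$n_fruit[1]:cfg$n_fruit[2], 1)
  ell <- list(); rr2 <- list()
  amin <- cfg$fruit_axis_px[1]; amax <- cfg$fruit_axis_px[2]
  k <- 0L; attempts <- 0L
  while (k < nf && attempts < 40L * max(nf, 1L)) {
    attempts <- attempts + 1L
    a <- stats::runif(1, amin, amax); b <- stats::runif(1, amin, amax)
    theta <- stats::runif(1, 0, pi)
    at_edge <- stats::runif(1) < cfg$edge_prob
    margin <- if (at_edge) 2 else max(a, b)
    cy <- stats::runif(1, 1 + margin, h - margin)
    cx <- stats::runif(1, 1 + margin, w - margin)
    r2 <- ellipse_radius2(h, w, cy, cx, a, b, theta)
    cand <- r2 <= 1
    if (sum(cand) < 80) next
    # do not let the new (front) fruit hide too much of any placed fruit
    ok <- TRUE
    if (k > 0L) {
      for (j in seq_len(k)) {
        hidden <- sum(ell[[j]] & cand) / sum(ell[[j]])
        if (hidden > 0.45) { ok <- FALSE; break }
      }
    }
    if (!ok) next
    k <- k + 1L
    ell[[k]] <- cand
    rr2[[k]] <- r2
  }
  nf <- k

  # visible (manual) per-fruit masks: front fruit own shared pixels
  vis <- ell
  if (nf > 1L) for (j in seq_len(nf - 1L)) {
    front <- Reduce(`|`, ell[(j + 1L):nf])
    vis[[j]] <- ell[[j]] & !front
  }

  # paint fruit: radial shading + smooth low-frequency surface noise
  smooth_noise <- value_noise(h, w, 6)
  for (j in seq_len(nf)) {
    m <- vis[[j]]
    shade <- pmin(rr2[[j]], 1)
    for (ch in 1:3) {
      base <- cfg$fruit_color[ch] - cfg$fruit_shading * c(1, 0.8, 0.35)[ch] * shade
      plane <- img[, , ch]
      plane[m] <- (base + cfg$fruit_noise * c(1, 0.8, 0.5)[ch] * smooth_noise)[m]
      img[, , ch] <- plane
    }
  }

  # branch-like occluders: a cap of the fruit's visible area, cut by a
  # chord so the remainder stays connected; painted in a cool branch color
  occluder <- matrix(FALSE, h, w)
  occ_frac <- numeric(nf)
  branch_color <- c(60, 52, 78)
  for (j in seq_len(nf)) {
    if (stats::runif(1) >= cfg$occluder_density) next
    m_idx <- which(vis[[j]])
    if (length(m_idx) < 160) next
    frac <- stats::runif(1, cfg$occluded_frac_range[1], cfg$occluded_frac_range[2])
    ang <- stats::runif(1, 0, 2 * pi)
    ri <- (m_idx - 1L) %% h + 1L
    ci <- (m_idx - 1L) %/% h + 1L
    proj <- ri * sin(ang) + ci * cos(ang)
    cap <- m_idx[proj >= stats::quantile(proj, 1 - frac)]
    occluder[cap] <- TRUE
    occ_frac[j] <- length(cap) / length(m_idx)
  }
  if (any(occluder)) {
    bn <- matrix(stats::runif(h * w, -1, 1), h, w)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[occluder] <- branch_color[ch] + 10 * bn[occluder]
      img[, , ch] <- plane
    }
  }

  # soil confounder: fruit-like palette, rough two-tone speckle
  confounder <- matrix(0L, h, w)
  sp <- cfg$soil_patch
  if (isTRUE(sp$enabled)) {
    fruit_union <- if (nf > 0L) Reduce(`|`, ell) else matrix(FALSE, h, w)
    dist_to_fruit <- if (any(fruit_union)) EBImage::distmap(1 - fruit_union * 1)
                     else matrix(Inf, h, w)
    for (try in 1:40) {
      a <- stats::runif(1, sp$axis_px[1], sp$axis_px[2])
      b <- stats::runif(1, sp$axis_px[1], sp$axis_px[2])
      theta <- stats::runif(1, 0, pi)
      cy <- stats::runif(1, 1 + a, h - a); cx <- stats::runif(1, 1 + b, w - b)
      m <- ellipse_radius2(h, w, cy, cx, a, b, theta) <= 1
      if (sum(m) >= 400 && min(dist_to_fruit[m]) > 8) {
        confounder[m] <- 1L
        tone <- stats::runif(sum(m)) < 0.5
        scale3 <- c(1, 0.6, 0.35)
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[m] <- sp$color[ch] + ifelse(tone, 1, -1) * sp$tone_delta * scale3[ch]
          img[, , ch] <- plane
        }
        break
      }
    }
  }

  # sensor noise
  img <- img + array(stats::rnorm(h * w * 3, 0, cfg$noise_sigma), c(h, w, 3))
  storage.mode(img) <- "double"
  img <- array(as.integer(clip8(img)), c(h, w, 3))

  fruit_masks <- lapply(seq_len(nf), function(j) vis[[j]] * 1L)
  fruit_mask <- if (nf > 0L) (Reduce(`|`, vis)) * 1L else matrix(0L, h, w)
  overlap <- vapply(seq_len(nf), function(j) {
    any(vapply(seq_len(nf)[-j], function(i) {
      inter <- sum(ell[[j]] & ell[[i]])
      inter > 0.02 * min(sum(ell[[j]]), sum(ell[[i]]))
    }, logical(1)))
  }, logical(1))
  annotations <- data.frame(
    fruit_id = seq_len(nf),
    area = vapply(fruit_masks, sum, numeric(1)),
    occluded_fraction = occ_frac[seq_len(nf)],
    overlap = overlap,
    category = ifelse(occ_frac[seq_len(nf)] > 0 | overlap, "incomplete", "complete"),
    target = occ_frac[seq_len(nf)] <= 0.6
  )
  if (nf == 0L) annotations <- data.frame(
    fruit_id = integer(), area = numeric(), occluded_fraction = numeric(),
    overlap = logical(), category = character(), target = logical())

  structure(list(image = img, fruit_mask = fruit_mask,
                 fruit_masks = fruit_masks, occluder_mask = occluder * 1L,
                 confounder_mask = confounder, annotations = annotations,
                 cfg = cfg), class = "msx_scene")
}

#' @export
print.msx_scene <- function(x, ...) {
  cat(sprintf("Synthetic MSX scene: %d x %d, %d fruit (%d incomplete), soil confounder: %s\n",
              dim(x$image)[1], dim(x$image)[2], nrow(x$annotations),
              sum(x$annotations$category == "incomplete"),
              if (sum(x$confounder_mask) > 0) "yes" else "no"))
  invisible(x)
}

# Deterministic per-scene seed derivation (kept below 2^31).
scene_seed <- function(base_seed, i) {
  as.integer((as.numeric(base_seed) + 104729 * as.numeric(i)) %% 2147483647)
}

#' Generate a labeled region training set from synthetic scenes
#'
#' Runs the pre-processing and texture stages on `n_scenes` generated
#' scenes and labels every detected connected region -1 (fruit) or +1
#' (non-fruit) by majority pixel overlap with the scene's ground-truth
#' fruit mask.
#'
#' @param cfg an [synth_config()] object; scene i uses a seed derived
#'   deterministically from `cfg$seed` and i.
#' @param n_scenes number of scenes (>= 1).
#' @param run_cfg an [msx_config()] for the pipeline stages.
#' @return list with `features` (data.frame: scene, region_id, feature
#'   columns) and `labels` (data.frame: scene, region_id, label).
#' @export
generate_training_set <- function(cfg = synth_config(), n_scenes = 10,
                                  run_cfg = msx_config()) {
  if (n_scenes < 1) msx_stop_validation("n_scenes must be >= 1")
  feats <- list(); labs <- list()
  for (i in seq_len(n_scenes)) {
    scfg <- cfg; scfg$seed <- scene_seed(cfg$seed, i)
    scene <- generate_scene(scfg)
    pre <- preprocess_image(scene$image, run_cfg)
    f <- extract_features(pre, run_cfg)
    if (nrow(f) == 0) next
    f$scene <- i
    lab <- vapply(f$region_id, function(id) {
      px <- pre$labels == id
      if (sum(scene$fruit_mask[px]) / sum(px) > 0.5) -1L else 1L
    }, integer(1))
    feats[[length(feats) + 1L]] <- f
    labs[[length(labs) + 1L]] <- data.frame(scene = i,
                                            region_id = f$region_id,
                                            label = lab)
  }
  list(features = do.call(rbind, feats), labels = do.call(rbind, labs))
}
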