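#' Ocular component labels
#'
#' The six component labels used throughout: three pathology components
#' (microaneurysm, hemorrhage, exudate) and three non-pathology components
#' (optic disc, vessels, other retinal tissue inside the field of view).
#' @export
dr_components <- function() {
  c("microaneurysm", "hemorrhage", "exudate", "optic_disc", "vessels",
    "other")
}

#' Pathology component labels
#' @export
dr_pathology_components <- function() c("microaneurysm", "hemorrhage",
                                        "exudate")

## ---- low-level raster helpers (row, col indexing, origin top-left) ----

#' Logical disk mask stamped into an H x W matrix (local-window rasterizer)
#' @noRd
stamp_disk <- function(mask, cy, cx, r) {
  h <- nrow(mask); w <- ncol(mask)
  r0 <- max(1L, floor(cy - r)); r1 <- min(h, ceiling(cy + r))
  c0 <- max(1L, floor(cx - r)); c1 <- min(w, ceiling(cx + r))
  if (r0 > r1 || c0 > c1) return(mask)
  yy <- r0:r1; xx <- c0:c1
  d2 <- outer((yy - cy)^2, (xx - cx)^2, `+`)
  mask[yy, xx] <- mask[yy, xx] | (d2 <= r^2)
  mask
}

#' Circular field-of-view mask for a scene spec
#' @param spec A [scene_spec()].
#' @return Logical H x W matrix.
#' @export
fov_mask <- function(spec) {
  n <- spec$image_size
  ctr <- (n + 1) / 2
  r <- spec$fov_radius_fraction * n / 2
  yy <- seq_len(n)
  outer((yy - ctr)^2, (yy - ctr)^2, `+`) <= r^2
}

#' Corner watermark region (used by the falsification-control scenes)
#'
#' A fixed rectangle in the top-left image corner, outside the circular
#' field of view, where [generate_image()] encodes the grade when the
#' spec's `label_source` is `"watermark"`.
#' @param spec A [scene_spec()].
#' @return Logical H x W matrix.
#' @export
watermark_region <- function(spec) {
  n <- spec$image_size
  m <- matrix(FALSE, n, n)
  m[2:15, 2:15] <- TRUE
  m
}

## Random-walk vessel tree rendered by stamping disks along each path.
## Returns the updated vessel mask; drawing into the image is done by the
## caller from the mask.
draw_vessel_tree <- function(mask, start, angle0, width, depth, n_steps,
                             step_len = 1.5, wiggle = 0.22) {
  pos <- start
  ang <- angle0
  h <- nrow(mask)
  for (i in seq_len(n_steps)) {
    ang <- ang + stats::rnorm(1, 0, wiggle)
    pos <- pos + step_len * c(sin(ang), cos(ang))
    if (any(pos < 1) || any(pos > h)) break
    mask <- stamp_disk(mask, pos[1], pos[2], width / 2)
    if (depth > 0 && stats::runif(1) < 0.04) {
      mask <- draw_vessel_tree(mask, pos, ang + sample(c(-1, 1), 1) * 0.7,
                               max(width * 0.7, 1), depth - 1,
                               round(n_steps * 0.6), step_len, wiggle)
    }
  }
  mask
}

## Smooth low-frequency background texture in [-1, 1], via bilinear upsample
## of a coarse noise grid.
background_texture <- function(n, coarse = 8) {
  g <- matrix(stats::rnorm(coarse^2), coarse, coarse)
  up <- EBImage::resize(g, w = n, h = n, filter = "bilinear")
  up / max(abs(up), 1e-8)
}

#' Generate one synthetic annotated fundus image
#'
#' Draws a fundus-like RGB scene from a [scene_spec()]: circular field of
#' view, textured retinal background, bright optic disc, dark branching
#' vessel tree, and lesions drawn from the spec's count ranges. Every drawn
#' element is recorded in an exact per-component binary mask, and the grade
#' label is assigned by the deterministic lesion-burden rule
#' [grade_from_counts()] (or encoded in a corner watermark for
#' falsification-control scenes).
#'
#' Masks are recorded independently per component; the `"other"` component
#' is the field of view minus the union of all named components. Neovascular
#' tuft pixels are recorded under `vessels` (they are vessel tissue); their
#' presence is what drives grade 4.
#'
#' @param spec A valid [scene_spec()].
#' @param seed RNG seed; defaults to `spec$seed`. The result is a pure
#'   function of `(spec, seed, grade)`.
#' @param grade Target grade 0--4, only used (and required) when
#'   `spec$label_source == "watermark"`; ignored otherwise.
#' @param image_id Identifier stored in the result.
#' @return An object of class `annotated_fundus`: list with `image`
#'   (H x W x 3 array in \[0,1\]), `masks` (named list of H x W 0/1 integer
#'   matrices, one per [dr_components()]), `grade` and `image_id`.
#' @export
generate_image <- function(spec, seed = spec$seed, grade = NULL,
                           image_id = sprintf("img_%08d", seed)) {
  validate_scene_spec(spec)
  if (spec$label_source == "watermark" && is.null(grade))
    validation_error("grade", "required when label_source is 'watermark'")
  with_seed(seed, .generate_image_impl(spec, grade, image_id))
}

.generate_image_impl <- function(spec, grade, image_id) {
  n <- spec$image_size
  fov <- fov_mask(spec)
  ctr <- (n + 1) / 2
  fov_r <- spec$fov_radius_fraction * n / 2

  ## background: warm retinal base with low-frequency texture + pixel noise
  tex <- background_texture(n)
  base_rgb <- c(0.82, 0.42, 0.18)
  img <- array(0, c(n, n, 3))
  for (ch in 1:3) {
    img[, , ch] <- base_rgb[ch] + 0.06 * tex +
      stats::rnorm(n * n, 0, spec$noise_sd)
  }

  masks <- stats::setNames(
    rep(list(matrix(FALSE, n, n)), length(dr_components())), dr_components())

  ## optic disc: bright circle offset from center
  off <- spec$optic_disc$center_offset
  disc_c <- c(ctr + off[1] * fov_r, ctr + off[2] * fov_r)
  disc_r <- stats::runif(1, spec$optic_disc$radius_range[1],
                         spec$optic_disc$radius_range[2]) * n
  masks$optic_disc <- stamp_disk(masks$optic_disc, disc_c[1], disc_c[2],
                                 disc_r)
  disc_col <- c(0.96, 0.88, 0.55)

  ## vessel tree radiating from the disc
  vp <- spec$vessel_params
  for (b in seq_len(vp$branch_count)) {
    ang <- stats::runif(1, 0, 2 * pi)
    wd <- stats::runif(1, vp$width_range[1], vp$width_range[2])
    masks$vessels <- draw_vessel_tree(masks$vessels, disc_c, ang, wd,
                                      vp$branching_depth,
                                      n_steps = round(1.4 * fov_r))
  }

  ## lesions: counts drawn from the spec ranges (watermark scenes draw the
  ## same ranges but the label is independent of them)
  draw_count <- function(cl) {
    rng <- spec$lesion_counts[[cl]]
    if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1)
  }
  counts <- stats::setNames(
    lapply(names(spec$lesion_counts), draw_count),
    names(spec$lesion_counts))

  lesion_pos <- function() {
    repeat {
      p <- ctr + 0.9 * fov_r * stats::runif(2, -1, 1)
      if ((p[1] - ctr)^2 + (p[2] - ctr)^2 <= (0.9 * fov_r)^2) return(p)
    }
  }
  lesion_radius <- function(cl)
    stats::runif(1, spec$lesion_size_ranges[[cl]][1],
                 spec$lesion_size_ranges[[cl]][2])

  for (i in seq_len(counts$microaneurysm)) {
    p <- lesion_pos()
    masks$microaneurysm <- stamp_disk(masks$microaneurysm, p[1], p[2],
                                      lesion_radius("microaneurysm"))
  }
  for (i in seq_len(counts$hemorrhage)) {
    p <- lesion_pos(); r <- lesion_radius("hemorrhage")
    ## irregular blot: union of overlapping disks
    for (k in 1:3) {
      q <- p + stats::runif(2, -r / 2, r / 2)
      masks$hemorrhage <- stamp_disk(masks$hemorrhage, q[1], q[2],
                                     r * stats::runif(1, 0.6, 1))
    }
  }
  for (i in seq_len(counts$exudate)) {
    p <- lesion_pos()
    masks$exudate <- stamp_disk(masks$exudate, p[1], p[2],
                                lesion_radius("exudate"))
  }
  for (i in seq_len(counts$neovascular_tuft)) {
    p <- lesion_pos(); r <- lesion_radius("neovascular_tuft")
    tuft <- matrix(FALSE, n, n)
    for (k in 1:4) {
      tuft <- draw_vessel_tree(tuft, p + stats::runif(2, -r / 3, r / 3),
                               stats::runif(1, 0, 2 * pi), 1.2, 0,
                               n_steps = round(2.5 * r), step_len = 1,
                               wiggle = 0.8)
    }
    ## confine the tangle to its neighbourhood and file it under vessels
    lim <- stamp_disk(matrix(FALSE, n, n), p[1], p[2], r)
    masks$vessels <- masks$vessels | (tuft & lim)
  }

  ## paint components into the image (later-drawn overwrite earlier)
  paint <- function(img, mask, col, jitter = 0.03) {
    idx <- which(mask)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[idx] <- col[ch] + stats::rnorm(length(idx), 0, jitter)
      img[, , ch] <- plane
    }
    img
  }
  img <- paint(img, masks$optic_disc, disc_col)
  img <- paint(img, masks$vessels, c(0.45, 0.12, 0.08))
  img <- paint(img, masks$microaneurysm, c(0.33, 0.07, 0.05))
  img <- paint(img, masks$hemorrhage, c(0.28, 0.05, 0.05))
  img <- paint(img, masks$exudate, c(0.97, 0.93, 0.55))

  ## label
  if (spec$label_source == "lesions") {
    grade <- grade_from_counts(counts$microaneurysm, counts$hemorrhage,
                               counts$exudate, counts$neovascular_tuft,
                               K = spec$grade_threshold)
  } else {
    grade <- as.integer(grade)
    ## grade encoded as the side length of a bright corner block
    side <- 6 + 2 * grade
    for (ch in 1:3) img[2:(1 + side), 2:(1 + side), ch] <- 1
  }

  ## clip to FOV and valid range
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[!fov] <- 0
    if (spec$label_source == "watermark") {
      wm <- watermark_region(spec) & !fov
      plane[wm] <- img[, , ch][wm]
    }
    img[, , ch] <- pmin(pmax(plane, 0), 1)
  }

  ## masks are clipped to the FOV; "other" is the unclaimed FOV remainder
  named <- c("microaneurysm", "hemorrhage", "exudate", "optic_disc",
             "vessels")
  for (nm in named) masks[[nm]] <- masks[[nm]] & fov
  claimed <- Reduce(`|`, masks[named])
  masks$other <- fov & !claimed
  masks <- lapply(masks, function(m) {
    storage.mode(m) <- "integer"
    m
  })

  structure(list(image = img, masks = masks, grade = as.integer(grade),
                 image_id = image_id),
            class = "annotated_fundus")
}

#' @export
print.annotated_fundus <- function(x, ...) {
  cat(sprintf("annotated_fundus '%s': %dx%d, grade %d\n", x$image_id,
              dim(x$image)[1], dim(x$image)[2], x$grade))
  cat("  mask pixels:",
      paste(sprintf("%s=%d", names(x$masks),
                    vapply(x$masks, sum, 0L)), collapse = " "), "\n")
  invisible(x)
}

#' Validate an annotated fundus object
#' @param af An `annotated_fundus`.
#' @export
validate_annotated_fundus <- function(af) {
  assert_that(inherits(af, "annotated_fundus"), "af", "not annotated_fundus")
  d <- dim(af$image)
  assert_that(length(d) == 3 && d[3] == 3, "image", "must be H x W x 3")
  assert_that(all(af$image >= 0 & af$image <= 1), "image",
              "intensities must lie in [0, 1]")
  assert_that(identical(sort(names(af$masks)), sort(dr_components())),
              "masks", "must contain exactly the six components")
  for (nm in names(af$masks))
    assert_that(identical(dim(af$masks[[nm]]), d[1:2]) &&
                  all(af$masks[[nm]] %in% c(0L, 1L)),
                paste0("masks$", nm), "must be a binary H x W matrix")
  assert_that(af$grade %in% 0:4, "grade", "must be in 0..4")
  invisible(af)
}
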