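#' Min--max normalize a saliency map to \[0, 1\]
#'
#' Constant maps (no spatial preference) normalize to all zeros,
#' signalling "no attention"; any non-constant map attains max 1.
#' Idempotent: normalizing twice equals normalizing once.
#' @param v Numeric matrix.
#' @param tol Range below which the map counts as constant.
#' @return Matrix with values in \[0, 1\].
#' @export
normalize_saliency <- function(v, tol = 1e-12) {
  rng <- range(v)
  if (!all(is.finite(rng))) stop("non-finite saliency values")
  if (diff(rng) < tol) return(array(0, dim(v)))
  (v - rng[1]) / diff(rng)
}

new_saliency_map <- function(values, model_id, target_class, layer_id,
                             image_id = NA_character_) {
  structure(list(values = values, model_id = model_id,
                 target_class = as.integer(target_class),
                 layer_id = layer_id, image_id = image_id),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf(
    "saliency_map %dx%d (model '%s', class %d, layer '%s', image '%s')\n",
    nrow(x$values), ncol(x$values), x$model_id, x$target_class,
    x$layer_id, x$image_id))
  invisible(x)
}

#' Grad-CAM saliency map
#'
#' Gradient-weighted class activation mapping: the gradient of the target
#' class score (logit) with respect to the activation maps of the last
#' convolutional feature layer is averaged spatially to give one weight
#' per channel; the weighted sum of activation maps is rectified,
#' bilinearly upsampled to image resolution and min--max normalized to
#' \[0, 1\]. By default the target class is the model's predicted label
#' for the image.
#'
#' @param model A trained `dr_model`.
#' @param image `H x W x 3` array matching the model input size.
#' @param target_class Grade 0--4; defaults to the predicted label.
#' @param layer Node id of the feature layer; defaults to
#'   `model$gradcam_layer`.
#' @param image_id Identifier carried into the result.
#' @return A `saliency_map`.
#' @export
gradcam <- function(model, image, target_class = NULL,
                    layer = model$gradcam_layer,
                    image_id = NA_character_) {
  stopifnot(inherits(model, "dr_model"))
  x <- image
  dim(x) <- c(1, dim(image))
  fw <- nn_forward(model, x)
  if (is.null(fw$outs[[layer]]))
    validation_error("layer", sprintf("no node named '%s'", layer))
  probs <- softmax(fw$logits)
  if (is.null(target_class)) target_class <- which.max(probs[1, ]) - 1L
  assert_that(target_class %in% 0:4, "target_class", "must be in 0..4")

  dlogits <- matrix(0, 1, ncol(fw$logits))
  dlogits[1, target_class + 1L] <- 1
  bw <- nn_backward(model, fw$outs, dlogits, want_params = FALSE)
  A <- fw$outs[[layer]]
  G <- bw$douts[[layer]]
  if (is.null(G) || !all(is.finite(G))) stop("non-finite Grad-CAM gradients")
  d <- dim(A)                      # (1, h, w, ch)
  Am <- A; dim(Am) <- c(d[2] * d[3], d[4])
  Gm <- G; dim(Gm) <- c(d[2] * d[3], d[4])
  wts <- colMeans(Gm)              # spatial average of gradients
  cam <- matrix(Am %*% wts, d[2], d[3])
  cam <- pmax(cam, 0)              # rectify
  up <- EBImage::resize(cam, w = dim(image)[1], h = dim(image)[2],
                        filter = "bilinear")
  new_saliency_map(normalize_saliency(up), model$model_id, target_class,
                   layer, image_id)
}

#' Occlusion-sensitivity saliency map
#'
#' Slides a square occluding patch (filled with black) over the image and
#' records, per patch position, the drop in the target-class probability.
#' Drops are accumulated per pixel over all windows covering it, averaged
#' by coverage count, clamped at zero and min--max normalized. Serves as a
#' gradient-free cross-check of [gradcam()].
#'
#' @param model A trained `dr_model`.
#' @param image `H x W x 3` array.
#' @param patch_size Side of the occluding patch in pixels.
#' @param stride Window stride in pixels (>= 1). Edge windows are added so
#'   every pixel is covered.
#' @param target_class Grade 0--4; defaults to the predicted label.
#' @param image_id Identifier carried into the result.
#' @param batch_size Occluded variants evaluated per forward pass.
#' @return A `saliency_map` with `layer_id = "occlusion"`.
#' @export
occlusion_map <- function(model, image, patch_size = 8, stride = 4,
                          target_class = NULL, image_id = NA_character_,
                          batch_size = 64) {
  stopifnot(inherits(model, "dr_model"))
  h <- dim(image)[1]; w <- dim(image)[2]
  assert_that(patch_size <= h && patch_size <= w, "patch_size",
              "must not exceed the image size")
  assert_that(stride >= 1, "stride", "must be >= 1")
  p0 <- predict_grades(model, image)
  if (is.null(target_class)) target_class <- which.max(p0[1, ]) - 1L
  base_p <- p0[1, target_class + 1L]

  ys <- unique(c(seq(1, h - patch_size + 1, stride), h - patch_size + 1))
  xs <- unique(c(seq(1, w - patch_size + 1, stride), w - patch_size + 1))
  pos <- expand.grid(y = ys, x = xs)
  npos <- nrow(pos)

  sums <- matrix(0, h, w)
  cover <- matrix(0L, h, w)
  for (s in seq(1, npos, batch_size)) {
    e <- min(s + batch_size - 1, npos)
    nb <- e - s + 1
    xb <- array(0, c(nb, h, w, 3))
    for (j in seq_len(nb)) {
      im <- image
      yy <- pos$y[s + j - 1] + 0:(patch_size - 1)
      xx <- pos$x[s + j - 1] + 0:(patch_size - 1)
      im[yy, xx, ] <- 0
      xb[j, , , ] <- im
    }
    pb <- predict_grades(model, xb)
    for (j in seq_len(nb)) {
      yy <- pos$y[s + j - 1] + 0:(patch_size - 1)
      xx <- pos$x[s + j - 1] + 0:(patch_size - 1)
      sums[yy, xx] <- sums[yy, xx] + (base_p - pb[j, target_class + 1L])
      cover[yy, xx] <- cover[yy, xx] + 1L
    }
  }
  vals <- sums / pmax(cover, 1L)
  vals[cover == 0L] <- 0
  vals <- pmax(vals, 0)
  new_saliency_map(normalize_saliency(vals), model$model_id, target_class,
                   "occlusion", image_id)
}

#' Save a saliency map as grayscale PNG plus a JSON sidecar
#'
#' The PNG stores the normalized \[0, 1\] values at 8-bit depth; the
#' sidecar records model id, image id, target class and layer id so the
#' normalization convention travels with the file.
#' @param sm A `saliency_map`.
#' @param path PNG path; the sidecar is written next to it as
#'   `<path>.json`.
#' @export
save_saliency <- function(sm, path) {
  stopifnot(inherits(sm, "saliency_map"))
  png::writePNG(sm$values, path)
  jsonlite::write_json(
    list(model_id = sm$model_id, image_id = sm$image_id,
         target_class = sm$target_class, layer_id = sm$layer_id,
         normalization = "minmax01"),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_saliency
#' @export
load_saliency <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3) v <- v[, , 1]
  meta <- jsonlite::read_json(paste0(path, ".json"))
  new_saliency_map(v, meta$model_id, meta$target_class, meta$layer_id,
                   meta$image_id %||% NA_character_)
}

#' Write a heatmap overlay PNG for human inspection
#'
#' Blends the image with a red-tinted rendering of the saliency map.
#' The overlay is for reporting only; all scoring uses the raw normalized
#' map.
#' @param image `H x W x 3` array.
#' @param sm A `saliency_map`.
#' @param path Output PNG path.
#' @param alpha Heatmap opacity in \[0, 1\].
#' @export
save_overlay <- function(image, sm, path, alpha = 0.45) {
  v <- sm$values
  out <- image
  for (ch in 1:3) out[, , ch] <- image[, , ch] * (1 - alpha * v)
  out[, , 1] <- out[, , 1] + alpha * v   # red channel carries attention
  png::writePNG(pmin(pmax(out, 0), 1), path)
  invisible(path)
}
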