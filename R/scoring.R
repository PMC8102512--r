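#' Binarize a saliency map with Otsu's method
#'
#' The threshold maximizes the between-class variance over a 256-bin
#' histogram of the map values (bins are left-open on \[0, 1\], matching
#' the 8-bit convention). Pixels strictly above the threshold become 1;
#' ties at the threshold go to background. A constant map yields an
#' all-zero binary map with the constant recorded as the threshold.
#'
#' Class statistics are accumulated from the exact pixel values within
#' each bin, so the selected threshold coincides with an exhaustive
#' between-class-variance search over the 255 candidate cuts.
#'
#' @param map A `saliency_map` or a numeric matrix with values in \[0, 1\].
#' @return A `binary_map`: list with `values` (0/1 integer matrix),
#'   `threshold`, and `source` (model and image ids when available).
#' @export
binarize_otsu <- function(map) {
  v <- if (inherits(map, "saliency_map")) map$values else map
  assert_that(all(v >= 0 & v <= 1), "map", "values must lie in [0, 1]")
  src <- if (inherits(map, "saliency_map"))
    list(model_id = map$model_id, image_id = map$image_id)
  else list(model_id = NA_character_, image_id = NA_character_)

  if (diff(range(v)) == 0) {
    out <- array(0L, dim(v))
    return(structure(list(values = out, threshold = v[1], source = src),
                     class = "binary_map"))
  }

  nb <- 256L
  bin <- pmax(ceiling(as.vector(v) * nb), 1L)  # bin i holds ((i-1)/nb, i/nb]
  counts <- tabulate(bin, nbins = nb)
  sums <- numeric(nb)
  agg <- rowsum(as.vector(v), bin)
  sums[as.integer(rownames(agg))] <- agg[, 1]

  n <- length(v)
  w0 <- cumsum(counts)[1:(nb - 1)]
  s0 <- cumsum(sums)[1:(nb - 1)]
  w1 <- n - w0
  s1 <- sum(v) - s0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, nb - 1)
  sigma_b[valid] <- (w0[valid] / n) * (w1[valid] / n) *
    (s0[valid] / w0[valid] - s1[valid] / w1[valid])^2
  k <- which.max(sigma_b)
  thr <- k / nb
  out <- (v > thr) * 1L
  dim(out) <- dim(v)
  structure(list(values = out, threshold = thr, source = src),
            class = "binary_map")
}

#' @export
print.binary_map <- function(x, ...) {
  cat(sprintf("binary_map %dx%d, threshold %.4f, %d foreground px\n",
              nrow(x$values), ncol(x$values), x$threshold,
              sum(x$values)))
  invisible(x)
}

as_binary_matrix <- function(x) {
  if (inherits(x, "binary_map")) return(x$values)
  if (is.matrix(x) || is.array(x)) return(x)
  stop("expected a binary_map or matrix")
}

#' Intersection over union of two binary maps
#'
#' `|A intersect B| / |A union B|` over pixels. When both maps are empty
#' the score is undefined and `NA` is returned; `NA` scores are excluded
#' from all aggregations.
#'
#' @param detection,mask Binary matrices (or `binary_map`s) of equal
#'   shape.
#' @return A number in \[0, 1\], or `NA` if both are empty.
#' @export
iou <- function(detection, mask) {
  a <- as_binary_matrix(detection)
  b <- as_binary_matrix(mask)
  if (!identical(dim(a), dim(b)))
    validation_error("mask", "shape mismatch with detection")
  uni <- sum(a | b)
  if (uni == 0) return(NA_real_)
  sum(a & b) / uni
}

#' IoU records for a set of detections against component masks
#'
#' Computes one IoU score per (image, model, component).
#'
#' @param detections Named list: `detections[[model_id]][[image_id]]` is a
#'   `binary_map`.
#' @param fundus_list Named list of `annotated_fundus` objects keyed by
#'   image id.
#' @return A data.frame with columns `image_id`, `model_id`, `component`,
#'   `score` (`NA` when undefined).
#' @export
compute_iou_records <- function(detections, fundus_list) {
  rows <- list()
  for (model_id in names(detections)) {
    for (image_id in names(detections[[model_id]])) {
      af <- fundus_list[[image_id]]
      if (is.null(af)) stop("no masks for image ", image_id)
      det <- detections[[model_id]][[image_id]]
      for (comp in dr_components()) {
        rows[[length(rows) + 1]] <- data.frame(
          image_id = image_id, model_id = model_id, component = comp,
          score = iou(det, af$masks[[comp]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Mean IoU aggregated by model and component
#'
#' Arithmetic mean over the defined (non-`NA`) scores in each
#' (model, component) group; the number of defined scores is reported
#' alongside. A group with no defined scores gets `NA`, never zero.
#'
#' @param records Data.frame as from [compute_iou_records()].
#' @return Data.frame with `model_id`, `component`, `mean_iou`,
#'   `n_defined`.
#' @export
mean_iou_by_component <- function(records) {
  assert_that(nrow(records) > 0, "records", "must be non-empty")
  key <- interaction(records$model_id, records$component, drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(g) {
    ok <- !is.na(g$score)
    data.frame(model_id = g$model_id[1], component = g$component[1],
               mean_iou = if (any(ok)) mean(g$score[ok]) else NA_real_,
               n_defined = sum(ok), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$model_id, out$component), ]
}

#' Pairwise inter-model agreement matrix
#'
#' Agreement between two models is the mean, over images, of the IoU of
#' their binarized saliency maps; the optional component-stratified
#' variant intersects both maps with the component mask first. The matrix
#' is symmetric with unit diagonal. Image pairs where both restricted
#' maps are empty are excluded from the mean.
#'
#' @param detections Named list `detections[[model_id]][[image_id]]` of
#'   `binary_map`s; all models must cover the same image set.
#' @param component_masks Optional named list of component masks keyed by
#'   image id (for the stratified variant).
#' @return Square numeric matrix with model ids as dimnames, class
#'   `agreement_matrix`.
#' @export
pairwise_agreement <- function(detections, component_masks = NULL) {
  models <- names(detections)
  assert_that(length(models) >= 1, "detections", "must name >= 1 model")
  image_sets <- lapply(detections, function(d) sort(names(d)))
  for (m in models)
    assert_that(identical(image_sets[[m]], image_sets[[1]]),
                "detections", "models cover different image sets")
  images <- image_sets[[1]]
  A <- matrix(1, length(models), length(models),
              dimnames = list(models, models))
  if (length(models) >= 2) {
    for (i in seq_along(models)) for (j in seq_len(i - 1)) {
      vals <- vapply(images, function(im) {
        a <- as_binary_matrix(detections[[models[i]]][[im]])
        b <- as_binary_matrix(detections[[models[j]]][[im]])
        if (!is.null(component_masks)) {
          mc <- as_binary_matrix(component_masks[[im]])
          a <- a * mc
          b <- b * mc
        }
        iou(a, b)
      }, 0)
      v <- mean(vals, na.rm = TRUE)
      A[i, j] <- A[j, i] <- if (is.nan(v)) NA_real_ else v
    }
  }
  structure(A, class = c("agreement_matrix", class(A)))
}

#' Missed-pathology record for one detection map
#'
#' Lesions are the 4-connected components of the union of the three
#' pathology masks. A lesion counts as detected when the overlap of the
#' detection map with it is at least `tau` of its area (default `tau = 0`:
#' any overlapping pixel counts). The pixel-level missed fraction is also
#' reported for transparency.
#'
#' @param detection A `binary_map` (or binary matrix).
#' @param pathology_masks Named list with the three pathology masks
#'   (an `annotated_fundus` is also accepted).
#' @param tau Minimum overlap fraction for a lesion to count as detected.
#' @return A one-row data.frame: `image_id`, `model_id`, `lesions_total`,
#'   `lesions_missed`, `percent_missed` (`NA` when no lesions),
#'   `percent_missed_pixels`.
#' @export
missed_pathology <- function(detection, pathology_masks, tau = 0) {
  det <- as_binary_matrix(detection)
  if (inherits(pathology_masks, "annotated_fundus"))
    pathology_masks <- pathology_masks$masks[dr_pathology_components()]
  masks <- pathology_masks[dr_pathology_components()]
  for (m in masks)
    if (!identical(dim(m), dim(det)))
      validation_error("pathology_masks", "shape mismatch with detection")
  union_mask <- (Reduce(`+`, masks) > 0) * 1
  labels <- EBImage::bwlabel(union_mask)     # 4-connectivity
  n_lesions <- max(labels)
  ids <- if (inherits(detection, "binary_map")) detection$source
         else list(model_id = NA_character_, image_id = NA_character_)
  if (n_lesions == 0) {
    return(data.frame(image_id = ids$image_id, model_id = ids$model_id,
                      lesions_total = 0L, lesions_missed = 0L,
                      percent_missed = NA_real_,
                      percent_missed_pixels = NA_real_,
                      stringsAsFactors = FALSE))
  }
  lab_v <- as.vector(labels)
  det_v <- as.vector(det)
  area <- tabulate(lab_v, nbins = n_lesions)
  hit <- tabulate(lab_v[det_v > 0], nbins = n_lesions)
  detected <- if (tau <= 0) hit > 0 else hit >= tau * area
  missed <- sum(!detected)
  data.frame(image_id = ids$image_id, model_id = ids$model_id,
             lesions_total = n_lesions, lesions_missed = missed,
             percent_missed = 100 * missed / n_lesions,
             percent_missed_pixels =
               100 * sum(area - hit) / sum(area),
             stringsAsFactors = FALSE)
}

#' Randomly displace pathology masks within the field of view
#'
#' Produces the permutation-null version of an annotated fundus: each
#' pathology mask is independently rotated by a uniform angle and
#' translated by a uniform shift, then clipped to the field of view. Used
#' to test whether saliency maps overlap true lesion positions more than
#' chance placement would.
#'
#' @param af An `annotated_fundus`.
#' @param spec The [scene_spec()] that generated it (for the FOV).
#' @param seed RNG seed.
#' @param max_shift Maximum translation as a fraction of image size.
#' @return The `annotated_fundus` with displaced pathology masks.
#' @export
randomize_pathology_masks <- function(af, spec, seed = 1L,
                                      max_shift = 0.25) {
  out <- af
  fov <- fov_mask(spec)
  for (k in seq_along(dr_pathology_components())) {
    comp <- dr_pathology_components()[k]
    out$masks[[comp]] <- randomize_mask(af$masks[[comp]],
                                        within = fov,
                                        seed = derive_seed(seed, comp),
                                        max_shift = max_shift)
  }
  out
}

#' Randomly rotate and translate a single binary mask
#'
#' One draw of the placement null: the mask is rotated by a uniform angle
#' about the image center and translated by a uniform shift, with
#' nearest-neighbour resampling. To keep the null exchangeable with the
#' generator's placement distribution, draws whose mask would be clipped
#' by the `within` region (more than `1 - min_retention` of its pixels
#' lost) are rejected and redrawn; the best draw is kept if none fully
#' qualifies. Without rejection, displaced masks pile up against the
#' field-of-view boundary where saliency is systematically rarer, and the
#' null is biased low for any detector -- trained or not.
#'
#' @param mask Binary matrix.
#' @param within Optional admissible region (e.g. the field of view);
#'   `NULL` admits the whole frame.
#' @param seed RNG seed.
#' @param max_shift Maximum translation as a fraction of image size.
#' @param min_retention Minimum fraction of mask pixels that must survive
#'   clipping for a draw to be accepted.
#' @return The displaced 0/1 integer matrix.
#' @export
randomize_mask <- function(mask, within = NULL, seed = 1L,
                           max_shift = 0.25, min_retention = 0.9) {
  n <- nrow(mask)
  area <- sum(mask)
  if (area == 0) {
    m0 <- mask
    storage.mode(m0) <- "integer"
    return(m0)
  }
  with_seed(seed, {
    best <- NULL
    best_kept <- -1
    for (attempt in 1:20) {
      theta <- stats::runif(1, 0, 2 * pi)
      dy <- stats::runif(1, -max_shift, max_shift) * n
      dx <- stats::runif(1, -max_shift, max_shift) * n
      m <- affine_matrix(n, theta, dy, dx, 1)
      w <- EBImage::affine(mask + 0, m, filter = "none", bg.col = 0,
                           antialias = FALSE)
      w <- w > 0.5
      if (!is.null(within)) w <- w & within
      kept <- sum(w)
      if (kept > best_kept) {
        best <- w
        best_kept <- kept
      }
      if (kept >= min_retention * area) break
    }
    w <- if (best_kept > 0) best else mask > 0
    w <- w + 0L
    dim(w) <- dim(mask)
    w
  })
}
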