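test_that("gradcam matches a manual chain-rule computation", {
  # one conv layer, two channels; dense head reads only channel 1, so the
  # class score is W_d[1,c]/HW * sum(A_1). By hand:
  #   d score_c / d A_1 = W_d[1,c] / (H*W),  d score_c / d A_2 = 0
  #   channel weights: (W_d[1,c]/HW, 0)
  #   cam = relu(W_d[1,c]/HW * A_1)
  h <- 8
  conv_W <- withr::with_seed(2, array(rnorm(3 * 3 * 3 * 2),
                                      c(3, 3, 3, 2)))
  conv_b <- c(0.1, -0.2)
  dense_W <- rbind(c(2, -1, 0.5, 0, 1), c(0, 0, 0, 0, 0))
  dense_b <- numeric(5)
  m <- manual_conv_model(conv_W, conv_b, dense_W, dense_b, h)
  img <- withr::with_seed(3, array(runif(h * h * 3), c(h, h, 3)))

  for (target in c(0L, 1L)) {
    sm <- gradcam(m, img, target_class = target, layer = "c1")
    A <- drsaliency:::nn_forward(m, img)$outs[["c1"]]
    a1 <- A[1, , , 1]
    expected <- pmax((dense_W[1, target + 1] / (h * h)) * a1, 0)
    expected <- drsaliency:::normalize_saliency(
      EBImage::resize(expected, w = h, h = h, filter = "bilinear"))
    expect_equal(sm$values, expected, tolerance = 1e-5)
  }
  # a class with negative head weight rectifies to an all-zero map
  sm_neg <- gradcam(m, img, target_class = 1L, layer = "c1")
  a1 <- drsaliency:::nn_forward(m, img)$outs[["c1"]][1, , , 1]
  if (all(a1 >= 0)) expect_true(all(sm_neg$values == 0))
})

test_that("the default target class is the predicted label", {
  qf <- fixture_quadrant()
  te <- qf$manifest[qf$manifest$split == "test", ]
  af <- read_annotated(te[1, ])
  sm_default <- gradcam(qf$model, af$image)
  pred <- which.max(predict_grades(qf$model, af$image)[1, ]) - 1L
  sm_explicit <- gradcam(qf$model, af$image, target_class = pred)
  expect_identical(sm_default$values, sm_explicit$values)
  expect_identical(sm_default$target_class, as.integer(pred))
})

test_that("saliency maps live on [0,1] at image resolution", {
  qf <- fixture_quadrant()
  te <- qf$manifest[qf$manifest$split == "test", ]
  af <- read_annotated(te[1, ])
  for (sm in list(gradcam(qf$model, af$image),
                  occlusion_map(qf$model, af$image, patch_size = 8,
                                stride = 8))) {
    expect_identical(dim(sm$values), dim(af$image)[1:2])
    expect_gte(min(sm$values), 0)
    expect_lte(max(sm$values), 1)
    expect_equal(max(sm$values), 1)   # non-constant map attains 1
  }
  expect_error(gradcam(qf$model, af$image, layer = "nope"), "layer")
})

test_that("occlusion of a constant-logit model is identically zero", {
  m <- manual_conv_model(array(0, c(3, 3, 3, 2)), c(0, 0),
                         matrix(0, 2, 5), numeric(5), 16)
  img <- withr::with_seed(5, array(runif(16 * 16 * 3), c(16, 16, 3)))
  om <- occlusion_map(m, img, patch_size = 4, stride = 4)
  expect_true(all(om$values == 0))
  # one full-image window: constant pre-normalization map, so all zeros
  om1 <- occlusion_map(m, img, patch_size = 16, stride = 16)
  expect_true(all(om1$values == 0))
})

test_that("occlusion matches a brute-force sliding-window loop", {
  qf <- fixture_quadrant()
  te <- qf$manifest[qf$manifest$split == "test", ]
  af <- read_annotated(te[te$grade == 4, ][1, ])
  img <- af$image
  patch <- 8; stride <- 4
  om <- occlusion_map(qf$model, img, patch_size = patch, stride = stride)

  target <- om$target_class
  p0 <- predict_grades(qf$model, img)[1, target + 1]
  h <- dim(img)[1]
  sums <- matrix(0, h, h); cover <- matrix(0, h, h)
  ys <- unique(c(seq(1, h - patch + 1, stride), h - patch + 1))
  for (y in ys) for (x in ys) {
    oc <- img
    oc[y:(y + patch - 1), x:(x + patch - 1), ] <- 0
    drop <- p0 - predict_grades(qf$model, oc)[1, target + 1]
    sums[y:(y + patch - 1), x:(x + patch - 1)] <-
      sums[y:(y + patch - 1), x:(x + patch - 1)] + drop
    cover[y:(y + patch - 1), x:(x + patch - 1)] <-
      cover[y:(y + patch - 1), x:(x + patch - 1)] + 1
  }
  want <- drsaliency:::normalize_saliency(pmax(sums / pmax(cover, 1), 0))
  expect_equal(om$values, want, tolerance = 1e-10)
})

test_that("both saliency methods localize a known discriminative region", {
  qf <- fixture_quadrant()
  te <- qf$manifest[qf$manifest$split == "test", ]
  g4 <- te[te$grade == 4, ]
  expect_gte(nrow(g4), 1)
  cors <- numeric(0)
  for (i in seq_len(nrow(g4))) {
    af <- read_annotated(g4[i, ])
    smg <- gradcam(qf$model, af$image)
    smo <- occlusion_map(qf$model, af$image, patch_size = 8, stride = 4)
    top_g <- which(smg$values == max(smg$values), arr.ind = TRUE)[1, ]
    top_o <- which(smo$values == max(smo$values), arr.ind = TRUE)[1, ]
    # evidence for grade 4 sits in the top-left quadrant by construction
    expect_true(all(top_g <= 16))
    expect_true(all(top_o <= 16))
    cors <- c(cors, stats::cor(as.vector(smg$values),
                               as.vector(smo$values),
                               method = "spearman"))
  }
  expect_gt(mean(cors), 0)
})

test_that("normalization is idempotent and flags constants", {
  v <- withr::with_seed(8, matrix(runif(64, 0.2, 0.6), 8, 8))
  n1 <- normalize_saliency(v)
  expect_identical(normalize_saliency(n1), n1)
  expect_true(all(normalize_saliency(matrix(0.4, 4, 4)) == 0))
})

test_that("saliency PNG + sidecar round trip preserves identity", {
  qf <- fixture_quadrant()
  te <- qf$manifest[qf$manifest$split == "test", ]
  af <- read_annotated(te[1, ])
  sm <- gradcam(qf$model, af$image, image_id = af$image_id)
  path <- file.path(withr::local_tempdir(), "h.png")
  save_saliency(sm, path)
  back <- load_saliency(path)
  expect_identical(back$model_id, sm$model_id)
  expect_identical(back$image_id, af$image_id)
  expect_identical(back$target_class, sm$target_class)
  expect_lt(max(abs(back$values - sm$values)), 1 / 255)
})
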