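# Shared fixtures, memoised so expensive objects are built once per run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

tiny_spec <- function(...) scene_spec(image_size = 64, ...)

# A grade-3 annotated fundus (plenty of lesions) at 64px.
fixture_fundus <- function() fixture("fundus_g3", function() {
  generate_image(grade_scene_specs(tiny_spec())[["3"]], seed = 77)
})

# A small labelled dataset on disk: 6 images per grade at 64px.
fixture_dataset <- function() fixture("dataset", function() {
  dir <- file.path(tempdir(), "drsal_fixture_data")
  man <- generate_dataset(tiny_spec(), 6, dir, seed = 555)
  list(dir = dir, manifest = man)
})

# Build an annotated_fundus directly from matrices (for hand-drawn cases).
manual_fundus <- function(image, masks, grade = 0L, image_id = "manual") {
  n <- nrow(image[, , 1])
  full <- stats::setNames(lapply(dr_components(), function(comp) {
    m <- masks[[comp]]
    if (is.null(m)) m <- matrix(0L, n, n)
    storage.mode(m) <- "integer"
    m
  }), dr_components())
  structure(list(image = image, masks = full, grade = as.integer(grade),
                 image_id = image_id),
            class = "annotated_fundus")
}

# Hand-built one-conv-layer model: input (h x w x 1-ish) -> conv(k) ->
# gap -> dense. Weights supplied explicitly so gradients can be derived by
# hand. Returns a dr_model usable with gradcam()/predict_grades().
manual_conv_model <- function(conv_W, conv_b, dense_W, dense_b,
                              input_size) {
  nodes <- list(
    drsaliency:::nn_node("c1", "conv", "input",
                         list(W = conv_W, b = conv_b), stride = 1L),
    drsaliency:::nn_node("gap", "gap", "c1"),
    drsaliency:::nn_node("logits", "dense", "gap",
                         list(W = dense_W, b = dense_b)))
  structure(list(nodes = nodes,
                 config = model_config("plain", input_size = max(input_size, 16),
                                       seed = 1),
                 model_id = "manual", gradcam_layer = "c1",
                 trained = TRUE, history = NULL),
            class = "dr_model")
}

# Exhaustive Otsu oracle: direct between-class-variance sweep over the 255
# candidate cuts, computed from raw pixel values.
otsu_oracle_threshold <- function(v) {
  v <- as.vector(v)
  n <- length(v)
  cands <- (1:255) / 256
  sb <- vapply(cands, function(t) {
    n0 <- sum(v <= t)
    if (n0 == 0 || n0 == n) return(-Inf)
    (n0 / n) * ((n - n0) / n) * (mean(v[v <= t]) - mean(v[v > t]))^2
  }, 0)
  cands[which.max(sb)]
}

# Naive double-loop IoU oracle.
iou_oracle <- function(a, b) {
  inter <- 0L; uni <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    ai <- a[i, j] > 0; bi <- b[i, j] > 0
    if (ai && bi) inter <- inter + 1L
    if (ai || bi) uni <- uni + 1L
  }
  if (uni == 0) NA_real_ else inter / uni
}

# A complete reduced pipeline run: one variant, 8 images per grade at
# 64 px, 3 full epochs. Shared by the pipeline tests and the end-to-end
# acceptance check.
fixture_smoke_run <- function() fixture("smoke_run", function() {
  out_dir <- file.path(tempdir(), "drsal_smoke_run")
  cfg <- run_config(
    scene = tiny_spec(),
    n_per_grade = 8,
    rebalance_cap = 8,
    model_variants = "residual",
    base_channels = 4,
    train = train_config(head_epochs = 1, full_epochs = 2, patience = 2,
                         batch_size = 16, seed = 7),
    out_dir = out_dir,
    seed = 99)
  summary <- suppressMessages(run_pipeline(cfg))
  list(config = cfg, summary = summary, dir = out_dir)
})

# A dataset + trained model pair for saliency tests where the
# class-discriminative evidence sits in a known image quadrant.
fixture_quadrant <- function() fixture("quadrant", function() {
  dir <- file.path(tempdir(), "drsal_quadrant")
  dir.create(dir, showWarnings = FALSE)
  withr::with_seed(42, {
    mk <- function(g, i) {
      img <- array(stats::runif(32 * 32 * 3, 0, 0.2), c(32, 32, 3))
      if (g == 4) {
        r <- sample(3:12, 1); c <- sample(3:12, 1)
      } else {
        r <- sample(19:28, 1); c <- sample(19:28, 1)
      }
      img[r:(r + 3), c:(c + 3), ] <- 0.95
      masks <- list(other = matrix(1L, 32, 32))
      af <- manual_fundus(img, masks, grade = g,
                          image_id = sprintf("q_g%d_%02d", g, i))
      write_annotated(af, dir)
    }
    rows <- c(lapply(1:30, function(i) mk(0L, i)),
              lapply(1:30, function(i) mk(4L, i)))
  })
  man <- split_manifest(do.call(rbind, rows), seed = 3)
  m <- build_model(model_config("residual", input_size = 32,
                                base_channels = 4, seed = 5))
  m <- suppressMessages(train_model(
    m, man[man$split == "train", ], man[man$split == "val", ],
    train_config(head_epochs = 2, full_epochs = 10, patience = 10,
                 batch_size = 8, seed = 6)))
  list(model = m, manifest = man)
})
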