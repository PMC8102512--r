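#' Configuration for a small CNN grade classifier
#'
#' The four variants are compact analogues of the architecture families
#' commonly used for fundus grading, each carrying that family's
#' distinguishing motif:
#' \describe{
#'   \item{plain}{stacked single-path convolutions (the baseline pattern of
#'     early deep classifiers).}
#'   \item{residual}{additive identity skip connections (the ResNet
#'     motif).}
#'   \item{multibranch}{parallel convolutions over the same tensor whose
#'     results are concatenated (the Inception-block motif).}
#'   \item{separable}{depth-wise convolution followed by a 1x1 pointwise
#'     convolution (the Xception motif).}
#' }
#' All variants share the same skeleton -- a stride-2 stem, two variant
#' blocks, global average pooling and a 5-way softmax head -- so that
#' differences in saliency behaviour are attributable to the motif.
#'
#' @param variant One of `"plain"`, `"residual"`, `"multibranch"`,
#'   `"separable"`.
#' @param input_size Input image side in pixels (square RGB input).
#' @param base_channels Channel width of the stem; later stages use 2x and
#'   4x this width.
#' @param num_classes Number of grade classes; fixed at 5 for the 0--4
#'   diabetic retinopathy scale.
#' @param seed Seed for Glorot-uniform weight initialization.
#' @return A `model_config` list.
#' @export
model_config <- function(variant = c("plain", "residual", "multibranch",
                                     "separable"),
                         input_size = 128, base_channels = 8,
                         num_classes = 5, seed = 1L) {
  variant <- match.arg(variant)
  assert_that(input_size >= 16, "input_size", "must be >= 16")
  assert_that(base_channels >= 2, "base_channels", "must be >= 2")
  assert_that(num_classes == 5, "num_classes",
              "must be 5 (grades 0..4)")
  structure(list(variant = variant, input_size = as.integer(input_size),
                 base_channels = as.integer(base_channels),
                 num_classes = 5L, seed = as.integer(seed)),
            class = "model_config")
}

#' Build an (untrained) CNN grade classifier
#'
#' Constructs the network graph for a [model_config()] with seeded
#' Glorot-uniform weights. The returned model exposes everything Grad-CAM
#' needs: per-node activations, gradients of any class score with respect
#' to them, and the identifier of the last convolutional feature layer
#' (`$gradcam_layer`).
#'
#' @param config A [model_config()].
#' @param model_id Identifier stored with predictions and saliency maps;
#'   defaults to the variant name.
#' @return An object of class `dr_model`.
#' @export
build_model <- function(config, model_id = config$variant) {
  stopifnot(inherits(config, "model_config"))
  C <- config$base_channels
  nodes <- list()
  push <- function(...) nodes[[length(nodes) + 1]] <<- nn_node(...)

  with_seed(config$seed, {
    ## stem: 3x3 stride-2 conv
    push("stem", "conv", "input", init_conv(3, 3, C), stride = 2)
    push("stem_relu", "relu", "stem")

    block <- function(tag, input, cin, cout, stride) {
      out_id <- paste0(tag, "_out")
      switch(config$variant,
        plain = {
          push(paste0(tag, "_c1"), "conv", input, init_conv(3, cin, cout),
               stride)
          push(paste0(tag, "_r1"), "relu", paste0(tag, "_c1"))
          push(paste0(tag, "_c2"), "conv", paste0(tag, "_r1"),
               init_conv(3, cout, cout), 1)
          push(out_id, "relu", paste0(tag, "_c2"))
        },
        residual = {
          push(paste0(tag, "_c1"), "conv", input, init_conv(3, cin, cout),
               stride)
          push(paste0(tag, "_r1"), "relu", paste0(tag, "_c1"))
          push(paste0(tag, "_c2"), "conv", paste0(tag, "_r1"),
               init_conv(3, cout, cout), 1)
          ## additive identity skip over the second conv
          push(paste0(tag, "_add"), "add",
               c(paste0(tag, "_c2"), paste0(tag, "_r1")))
          push(out_id, "relu", paste0(tag, "_add"))
        },
        multibranch = {
          ## two parallel convolutions over the same tensor, concatenated
          half <- cout %/% 2
          push(paste0(tag, "_b3"), "conv", input, init_conv(3, cin, half),
               stride)
          push(paste0(tag, "_b1"), "conv", input,
               init_conv(1, cin, cout - half), stride)
          push(paste0(tag, "_cat"), "concat",
               c(paste0(tag, "_b3"), paste0(tag, "_b1")))
          push(out_id, "relu", paste0(tag, "_cat"))
        },
        separable = {
          ## depth-wise then 1x1 pointwise convolution
          push(paste0(tag, "_dw"), "dwconv", input, init_dwconv(3, cin),
               stride)
          push(paste0(tag, "_pw"), "conv", paste0(tag, "_dw"),
               init_conv(1, cin, cout), 1)
          push(out_id, "relu", paste0(tag, "_pw"))
        })
      out_id
    }

    b1 <- block("b1", "stem_relu", C, 2L * C, stride = 2)
    b2 <- block("b2", b1, 2L * C, 4L * C, stride = 1)

    push("gap", "gap", b2)
    push("logits", "dense", "gap", init_dense(4L * C, config$num_classes))
  })

  structure(list(nodes = nodes, config = config, model_id = model_id,
                 gradcam_layer = "b2_out", trained = FALSE,
                 history = NULL),
            class = "dr_model")
}

#' @export
print.dr_model <- function(x, ...) {
  cat(sprintf("dr_model '%s' (%s, input %dx%d, %s)\n", x$model_id,
              x$config$variant, x$config$input_size, x$config$input_size,
              if (x$trained) "trained" else "untrained"))
  cat("  nodes:", paste(vapply(x$nodes, `[[`, "", "id"), collapse = " "),
      "\n")
  invisible(x)
}

#' Structural motif check for a model variant
#'
#' Verifies, from the network graph itself, that the variant's
#' distinguishing motif is present: an additive skip for `residual`, >= 2
#' parallel convolution paths feeding a concatenation for `multibranch`,
#' and a depth-wise convolution followed by a 1x1 pointwise convolution
#' for `separable`. `plain` requires the absence of all three motifs.
#'
#' @param model A `dr_model`.
#' @return `TRUE` if the motif is present, else `FALSE`.
#' @export
has_variant_motif <- function(model) {
  ops <- vapply(model$nodes, `[[`, "", "op")
  ids <- vapply(model$nodes, `[[`, "", "id")
  by_id <- stats::setNames(model$nodes, ids)
  has_add <- "add" %in% ops
  has_concat <- any(vapply(model$nodes, function(n) {
    n$op == "concat" &&
      all(vapply(n$inputs, function(i) by_id[[i]]$op == "conv",
                 TRUE))
  }, TRUE))
  has_sep <- any(vapply(model$nodes, function(n) {
    n$op == "conv" && dim(n$params$W)[1] == 1 &&
      by_id[[n$inputs[1]]]$op == "dwconv"
  }, TRUE))
  switch(model$config$variant,
         plain = !has_add && !has_concat && !has_sep,
         residual = has_add,
         multibranch = has_concat,
         separable = has_sep)
}

#' Predict grade probabilities
#'
#' @param model A `dr_model`.
#' @param x A single image (`H x W x 3`) or a batch (`N x H x W x 3`).
#' @return `N x 5` matrix of class probabilities, columns named `"0"`..
#'   `"4"`; rows sum to 1.
#' @export
predict_grades <- function(model, x) {
  stopifnot(inherits(model, "dr_model"))
  d <- dim(x)
  if (length(d) == 3) dim(x) <- c(1, d)
  d <- dim(x)
  if (d[2] != model$config$input_size || d[3] != model$config$input_size ||
      d[4] != 3)
    validation_error("x", sprintf("expected %1$dx%1$dx3 input",
                                  model$config$input_size))
  probs <- softmax(nn_forward(model, x)$logits)
  colnames(probs) <- as.character(0:4)
  probs
}

#' @rdname predict_grades
#' @param ... Passed to [predict_grades()].
#' @param object A `dr_model`.
#' @export
predict.dr_model <- function(object, x, ...) predict_grades(object, x)

#' Save / load a model
#' @param model A `dr_model`.
#' @param path File path (`.rds`).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  log_info("saved model '%s' to %s (md5 %s)", model$model_id, path,
           content_hash(path))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "dr_model"))
  m
}
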