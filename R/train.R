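#' Training configuration
#'
#' The training schedule has two phases: the classification head alone is
#' trained first (with all convolutional weights frozen), then the entire
#' model is fine-tuned with early stopping on validation loss. Defaults
#' follow the conventional fundus-grading recipe: 5 head epochs, up to 100
#' full-model epochs with patience 20, Adam at learning rate 0.001 and
#' categorical cross-entropy loss.
#'
#' @param head_epochs Epochs of head-only training (phase 1).
#' @param full_epochs Maximum epochs of full-model training (phase 2).
#' @param patience Early-stopping patience, in epochs without validation
#'   loss improvement; must be <= `full_epochs` (when `full_epochs` > 0).
#' @param learning_rate Adam step size (> 0).
#' @param batch_size Mini-batch size.
#' @param seed RNG seed for shuffling.
#' @param augment_params Optional list of [augment()] arguments applied to
#'   each training image on every epoch (`NULL` disables augmentation).
#' @return A `train_config` list.
#' @export
train_config <- function(head_epochs = 5, full_epochs = 100, patience = 20,
                         learning_rate = 0.001, batch_size = 32, seed = 1L,
                         augment_params = NULL) {
  assert_that(head_epochs >= 0, "head_epochs", "must be >= 0")
  assert_that(full_epochs >= 0, "full_epochs", "must be >= 0")
  assert_that(full_epochs == 0 || patience <= full_epochs, "patience",
              "must be <= full_epochs")
  assert_that(learning_rate > 0, "learning_rate", "must be > 0")
  assert_that(batch_size >= 1, "batch_size", "must be >= 1")
  structure(list(head_epochs = as.integer(head_epochs),
                 full_epochs = as.integer(full_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 augment_params = augment_params),
            class = "train_config")
}

#' Load all images of a manifest into a batch array
#'
#' @param manifest A manifest data.frame.
#' @return List with `x` (`N x H x W x 3` array), `y` (integer grades) and
#'   `ids`.
#' @export
load_manifest_images <- function(manifest) {
  validate_manifest(manifest, check_files = TRUE)
  afs <- lapply(seq_len(nrow(manifest)),
                function(i) read_annotated(manifest[i, ]))
  h <- dim(afs[[1]]$image)[1]; w <- dim(afs[[1]]$image)[2]
  x <- array(0, c(length(afs), h, w, 3))
  for (i in seq_along(afs)) x[i, , , ] <- afs[[i]]$image
  list(x = x, y = vapply(afs, `[[`, 0L, "grade"),
       ids = vapply(afs, `[[`, "", "image_id"))
}

cross_entropy <- function(probs, y) {
  ## y: integer grades 0..4
  p <- probs[cbind(seq_along(y), y + 1L)]
  -mean(log(pmax(p, 1e-12)))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0)
}

adam_step <- function(state, params, grads, lr, which_params,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in which_params) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(state = state, params = params)
}

## flatten per-node gradient list into "id.W"/"id.b" names
flatten_pgrads <- function(pgrads) {
  out <- list()
  for (id in names(pgrads)) {
    out[[paste0(id, ".W")]] <- pgrads[[id]]$W
    out[[paste0(id, ".b")]] <- pgrads[[id]]$b
  }
  out
}

eval_model <- function(model, x, y, batch_size = 64) {
  n <- dim(x)[1]
  probs <- matrix(0, n, 5)
  for (s in seq(1, n, batch_size)) {
    e <- min(s + batch_size - 1, n)
    probs[s:e, ] <- softmax(nn_forward(model,
                                       x[s:e, , , , drop = FALSE])$logits)
  }
  list(loss = cross_entropy(probs, y),
       acc = mean(max.col(probs) - 1L == y),
       probs = probs)
}

#' Train a CNN grade classifier
#'
#' Runs the two-phase schedule of [train_config()]: phase 1 updates only
#' the dense head (convolutional weights frozen), phase 2 updates the full
#' model with early stopping monitored on validation loss. The weights
#' achieving the lowest validation loss across all epochs are restored at
#' the end. Deterministic given the config seed (single-threaded
#' floating-point pipeline).
#'
#' @param model An untrained (or previously trained) `dr_model`.
#' @param train_manifest,val_manifest Manifests of labelled images.
#' @param cfg A [train_config()].
#' @return The trained `dr_model`, with a `history` data.frame (columns
#'   `epoch`, `phase`, `train_loss`, `train_acc`, `val_loss`, `val_acc`)
#'   and `best_epoch` attached.
#' @export
train_model <- function(model, train_manifest, val_manifest,
                        cfg = train_config()) {
  stopifnot(inherits(model, "dr_model"), inherits(cfg, "train_config"))
  assert_that(nrow(train_manifest) > 0, "train_manifest", "is empty")
  assert_that(nrow(val_manifest) > 0, "val_manifest", "is empty")
  tr <- load_manifest_images(train_manifest)
  va <- load_manifest_images(val_manifest)

  params <- nn_params(model)
  opt <- adam_init(params)
  head_params <- grep("^logits\\.", names(params), value = TRUE)
  all_params <- names(params)

  history <- list()
  best <- list(loss = Inf, params = params, epoch = 0L)
  epoch <- 0L
  ntr <- dim(tr$x)[1]

  run_epoch <- function(params, trainable, rng_epoch) {
    ord <- with_seed(derive_seed(cfg$seed, paste0("shuffle", rng_epoch)),
                     sample(ntr))
    tot_loss <- 0; tot_correct <- 0
    for (s in seq(1, ntr, cfg$batch_size)) {
      idx <- ord[s:min(s + cfg$batch_size - 1, ntr)]
      xb <- tr$x[idx, , , , drop = FALSE]
      yb <- tr$y[idx]
      if (!is.null(cfg$augment_params)) {
        for (j in seq_along(idx)) {
          xb[j, , , ] <- augment_image(
            xb[j, , , ], cfg$augment_params,
            seed = derive_seed(cfg$seed,
                               sprintf("aug_%d_%d", rng_epoch, idx[j])))
        }
      }
      model_b <- nn_set_params(model, params)
      fw <- nn_forward(model_b, xb)
      probs <- softmax(fw$logits)
      loss <- cross_entropy(probs, yb)
      if (!is.finite(loss))
        stop(sprintf("non-finite training loss at epoch %d (batch %d)",
                     rng_epoch, s))
      tot_loss <- tot_loss + loss * length(idx)
      tot_correct <- tot_correct + sum(max.col(probs) - 1L == yb)
      onehot <- matrix(0, length(yb), 5)
      onehot[cbind(seq_along(yb), yb + 1L)] <- 1
      dlogits <- (probs - onehot) / length(yb)
      bw <- nn_backward(model_b, fw$outs, dlogits)
      step <- adam_step(opt, params, flatten_pgrads(bw$pgrads),
                        cfg$learning_rate, trainable)
      opt <<- step$state
      params <- step$params
    }
    list(params = params, loss = tot_loss / ntr, acc = tot_correct / ntr)
  }

  record <- function(phase, res, params) {
    epoch <<- epoch + 1L
    vm <- eval_model(nn_set_params(model, params), va$x, va$y)
    history[[epoch]] <<- data.frame(
      epoch = epoch, phase = phase, train_loss = res$loss,
      train_acc = res$acc, val_loss = vm$loss, val_acc = vm$acc)
    if (vm$loss < best$loss)
      best <<- list(loss = vm$loss, params = params, epoch = epoch)
    vm$loss
  }

  ## phase 1: head only
  for (e in seq_len(cfg$head_epochs)) {
    res <- run_epoch(params, head_params, epoch + 1L)
    params <- res$params
    record("head", res, params)
  }

  ## phase 2: full model, early stopping on validation loss
  opt <- adam_init(params)   # fresh optimizer state for fine-tuning
  since_best <- 0L
  best_phase2 <- Inf
  for (e in seq_len(cfg$full_epochs)) {
    res <- run_epoch(params, all_params, epoch + 1L)
    params <- res$params
    vloss <- record("full", res, params)
    if (vloss < best_phase2) {
      best_phase2 <- vloss
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= cfg$patience) {
        log_info("early stopping at epoch %d (no val improvement for %d)",
                 epoch, cfg$patience)
        break
      }
    }
  }

  model <- nn_set_params(model, best$params)
  model$trained <- TRUE
  model$history <- do.call(rbind, history)
  model$best_epoch <- best$epoch
  model$train_config <- cfg
  log_info("trained '%s': %d epochs, best val loss %.4f at epoch %d",
           model$model_id, epoch, best$loss, best$epoch)
  model
}
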