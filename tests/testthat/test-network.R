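# The engine is exercised through internal helpers; its correctness
# underwrites both training and Grad-CAM.

conv_oracle <- function(x, W, b, stride) {
  # direct quadruple loop over TF-style "same"-padded windows
  k <- dim(W)[1]; cin <- dim(W)[3]; cout <- dim(W)[4]
  H <- dim(x)[1]; Wd <- dim(x)[2]
  ph <- drsaliency:::same_pad(H, k, stride)
  pw <- drsaliency:::same_pad(Wd, k, stride)
  xp <- array(0, c(H + ph$beg + ph$end, Wd + pw$beg + pw$end, cin))
  xp[ph$beg + seq_len(H), pw$beg + seq_len(Wd), ] <- x
  out <- array(0, c(ph$out, pw$out, cout))
  for (i in seq_len(ph$out)) for (j in seq_len(pw$out))
    for (co in seq_len(cout)) {
      acc <- b[co]
      for (di in 1:k) for (dj in 1:k) for (ci in seq_len(cin))
        acc <- acc + xp[(i - 1) * stride + di, (j - 1) * stride + dj,
                        ci] * W[di, dj, ci, co]
      out[i, j, co] <- acc
    }
  out
}

test_that("convolution matches a direct sliding-window oracle", {
  withr::with_seed(11, {
    for (case in list(list(h = 7, cin = 2, cout = 3, s = 1),
                      list(h = 8, cin = 3, cout = 2, s = 2),
                      list(h = 9, cin = 1, cout = 4, s = 2))) {
      x <- array(rnorm(case$h^2 * case$cin), c(1, case$h, case$h,
                                               case$cin))
      W <- array(rnorm(9 * case$cin * case$cout),
                 c(3, 3, case$cin, case$cout))
      b <- rnorm(case$cout)
      got <- drsaliency:::conv_forward(x, W, b, case$s)
      want <- conv_oracle(x[1, , , , drop = TRUE] |>
                            array(c(case$h, case$h, case$cin)),
                          W, b, case$s)
      expect_equal(got[1, , , ], want, tolerance = 1e-10)
    }
  })
})

test_that("backpropagation matches numerical gradients for all variants", {
  h <- 8
  for (variant in c("plain", "residual", "multibranch", "separable")) {
    m <- build_model(model_config(variant, input_size = 16,
                                  base_channels = 2, seed = 3))
    x <- withr::with_seed(5, array(runif(h * h * 3), c(1, h, h, 3)))
    y <- 2L
    loss_fn <- function(params) {
      mm <- drsaliency:::nn_set_params(m, params)
      probs <- drsaliency:::softmax(drsaliency:::nn_forward(mm, x)$logits)
      -log(probs[1, y + 1])
    }
    params <- drsaliency:::nn_params(m)
    fw <- drsaliency:::nn_forward(m, x)
    probs <- drsaliency:::softmax(fw$logits)
    onehot <- matrix(0, 1, 5); onehot[1, y + 1] <- 1
    bw <- drsaliency:::nn_backward(m, fw$outs, probs - onehot)
    grads <- drsaliency:::flatten_pgrads(bw$pgrads)
    eps <- 1e-5
    f0 <- loss_fn(params)
    checked <- 0L
    withr::with_seed(7, {
      for (nm in names(params)) {
        n_el <- length(params[[nm]])
        for (idx in sample(n_el, min(5, n_el))) {
          pp <- params; pp[[nm]][idx] <- pp[[nm]][idx] + eps
          pm <- params; pm[[nm]][idx] <- pm[[nm]][idx] - eps
          fp <- loss_fn(pp); fm <- loss_fn(pm)
          # one-sided slopes disagree only when the perturbation crosses
          # a relu kink; the two-sided difference is invalid there
          if (abs((fp - f0) / eps - (f0 - fm) / eps) >
                3e-5 * (1 + abs(grads[[nm]][idx]))) next
          num <- (fp - fm) / (2 * eps)
          expect_equal(grads[[nm]][idx], num, tolerance = 1e-4)
          checked <- checked + 1L
        }
      }
    })
    # the kink filter must not have eaten the test
    expect_gt(checked, 0.6 * length(params) * 2)
  }
})

test_that("gradients with respect to activations pass the same check", {
  # perturb the input image and compare against the backpropagated
  # gradient at the input node (the same path Grad-CAM uses at any layer)
  m <- build_model(model_config("residual", input_size = 16,
                                base_channels = 2, seed = 9))
  x <- withr::with_seed(13, array(runif(8 * 8 * 3), c(1, 8, 8, 3)))
  fw <- drsaliency:::nn_forward(m, x)
  target <- 4L
  dl <- matrix(0, 1, 5); dl[1, target + 1] <- 1
  bw <- drsaliency:::nn_backward(m, fw$outs, dl, want_params = FALSE)
  din <- bw$douts[["input"]]
  eps <- 1e-5
  score <- function(xx) drsaliency:::nn_forward(m, xx)$logits[1,
                                                              target + 1]
  withr::with_seed(17, {
    for (idx in sample(length(x), 12)) {
      xp <- x; xp[idx] <- xp[idx] + eps
      xm <- x; xm[idx] <- xm[idx] - eps
      num <- (score(xp) - score(xm)) / (2 * eps)
      expect_equal(din[idx], num, tolerance = 1e-4)
    }
  })
})
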