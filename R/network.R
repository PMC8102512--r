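## Minimal convolutional-network engine.
##
## Networks are explicit directed acyclic graphs: an ordered list of nodes,
## each naming its input node(s). Supported ops: conv (k x k, TF-style
## "same" padding), dwconv (depth-wise), relu, add, concat (channel axis),
## gap (global average pooling) and dense. Activations are (N, H, W, C)
## arrays. The engine exposes both parameter gradients (for training) and
## the gradient of any logit with respect to any node's output (for
## Grad-CAM), which is why it is written in-house rather than behind an
## opaque fitting interface.

nn_node <- function(id, op, inputs, params = NULL, stride = 1L) {
  list(id = id, op = op, inputs = inputs, params = params,
       stride = as.integer(stride))
}

## Glorot/Xavier uniform init, the standard fan-based scheme for fresh
## layers.
glorot_uniform <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

init_conv <- function(k, cin, cout) {
  list(W = glorot_uniform(c(k, k, cin, cout), k * k * cin, k * k * cout),
       b = numeric(cout))
}

init_dwconv <- function(k, c) {
  list(W = glorot_uniform(c(k, k, c), k * k, k * k), b = numeric(c))
}

init_dense <- function(cin, cout) {
  list(W = glorot_uniform(c(cin, cout), cin, cout), b = numeric(cout))
}

## TF-style "same" padding bounds for size H, kernel k, stride s
same_pad <- function(H, k, s) {
  out <- ceiling(H / s)
  total <- max((out - 1) * s + k - H, 0)
  list(out = out, beg = total %/% 2, end = total - total %/% 2)
}

pad_input <- function(x, k, s) {
  d <- dim(x)
  ph <- same_pad(d[2], k, s); pw <- same_pad(d[3], k, s)
  if (ph$beg + ph$end + pw$beg + pw$end == 0)
    return(list(x = x, ph = ph, pw = pw))
  xp <- array(0, c(d[1], d[2] + ph$beg + ph$end, d[3] + pw$beg + pw$end,
                   d[4]))
  xp[, ph$beg + seq_len(d[2]), pw$beg + seq_len(d[3]), ] <- x
  list(x = xp, ph = ph, pw = pw)
}

conv_forward <- function(x, W, b, stride) {
  k <- dim(W)[1]; cin <- dim(W)[3]; cout <- dim(W)[4]
  d <- dim(x); N <- d[1]
  p <- pad_input(x, k, stride)
  ho <- p$ph$out; wo <- p$pw$out
  out <- matrix(rep(b, each = N * ho * wo), N * ho * wo, cout)
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    ii <- seq(di, by = stride, length.out = ho)
    jj <- seq(dj, by = stride, length.out = wo)
    M <- p$x[, ii, jj, , drop = FALSE]
    dim(M) <- c(N * ho * wo, cin)
    out <- out + M %*% matrix(W[di, dj, , ], cin, cout)
  }
  dim(out) <- c(N, ho, wo, cout)
  out
}

conv_backward <- function(dout, x, W, stride) {
  k <- dim(W)[1]; cin <- dim(W)[3]; cout <- dim(W)[4]
  d <- dim(x); N <- d[1]
  p <- pad_input(x, k, stride)
  ho <- p$ph$out; wo <- p$pw$out
  dmat <- dout; dim(dmat) <- c(N * ho * wo, cout)
  dW <- array(0, dim(W))
  dxp <- array(0, dim(p$x))
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    ii <- seq(di, by = stride, length.out = ho)
    jj <- seq(dj, by = stride, length.out = wo)
    M <- p$x[, ii, jj, , drop = FALSE]
    dim(M) <- c(N * ho * wo, cin)
    dW[di, dj, , ] <- crossprod(M, dmat)
    dsl <- dmat %*% t(matrix(W[di, dj, , ], cin, cout))
    dim(dsl) <- c(N, ho, wo, cin)
    dxp[, ii, jj, ] <- dxp[, ii, jj, , drop = FALSE] + dsl
  }
  dx <- dxp[, p$ph$beg + seq_len(d[2]), p$pw$beg + seq_len(d[3]), ,
            drop = FALSE]
  list(dx = dx, dW = dW, db = colSums(dmat))
}

dwconv_forward <- function(x, W, b, stride) {
  k <- dim(W)[1]; cc <- dim(W)[3]
  d <- dim(x); N <- d[1]
  p <- pad_input(x, k, stride)
  ho <- p$ph$out; wo <- p$pw$out
  out <- matrix(rep(b, each = N * ho * wo), N * ho * wo, cc)
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    ii <- seq(di, by = stride, length.out = ho)
    jj <- seq(dj, by = stride, length.out = wo)
    M <- p$x[, ii, jj, , drop = FALSE]
    dim(M) <- c(N * ho * wo, cc)
    out <- out + M * matrix(W[di, dj, ], N * ho * wo, cc, byrow = TRUE)
  }
  dim(out) <- c(N, ho, wo, cc)
  out
}

dwconv_backward <- function(dout, x, W, stride) {
  k <- dim(W)[1]; cc <- dim(W)[3]
  d <- dim(x); N <- d[1]
  p <- pad_input(x, k, stride)
  ho <- p$ph$out; wo <- p$pw$out
  dmat <- dout; dim(dmat) <- c(N * ho * wo, cc)
  dW <- array(0, dim(W))
  dxp <- array(0, dim(p$x))
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    ii <- seq(di, by = stride, length.out = ho)
    jj <- seq(dj, by = stride, length.out = wo)
    M <- p$x[, ii, jj, , drop = FALSE]
    dim(M) <- c(N * ho * wo, cc)
    dW[di, dj, ] <- colSums(M * dmat)
    dsl <- dmat * matrix(W[di, dj, ], N * ho * wo, cc, byrow = TRUE)
    dim(dsl) <- c(N, ho, wo, cc)
    dxp[, ii, jj, ] <- dxp[, ii, jj, , drop = FALSE] + dsl
  }
  dx <- dxp[, p$ph$beg + seq_len(d[2]), p$pw$beg + seq_len(d[3]), ,
            drop = FALSE]
  list(dx = dx, dW = dW, db = colSums(dmat))
}

gap_forward <- function(x) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1], d[2] * d[3], d[4])
  out <- colMeans(aperm(xm, c(2, 1, 3)))
  dim(out) <- c(d[1], d[4])
  out
}

gap_backward <- function(dout, xdim) {
  hw <- xdim[2] * xdim[3]
  dx <- aperm(array(dout / hw, c(xdim[1], xdim[4], hw)), c(1, 3, 2))
  dim(dx) <- xdim
  dx
}

#' Forward pass through a network graph
#' @param net A `dr_model` (see [build_model()]).
#' @param x Input batch, `(N, H, W, C)` array.
#' @return List with `outs` (named list of every node's output, plus
#'   `"input"`) and `logits`.
#' @noRd
nn_forward <- function(net, x) {
  if (length(dim(x)) == 3) dim(x) <- c(1, dim(x))
  outs <- list(input = x)
  for (node in net$nodes) {
    a <- outs[[node$inputs[1]]]
    outs[[node$id]] <- switch(
      node$op,
      conv = conv_forward(a, node$params$W, node$params$b, node$stride),
      dwconv = dwconv_forward(a, node$params$W, node$params$b,
                              node$stride),
      relu = pmax(a, 0),
      add = a + outs[[node$inputs[2]]],
      concat = {
        b <- outs[[node$inputs[2]]]
        da <- dim(a); db <- dim(b)
        out <- array(0, c(da[1:3], da[4] + db[4]))
        out[, , , seq_len(da[4])] <- a
        out[, , , da[4] + seq_len(db[4])] <- b
        out
      },
      gap = gap_forward(a),
      dense = {
        o <- a %*% node$params$W
        o + matrix(node$params$b, nrow(o), ncol(o), byrow = TRUE)
      },
      stop("unknown op: ", node$op))
  }
  list(outs = outs, logits = outs[[net$nodes[[length(net$nodes)]]$id]])
}

#' Backward pass: parameter gradients and per-node output gradients
#'
#' Seeds the gradient at the logits and propagates it backwards through the
#' graph. `douts[[id]]` is d(objective)/d(output of node id), which is what
#' Grad-CAM reads at the last convolutional layer.
#' @noRd
nn_backward <- function(net, outs, dlogits, want_params = TRUE) {
  douts <- list()
  douts[[net$nodes[[length(net$nodes)]]$id]] <- dlogits
  pgrads <- list()
  acc <- function(douts, id, g) {
    douts[[id]] <- if (is.null(douts[[id]])) g else douts[[id]] + g
    douts
  }
  for (node in rev(net$nodes)) {
    d <- douts[[node$id]]
    if (is.null(d)) next
    a <- outs[[node$inputs[1]]]
    switch(
      node$op,
      conv = {
        g <- conv_backward(d, a, node$params$W, node$stride)
        if (want_params) pgrads[[node$id]] <- list(W = g$dW, b = g$db)
        douts <- acc(douts, node$inputs[1], g$dx)
      },
      dwconv = {
        g <- dwconv_backward(d, a, node$params$W, node$stride)
        if (want_params) pgrads[[node$id]] <- list(W = g$dW, b = g$db)
        douts <- acc(douts, node$inputs[1], g$dx)
      },
      relu = douts <- acc(douts, node$inputs[1],
                          d * (outs[[node$id]] > 0)),
      add = {
        douts <- acc(douts, node$inputs[1], d)
        douts <- acc(douts, node$inputs[2], d)
      },
      concat = {
        ca <- dim(a)[4]
        douts <- acc(douts, node$inputs[1],
                     d[, , , seq_len(ca), drop = FALSE])
        douts <- acc(douts, node$inputs[2],
                     d[, , , -seq_len(ca), drop = FALSE])
      },
      gap = douts <- acc(douts, node$inputs[1], gap_backward(d, dim(a))),
      dense = {
        if (want_params)
          pgrads[[node$id]] <- list(W = crossprod(a, d), b = colSums(d))
        douts <- acc(douts, node$inputs[1], d %*% t(node$params$W))
      })
  }
  list(pgrads = pgrads, douts = douts)
}

softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

## flat named list of all parameters ("nodeid.W", "nodeid.b")
nn_params <- function(net) {
  out <- list()
  for (node in net$nodes) {
    if (is.null(node$params)) next
    out[[paste0(node$id, ".W")]] <- node$params$W
    out[[paste0(node$id, ".b")]] <- node$params$b
  }
  out
}

nn_set_params <- function(net, params) {
  for (i in seq_along(net$nodes)) {
    id <- net$nodes[[i]]$id
    if (is.null(net$nodes[[i]]$params)) next
    net$nodes[[i]]$params$W <- params[[paste0(id, ".W")]]
    net$nodes[[i]]$params$b <- params[[paste0(id, ".b")]]
  }
  net
}
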