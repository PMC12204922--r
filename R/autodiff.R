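# Minimal reverse-mode autodiff tape for the convolutional network.
#
# Values are dense R arrays with dim = c(H, W, C, N). Each op appends a node
# (an environment) to the tape; backward() walks the tape in reverse
# creation order accumulating gradients. The heavy kernels (conv2d, pooling,
# bilinear upsampling, batch norm) are compiled; activations, concatenation
# and reductions are plain R. This is deliberately a static-shape, eager
# tape: exactly what one fixed encoder-decoder forward pass needs, nothing
# more.

new_tape <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$n <- 0L
  env
}

tape_node <- function(tape, value, parents = list(), backward = NULL,
                      name = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  nd$name <- name
  tape$n <- tape$n + 1L
  nd$id <- tape$n
  tape$nodes[[tape$n]] <- nd
  nd
}

ad_input <- function(tape, x, name = NULL) tape_node(tape, x, name = name)

ad_add_grad <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(node)
}

# Backward pass from a scalar loss node.
ad_backward <- function(tape, loss_node) {
  loss_node$grad <- array(1, dim = c(1, 1, 1, 1))
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    for (k in seq_along(nd$parents)) {
      if (!is.null(gs[[k]])) ad_add_grad(nd$parents[[k]], gs[[k]])
    }
  }
  invisible(NULL)
}

## ---- ops ------------------------------------------------------------------

ad_conv2d <- function(tape, x, w, b) {
  y <- .conv2d_fwd(x$value, w$value, b$value)
  xv <- x$value; wv <- w$value
  tape_node(tape, y, parents = list(x, w, b), backward = function(dy) {
    g <- .conv2d_bwd(xv, wv, dy)
    list(g$dx, g$dw, as.numeric(g$db))
  })
}

ad_relu <- function(tape, x) {
  y <- pmax(x$value, 0)
  dim(y) <- dim(x$value)
  pos <- x$value > 0
  tape_node(tape, y, parents = list(x), backward = function(dy) {
    g <- dy * pos
    dim(g) <- dim(dy)
    list(g)
  })
}

ad_sigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-x$value))
  dim(y) <- dim(x$value)
  tape_node(tape, y, parents = list(x), backward = function(dy) {
    g <- dy * y * (1 - y)
    dim(g) <- dim(dy)
    list(g)
  })
}

ad_maxpool <- function(tape, x, k) {
  fw <- .maxpool_fwd(x$value, as.integer(k))
  xd <- dim(x$value)
  tape_node(tape, fw$y, parents = list(x), backward = function(dy) {
    list(.maxpool_bwd(fw$arg, dy, as.integer(xd)))
  })
}

ad_upsample <- function(tape, x, k) {
  y <- .upsample_fwd(x$value, as.integer(k))
  xd <- dim(x$value)
  tape_node(tape, y, parents = list(x), backward = function(dy) {
    list(.upsample_bwd(dy, as.integer(k), as.integer(xd)))
  })
}

# Batch norm; in training mode uses batch statistics and updates the running
# moments stored in `state` (an environment with $mean, $var, $momentum).
ad_batchnorm <- function(tape, x, gamma, beta, state, training = TRUE,
                         eps = 1e-5) {
  if (training) {
    fw <- .bn_fwd(x$value, gamma$value, beta$value, eps)
    if (!is.null(state)) {
      mom <- state$momentum
      state$mean <- (1 - mom) * state$mean + mom * fw$mean
      state$var <- (1 - mom) * state$var + mom * fw$var
    }
    tape_node(tape, fw$y, parents = list(x, gamma, beta),
              backward = function(dy) {
                g <- .bn_bwd(dy, fw$xhat, gamma$value, fw$var, eps)
                list(g$dx, as.numeric(g$dgamma), as.numeric(g$dbeta))
              })
  } else {
    d <- dim(x$value)
    inv <- 1 / sqrt(state$var + eps)
    sc <- gamma$value * inv
    sh <- beta$value - state$mean * sc
    y <- sweep(sweep(x$value, 3L, sc, "*"), 3L, sh, "+")
    tape_node(tape, y, parents = list(x), backward = function(dy) {
      list(sweep(dy, 3L, sc, "*"))
    })
  }
}

ad_concat <- function(tape, xs) {
  dims <- lapply(xs, function(x) dim(x$value))
  H <- dims[[1]][1]; W <- dims[[1]][2]; N <- dims[[1]][4]
  chans <- vapply(dims, `[`, integer(1) + 0, 3)
  for (d in dims)
    if (d[1] != H || d[2] != W || d[4] != N)
      stop("concat: spatial mismatch after scaling (internal consistency)")
  y <- array(0, c(H, W, sum(chans), N))
  ofs <- cumsum(c(0, chans))
  for (i in seq_along(xs))
    y[, , (ofs[i] + 1):ofs[i + 1], ] <- xs[[i]]$value
  tape_node(tape, y, parents = xs, backward = function(dy) {
    lapply(seq_along(xs), function(i) {
      g <- dy[, , (ofs[i] + 1):ofs[i + 1], , drop = FALSE]
      g
    })
  })
}

# Masked mean squared error over foreground pixels: the background-masked
# training loss. mask is H x W x 1 x N with 1 on geometry pixels; each
# foreground pixel contributes its channel-mean squared difference.
ad_masked_mse <- function(tape, pred, target, mask) {
  C <- dim(pred$value)[3]
  ne <- sum(mask)
  if (ne == 0) stop("empty mask: effective pixel count N_e is zero")
  mfull <- array(rep(mask, times = C), dim = dim(pred$value)[c(1, 2, 4, 3)])
  # build mask with channel dim: replicate along C
  mfull <- aperm(mfull, c(1, 2, 4, 3))
  diff <- (pred$value - target) * mfull
  val <- sum(diff^2) / (C * ne)
  tape_node(tape, array(val, c(1, 1, 1, 1)), parents = list(pred),
            backward = function(dy) {
              list(2 * diff / (C * ne) * as.numeric(dy))
            })
}
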