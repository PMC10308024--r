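# Minimal reverse-mode automatic differentiation tape.
#
# A node is an environment holding `value` (numeric array), `parents` (list of
# nodes), `bw` (closure mapping the node's output gradient to a list of parent
# gradients) and `req` (TRUE if any ancestor is a learnable parameter).
# Gradients accumulate into `grad` on a reverse topological sweep. Arrays are
# channel-first (C, D, H, W); per-channel vectors have length C.

ad_node <- function(value, parents = list(), bw = NULL, req = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$parents <- parents
  n$bw <- bw
  n$grad <- NULL
  n$req <- if (!is.null(req)) req else
    length(parents) > 0 && any(vapply(parents, function(p) p$req, logical(1)))
  class(n) <- "ad_node"
  n
}

ad_const <- function(value) ad_node(value, req = FALSE)
ad_param <- function(value) ad_node(value, req = TRUE)

# Reverse topological order over the sub-graph that requires gradients.
ad_backward <- function(root, seed_grad = 1) {
  order <- vector("list", 256L)
  n_ord <- 0L
  stack <- list(list(node = root, stage = 1L))
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    if (top$stage == 1L) {
      if (!is.null(node$.mark) || !node$req) next
      node$.mark <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents)
        if (p$req && is.null(p$.mark))
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
    } else {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- node
    }
  }
  if (n_ord == 0L) return(invisible(NULL))
  order <- order[seq_len(n_ord)]
  root$grad <- array(seed_grad, dim = dim(root$value) %||% length(root$value))
  for (i in rev(seq_len(n_ord))) {
    node <- order[[i]]
    node$.mark <- NULL
    if (is.null(node$grad) || is.null(node$bw)) next
    pg <- node$bw(node$grad)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (!p$req || is.null(pg[[j]])) next
      p$grad <- if (is.null(p$grad)) pg[[j]] else p$grad + pg[[j]]
    }
    if (length(node$parents) > 0) node$grad <- NULL  # free intermediate grads
  }
  invisible(NULL)
}

# ---- elementwise ops --------------------------------------------------------

ad_add <- function(a, b) ad_node(a$value + b$value, list(a, b),
  function(g) list(g, g))

ad_sub <- function(a, b) ad_node(a$value - b$value, list(a, b),
  function(g) list(g, -g))

ad_mul <- function(a, b) {
  va <- a$value; vb <- b$value
  ad_node(va * vb, list(a, b), function(g) list(g * vb, g * va))
}

ad_scale <- function(a, s) ad_node(a$value * s, list(a), function(g) list(g * s))

ad_addc <- function(a, s) ad_node(a$value + s, list(a), function(g) list(g))

ad_relu <- function(a) {
  m <- a$value > 0
  ad_node(a$value * m, list(a), function(g) list(g * m))
}

ad_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  ad_node(s, list(a), function(g) list(g * s * (1 - s)))
}

ad_pow_const <- function(a, p) {
  v <- a$value
  ad_node(v^p, list(a), function(g) list(g * p * v^(p - 1)))
}

ad_rsqrt <- function(a) {
  v <- a$value
  r <- 1 / sqrt(v)
  ad_node(r, list(a), function(g) list(-0.5 * g * r / v))
}

ad_sum <- function(a) {
  dm <- dim(a$value) %||% length(a$value)
  ad_node(sum(a$value), list(a), function(g)
    list(array(as.numeric(g), dim = dm)))
}

ad_mean_vec <- function(a) {
  n <- length(a$value)
  ad_node(mean(a$value), list(a), function(g) list(rep(as.numeric(g) / n, n)))
}

# ---- channel-wise ops (x is (C, D, H, W)) -----------------------------------

ad_mean_spatial <- function(x) {
  dm <- dim(x$value)
  C <- dm[1]; N <- prod(dm[-1])
  v <- .rowMeans(x$value, C, N)
  ad_node(v, list(x), function(g)
    list(array(matrix(g / N, C, N), dim = dm)))
}

# y = a[c] * x + b[c], per-channel affine (the fused normalization pass)
ad_chan_affine <- function(x, a, b) {
  dm <- dim(x$value)
  C <- dm[1]; N <- prod(dm[-1])
  va <- a$value; vx <- x$value
  y <- array(vx * va + b$value, dim = dm)  # recycling down first dim
  ad_node(y, list(x, a, b), function(g) {
    list(array(g * va, dim = dm),
         .rowSums(g * vx, C, N),
         .rowSums(g, C, N))
  })
}

# multiply every channel of x by a single-channel map m (dim (1,D,H,W) or (D,H,W))
ad_mul_bcast1 <- function(x, m) {
  dm <- dim(x$value)
  C <- dm[1]; N <- prod(dm[-1])
  mv <- as.numeric(m$value)
  mrep <- matrix(mv, C, N, byrow = TRUE)
  xm <- matrix(x$value, C, N)
  ad_node(array(xm * mrep, dim = dm), list(x, m), function(g) {
    gm <- matrix(g, C, N)
    gmv <- .colSums(gm * xm, C, N)
    list(array(gm * mrep, dim = dm), array(gmv, dim = dim(m$value)))
  })
}

ad_softmax_chan <- function(x) {
  dm <- dim(x$value)
  C <- dm[1]; N <- prod(dm[-1])
  v <- matrix(x$value, C, N)
  mx <- v[1, ]
  for (k in seq_len(C)[-1]) mx <- pmax(mx, v[k, ])
  v <- v - matrix(mx, C, N, byrow = TRUE)
  e <- exp(v)
  p <- e / matrix(.colSums(e, C, N), C, N, byrow = TRUE)
  pv <- array(p, dim = dm)
  ad_node(pv, list(x), function(g) {
    gm <- matrix(g, C, N)
    s <- .colSums(gm * p, C, N)
    list(array(p * (gm - matrix(s, C, N, byrow = TRUE)), dim = dm))
  })
}

# ---- convolution ops --------------------------------------------------------

ad_conv3d <- function(x, W, b, k, stride = 1L, pad = 0L) {
  dims <- dim(x$value)
  f <- cpp_conv3d_fw(x$value, dims, W$value, b$value, k, stride, pad)
  odims <- f$dims
  vx <- x$value; vW <- W$value
  ad_node(f$y, list(x, W, b), function(g) {
    bw <- cpp_conv3d_bw(vx, dims, vW, g, odims, k, stride, pad)
    list(bw$gx, bw$gW, bw$gb)
  })
}

ad_convt3d <- function(x, W, b, k = 2L, stride = 2L) {
  dims <- dim(x$value)
  f <- cpp_convt3d_fw(x$value, dims, W$value, b$value, k, stride)
  vx <- x$value; vW <- W$value
  ad_node(f$y, list(x, W, b), function(g) {
    bw <- cpp_convt3d_bw(vx, dims, vW, g, k, stride)
    list(bw$gx, bw$gW, bw$gb)
  })
}

ad_upsample2 <- function(x) {
  dims <- dim(x$value)
  ad_node(cpp_upsample2_fw(x$value, dims), list(x), function(g)
    list(cpp_upsample2_bw(g, dims)))
}
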