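# Segmentation network: 3D residual U-Net with attention-gated skip
# connections and switchable normalization, built on the autodiff tape.

# ---- small-vector helper ops used by switchable normalization ---------------

ad_softmax_vec <- function(x) {
  v <- x$value
  e <- exp(v - max(v))
  p <- e / sum(e)
  ad_node(p, list(x), function(g) list(p * (g - sum(g * p))))
}

ad_get <- function(x, i) {
  n <- length(x$value)
  ad_node(x$value[i], list(x), function(g) {
    z <- numeric(n); z[i] <- as.numeric(g); list(z)
  })
}

# vector (or scalar) times scalar node
ad_smul <- function(v, s) {
  vv <- v$value; sv <- as.numeric(s$value)
  ad_node(vv * sv, list(v, s), function(g)
    list(g * sv, sum(g * vv)))
}

ad_bcastC <- function(s, C) {
  ad_node(rep(as.numeric(s$value), C), list(s), function(g) list(sum(g)))
}

# ---- switchable normalization ----------------------------------------------
# Learnable softmax mixture over instance / layer / batch statistics. With
# batch size 1 the batch branch coincides with the instance branch; the three
# mixture weights remain learnable and sum to 1.

sn_forward <- function(x, P, name, eps = 1e-5) {
  C <- dim(x$value)[1]
  gamma <- P[[paste0(name, ".gamma")]]
  beta  <- P[[paste0(name, ".beta")]]
  wm <- ad_softmax_vec(P[[paste0(name, ".wmean")]])
  wv <- ad_softmax_vec(P[[paste0(name, ".wvar")]])
  x2 <- ad_mul(x, x)
  mu_in <- ad_mean_spatial(x)
  m2_in <- ad_mean_spatial(x2)
  v_in <- ad_sub(m2_in, ad_mul(mu_in, mu_in))
  mu_ln <- ad_mean_vec(mu_in)
  v_ln <- ad_sub(ad_mean_vec(m2_in), ad_mul(mu_ln, mu_ln))
  # instance + batch branches share statistics at batch size 1
  w_ib_m <- ad_add(ad_get(wm, 1), ad_get(wm, 3))
  w_ib_v <- ad_add(ad_get(wv, 1), ad_get(wv, 3))
  mu_mix <- ad_add(ad_smul(mu_in, w_ib_m), ad_bcastC(ad_smul(mu_ln, ad_get(wm, 2)), C))
  v_mix  <- ad_add(ad_smul(v_in, w_ib_v), ad_bcastC(ad_smul(v_ln, ad_get(wv, 2)), C))
  inv <- ad_rsqrt(ad_addc(v_mix, eps))
  a <- ad_mul(gamma, inv)
  b <- ad_sub(beta, ad_mul(a, mu_mix))
  ad_chan_affine(x, a, b)
}

# ---- residual block (pre-activation) ---------------------------------------

res_forward <- function(x, P, name) {
  h <- ad_relu(sn_forward(x, P, paste0(name, ".sn1")))
  h <- ad_conv3d(h, P[[paste0(name, ".c1.W")]], P[[paste0(name, ".c1.b")]],
                 k = 3L, stride = 1L, pad = 1L)
  h <- ad_relu(sn_forward(h, P, paste0(name, ".sn2")))
  h <- ad_conv3d(h, P[[paste0(name, ".c2.W")]], P[[paste0(name, ".c2.b")]],
                 k = 3L, stride = 1L, pad = 1L)
  ad_add(x, h)
}

# ---- attention gate ---------------------------------------------------------
# Additive attention: 1x1x1 projections of the (strided) skip and the coarser
# decoder gating signal, ReLU, 1x1x1 collapse to a single channel, sigmoid,
# trilinear upsampling of the coefficient map, multiplicative gating.

att_forward <- function(skip, gate, P, name) {
  theta <- ad_conv3d(skip, P[[paste0(name, ".theta.W")]],
                     P[[paste0(name, ".theta.b")]], k = 1L, stride = 2L, pad = 0L)
  phi <- ad_conv3d(gate, P[[paste0(name, ".phi.W")]],
                   P[[paste0(name, ".phi.b")]], k = 1L, stride = 1L, pad = 0L)
  f <- ad_relu(ad_add(theta, phi))
  psi <- ad_conv3d(f, P[[paste0(name, ".psi.W")]],
                   P[[paste0(name, ".psi.b")]], k = 1L, stride = 1L, pad = 0L)
  alpha <- ad_sigmoid(psi)
  alpha_up <- ad_upsample2(alpha)
  list(gated = ad_mul_bcast1(skip, alpha_up), alpha = alpha_up)
}

# ---- model construction -----------------------------------------------------

#' Model configuration
#'
#' @param depth number of resolution levels.
#' @param base_channels feature channels at the finest level; doubled per level.
#' @param n_classes output classes including background.
#' @param seed initialization seed.
#' @return a `model_config` list.
#' @export
model_config <- function(depth = 4L, base_channels = 8L, n_classes = 6L,
                         seed = 1L) {
  assert_that(depth >= 1, "depth must be >= 1")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 n_classes = as.integer(n_classes),
                 seed = as.integer(seed)),
            class = "model_config")
}

he_init <- function(n_out, n_in_k3) {
  matrix(rnorm(n_out * n_in_k3, sd = sqrt(2 / n_in_k3)), n_out, n_in_k3)
}

#' Build a 3D residual attention U-Net
#'
#' Constructs the segmentation network: an encoder/decoder of `depth`
#' resolution levels with pre-activation residual blocks, strided-convolution
#' downsampling, transposed-convolution upsampling, attention-gated additive
#' skip connections, switchable normalization at every normalization site and
#' a softmax head.
#'
#' @param config a [model_config()].
#' @return a `seg_model` object (configuration plus named parameter arrays).
#' @export
build_model <- function(config) {
  L <- config$depth
  ch <- config$base_channels * 2^(0:(L - 1))
  P <- list()
  add_conv <- function(name, cin, cout, k) {
    P[[paste0(name, ".W")]] <<- he_init(cout, cin * k^3)
    P[[paste0(name, ".b")]] <<- numeric(cout)
  }
  add_sn <- function(name, C) {
    P[[paste0(name, ".gamma")]] <<- rep(1, C)
    P[[paste0(name, ".beta")]] <<- numeric(C)
    P[[paste0(name, ".wmean")]] <<- numeric(3)
    P[[paste0(name, ".wvar")]] <<- numeric(3)
  }
  add_res <- function(name, C) {
    add_sn(paste0(name, ".sn1"), C); add_conv(paste0(name, ".c1"), C, C, 3)
    add_sn(paste0(name, ".sn2"), C); add_conv(paste0(name, ".c2"), C, C, 3)
  }
  with_seed(config$seed, {
    add_conv("stem", 1, ch[1], 3)
    for (l in seq_len(L)) {
      add_res(paste0("enc", l - 1), ch[l])
      if (l < L) add_conv(paste0("down", l - 1), ch[l], ch[l + 1], 3)
    }
    for (l in seq_len(L - 1)) {
      cs <- ch[l]; cg <- ch[l + 1]; cint <- max(4L, cs %/% 2L)
      # transposed conv weight layout: (C_in x C_out * k^3)
      P[[paste0("up", l - 1, ".W")]] <-
        matrix(rnorm(cg * cs * 8, sd = sqrt(2 / (cg * 8))), cg, cs * 8)
      P[[paste0("up", l - 1, ".b")]] <- numeric(cs)
      add_conv(paste0("att", l - 1, ".theta"), cs, cint, 1)
      add_conv(paste0("att", l - 1, ".phi"), cg, cint, 1)
      add_conv(paste0("att", l - 1, ".psi"), cint, 1, 1)
      add_res(paste0("dec", l - 1), cs)
    }
    add_conv("head", ch[1], config$n_classes, 1)
  })
  structure(list(config = config, params = P), class = "seg_model")
}

# Forward pass on the tape. `P` is a named list of ad nodes, `x` an ad node of
# shape (1, D, H, W). Returns the softmax probability node plus attention maps.
unet_forward <- function(config, P, x) {
  L <- config$depth
  dm <- dim(x$value)[-1]
  if (any(dm %% 2^(L - 1) != 0))
    stopf("input dimensions (%s) must be divisible by %d for depth %d",
          paste(dm, collapse = "x"), 2^(L - 1), L)
  h <- ad_conv3d(x, P[["stem.W"]], P[["stem.b"]], 3L, 1L, 1L)
  skips <- vector("list", L - 1)
  for (l in seq_len(L)) {
    h <- res_forward(h, P, paste0("enc", l - 1))
    if (l < L) {
      skips[[l]] <- h
      h <- ad_conv3d(h, P[[paste0("down", l - 1, ".W")]],
                     P[[paste0("down", l - 1, ".b")]], 3L, 2L, 1L)
    }
  }
  alphas <- list()
  for (l in rev(seq_len(L - 1))) {
    u <- ad_convt3d(h, P[[paste0("up", l - 1, ".W")]],
                    P[[paste0("up", l - 1, ".b")]], 2L, 2L)
    at <- att_forward(skips[[l]], h, P, paste0("att", l - 1))
    alphas[[paste0("att", l - 1)]] <- at$alpha
    h <- res_forward(ad_add(u, at$gated), P, paste0("dec", l - 1))
  }
  logits <- ad_conv3d(h, P[["head.W"]], P[["head.b"]], 1L, 1L, 0L)
  list(prob = ad_softmax_chan(logits), alphas = alphas)
}

params_as_nodes <- function(params, trainable = TRUE) {
  lapply(params, if (trainable) ad_param else ad_const)
}

#' Forward pass of a segmentation model
#'
#' Maps a preprocessed (Z-normalized, padded) single-channel crop to per-voxel
#' class probabilities. Deterministic given fixed weights.
#'
#' @param model a `seg_model`.
#' @param x 3D numeric array (the crop), or a (1, D, H, W) array.
#' @param return_attention also return the attention coefficient maps.
#' @return array of probabilities with dim (n_classes, D, H, W); if
#'   `return_attention`, a list with elements `prob` and `attention`.
#' @export
model_forward <- function(model, x, return_attention = FALSE) {
  if (length(dim(x)) == 3) dim(x) <- c(1L, dim(x))
  P <- params_as_nodes(model$params, trainable = FALSE)
  out <- unet_forward(model$config, P, ad_const(x))
  if (return_attention)
    list(prob = out$prob$value,
         attention = lapply(out$alphas, function(a) a$value))
  else out$prob$value
}

#' Switchable-normalization mixture weights of a model
#'
#' @param model a `seg_model`.
#' @return data.frame with one row per normalization site and statistic kind,
#'   columns `site`, `kind`, and the three softmax weights (instance, layer,
#'   batch), which sum to 1.
#' @export
switchnorm_weights <- function(model) {
  nm <- grep("\\.(wmean|wvar)$", names(model$params), value = TRUE)
  do.call(rbind, lapply(nm, function(n) {
    e <- exp(model$params[[n]] - max(model$params[[n]]))
    w <- e / sum(e)
    data.frame(site = sub("\\.(wmean|wvar)$", "", n),
               kind = if (grepl("wmean$", n)) "mean" else "var",
               w_instance = w[1], w_layer = w[2], w_batch = w[3])
  }))
}
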