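h <- asNamespace("hippseg")

test_that("network output matches the shape contract and is a distribution", {
  m <- build_model(model_config(depth = 3, base_channels = 4, n_classes = 6,
                                seed = 2))
  x <- array(rnorm(16^3), dim = c(16, 16, 16))
  p <- model_forward(m, x)
  expect_equal(dim(p), c(6, 16, 16, 16))
  # probabilities sum to 1 at random voxels
  pm <- matrix(p, 6, 16^3)
  idx <- sample(16^3, 100)
  expect_true(all(abs(colSums(pm[, idx]) - 1) < 1e-5))
  expect_true(all(p >= 0))
  # deterministic in evaluation mode
  expect_identical(p, model_forward(m, x))
  # shape not divisible by 2^(depth-1) errors before compute
  expect_error(model_forward(m, array(0, dim = c(15, 16, 16))), "divisible")
})

test_that("attention coefficients lie in [0,1]", {
  m <- build_model(model_config(depth = 3, base_channels = 4, n_classes = 6,
                                seed = 3))
  x <- array(rnorm(16^3), dim = c(16, 16, 16))
  out <- model_forward(m, x, return_attention = TRUE)
  expect_gte(length(out$attention), 2)
  for (a in out$attention) {
    expect_true(all(a >= 0 & a <= 1))
    expect_gt(sd(a), 0)  # a real coefficient map, not a constant
  }
})

test_that("switchable-normalization mixture weights sum to 1 per site", {
  m <- build_model(model_config(depth = 2, base_channels = 4, seed = 1))
  w <- switchnorm_weights(m)
  expect_true(all(abs(rowSums(w[, c("w_instance", "w_layer", "w_batch")]) - 1) <
                    1e-12))
  expect_equal(nrow(w), 2 * sum(grepl("\\.sn[12]\\.gamma$",
                                      names(m$params))))
})

test_that("analytic gradients match directional finite differences", {
  set.seed(4)
  cfg <- model_config(depth = 2, base_channels = 4, n_classes = 3, seed = 42)
  m <- build_model(cfg)
  x <- array(rnorm(8^3), dim = c(1, 8, 8, 8))
  tgt <- array(sample(0:2, 512, TRUE), dim = c(8, 8, 8))
  cls <- c("BG", "DG", "CA1")
  lossval <- function(P) {
    pn <- lapply(P, h$ad_const)
    out <- h$unet_forward(cfg, pn, h$ad_const(x))
    h$observation_loss_node(out$prob, tgt, protocol_spec(), loss_config(),
                            cls)$value
  }
  pn <- lapply(m$params, h$ad_param)
  out <- h$unet_forward(cfg, pn, h$ad_const(x))
  ln <- h$observation_loss_node(out$prob, tgt, protocol_spec(), loss_config(),
                                cls)
  h$ad_backward(ln)
  # directional derivative along a random direction over all parameters:
  # averages out the float32 kernel noise that pointwise checks would hit
  dirs <- lapply(m$params, function(p) {
    d <- rnorm(length(p))
    dim(d) <- dim(p)
    d
  })
  ana <- sum(mapply(function(nm) sum(pn[[nm]]$grad * dirs[[nm]]),
                    names(m$params)))
  eps <- 1e-4
  shift <- function(s) mapply(function(p, d) p + s * d, m$params, dirs,
                              SIMPLIFY = FALSE)
  num <- (lossval(shift(eps)) - lossval(shift(-eps))) / (2 * eps)
  expect_equal(ana, num, tolerance = 1e-3)
})

test_that("a tiny model overfits a single phantom within 300 steps", {
  mdl <- tiny_trained_model()
  expect_lte(length(mdl$trace), 300)
  expect_lt(min(mdl$trace), 0.05)
  expect_lt(tail(mdl$trace, 1), head(mdl$trace, 1))
})

test_that("training is deterministic under a fixed seed", {
  ph <- tiny_phantom()
  obs <- list(list(image = z_normalize(ph$volume)$data,
                   target = ph$labels$data, protocol = protocol_spec()))
  cfgm <- model_config(depth = 2, base_channels = 4, n_classes = 6, seed = 1)
  cfgt <- train_config(epochs = 3L, peak_lr = 5e-3, seed = 9)  # augmented by default
  m1 <- train_weak_learner(obs, cfgm, loss_config(), cfgt)
  m2 <- train_weak_learner(obs, cfgm, loss_config(), cfgt)
  expect_identical(m1$trace, m2$trace)
  expect_identical(m1$params, m2$params)
})
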