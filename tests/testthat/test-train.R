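test_that("bootstrap sampling matches the 1 - (1 - 1/N)^N unique fraction", {
  N <- 50
  frac <- vapply(1:1000, function(s)
    length(unique(bootstrap_sample(seq_len(N), N, seed = s))) / N, numeric(1))
  expected <- 1 - (1 - 1 / N)^N
  se <- sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - expected), 3 * se + 1e-3)
  # dataset of one: n copies
  expect_equal(bootstrap_sample("a", 5, seed = 1), rep("a", 5))
  # same seed twice: identical multiset
  expect_identical(bootstrap_sample(1:20, 20, seed = 3),
                   bootstrap_sample(1:20, 20, seed = 3))
  expect_error(bootstrap_sample(1:5, 0), "n must be")
  expect_error(bootstrap_sample(integer(0), 3), "non-empty")
})

test_that("one-cycle schedule warms up to the peak then anneals", {
  lr <- vapply(1:100, function(s) hippseg:::one_cycle_lr(s, 100, 1e-2, 0.3),
               numeric(1))
  expect_equal(max(lr), 1e-2)
  expect_equal(which.max(lr), 30)
  expect_true(all(diff(lr[1:30]) > 0))
  expect_true(all(diff(lr[30:100]) <= 0))
  expect_lt(lr[100], 1e-5)
})

test_that("ensembles train on distinct bags with a full manifest", {
  ph <- tiny_phantom()
  obs1 <- list(image = z_normalize(ph$volume)$data, target = ph$labels$data,
               protocol = protocol_spec())
  dataset <- rep(list(obs1), 12)
  cfgm <- model_config(depth = 2, base_channels = 4, n_classes = 6, seed = 1)
  ens <- train_ensemble(dataset, cfgm, loss_config(),
                        train_config(n_models = 3L, epochs = 1L,
                                     peak_lr = 3e-3, seed = 4))
  expect_s3_class(ens, "ensemble")
  expect_length(ens$members, 3)
  expect_equal(nrow(ens$manifest), 3)
  # bags differ pairwise under the master seed
  expect_false(identical(ens$bags[[1]], ens$bags[[2]]))
  expect_false(identical(ens$bags[[2]], ens$bags[[3]]))
  # every member reduced its loss
  for (m in ens$members)
    expect_lt(tail(m$trace, 1), head(m$trace, 1))
  # default ensemble size is five
  expect_equal(train_config()$n_models, 5)
})

test_that("magnitude pruning zeroes the smallest weights to the target", {
  m <- build_model(model_config(depth = 3, base_channels = 8, n_classes = 6,
                                seed = 2))
  # sparsity 0: identity
  expect_identical(prune_magnitude(m, 0)$params, m$params)
  p <- prune_magnitude(m, 0.70)
  wn <- grep("\\.W$", names(m$params), value = TRUE)
  nw <- sum(vapply(m$params[wn], length, numeric(1)))
  fr <- prune_zero_fraction(p)
  expect_gte(fr, 0.70)
  expect_lt(fr, 0.70 + 1 / nw + 1e-12)
  # non-weight parameters untouched
  expect_identical(p$params[["enc0.sn1.gamma"]], m$params[["enc0.sn1.gamma"]])
  expect_identical(p$params[["stem.b"]], m$params[["stem.b"]])
  # only small-magnitude weights removed
  kept <- abs(unlist(p$params[wn]))
  thr <- min(kept[kept > 0])
  removed <- abs(unlist(m$params[wn]))[unlist(p$params[wn]) == 0]
  expect_lte(max(removed), thr + 1e-12)
  expect_error(prune_magnitude(m, 1), "sparsity")
})

test_that("pruned tiny model stays close to the unpruned one", {
  mdl <- tiny_trained_model()
  ph <- tiny_phantom()
  x <- z_normalize(ph$volume)$data
  d_of <- function(m) {
    res <- segment_crop(x, list(m), tta_config(n_versions = 1))
    mean(vapply(1:5, function(l) dice(ph$labels$data == l, res$labels == l),
                numeric(1)))
  }
  d0 <- d_of(mdl)
  d1 <- d_of(prune_magnitude(mdl, 0.5))
  expect_gt(d1, d0 - 0.15)
})

test_that("stochastic weight averaging records its window", {
  mdl <- tiny_trained_model()
  ep <- mdl$train_cfg$epochs
  start <- ceiling(mdl$train_cfg$swa_start * ep)
  expect_equal(mdl$swa_info$from_epoch, start)
  expect_equal(mdl$swa_info$n_averaged, ep - start + 1)
})
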