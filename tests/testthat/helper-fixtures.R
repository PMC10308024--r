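# Shared fixtures, built in code and memoized so expensive objects (a small
# trained model, a head scene) are constructed once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

tiny_phantom <- function() fixture("tiny_phantom", function() {
  make_hippocampus_phantom(phantom_spec(grid_shape = c(16, 16, 16),
                                        radius = 3.2, seed = 7))
})

small_scene <- function() fixture("small_scene", function() {
  make_head_scene(phantom_spec(seed = 3))
})

# a deliberately small model trained on one 16^3 phantom: enough signal for
# inference-path tests without the cost of the full desk benchmark
tiny_trained_model <- function() fixture("tiny_trained_model", function() {
  ph <- tiny_phantom()
  obs <- list(list(image = z_normalize(ph$volume)$data,
                   target = ph$labels$data, protocol = protocol_spec()))
  train_weak_learner(obs,
                     model_config(depth = 2, base_channels = 8, n_classes = 6,
                                  seed = 1),
                     loss_config(),
                     train_config(epochs = 300L, peak_lr = 3e-3,
                                  swa_start = 0.9, augment = FALSE, seed = 1))
})

# brute-force metric oracles, independent of the package implementations
oracle_dice <- function(a, b) {
  inter <- 0
  for (i in seq_along(a)) if (a[i] && b[i]) inter <- inter + 1
  2 * inter / (sum(a) + sum(b))
}

oracle_hausdorff <- function(a, b, spacing = c(1, 1, 1)) {
  pa <- which(a, arr.ind = TRUE); pb <- which(b, arr.ind = TRUE)
  dmat <- matrix(0, nrow(pa), nrow(pb))
  for (i in seq_len(nrow(pa))) for (j in seq_len(nrow(pb)))
    dmat[i, j] <- sqrt(sum(((pa[i, ] - pb[j, ]) * spacing)^2))
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

oracle_vs <- function(a, b) 1 - abs(sum(a) - sum(b)) / (sum(a) + sum(b))

random_mask <- function(dims, p = 0.3) {
  array(runif(prod(dims)) < p, dim = dims)
}
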