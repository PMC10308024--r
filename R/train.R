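# Bagged ensemble training: bootstrap bags, AdamW with a one-cycle learning
# rate schedule and stochastic weight averaging, plus global magnitude
# pruning for efficient model variants.

#' Training configuration
#'
#' @param n_models ensemble size (default 5).
#' @param bootstrap_n samples drawn with replacement per learner (default:
#'   training-set size).
#' @param epochs passes over the bag (desk default 40).
#' @param batch_size observations per step (1: variable input shapes).
#' @param peak_lr one-cycle peak learning rate.
#' @param warmup fraction of steps spent ramping up to the peak.
#' @param swa_start epoch fraction at which weight averaging begins.
#' @param weight_decay decoupled weight decay on convolution weights.
#' @param prune_sparsity default sparsity for [prune_magnitude()] (0.70).
#' @param augment apply a random TTA-family transform to each observation per
#'   step (on by default; deterministic given the seed). Disable for
#'   single-sample capacity checks.
#' @param seed master seed.
#' @return a `train_config` list.
#' @export
train_config <- function(n_models = 5L, bootstrap_n = NULL, epochs = 40L,
                         batch_size = 1L, peak_lr = 5e-3, warmup = 0.3,
                         swa_start = 0.75, weight_decay = 1e-4,
                         prune_sparsity = 0.70, augment = TRUE, seed = 1L) {
  assert_that(n_models >= 1, "n_models must be >= 1")
  assert_that(prune_sparsity >= 0 && prune_sparsity < 1,
              "prune_sparsity must be in [0, 1)")
  structure(list(n_models = as.integer(n_models), bootstrap_n = bootstrap_n,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 peak_lr = peak_lr, warmup = warmup, swa_start = swa_start,
                 weight_decay = weight_decay, prune_sparsity = prune_sparsity,
                 augment = isTRUE(augment), seed = as.integer(seed)),
            class = "train_config")
}

#' Bootstrap sample of dataset ids
#'
#' `n` i.i.d. uniform draws with replacement; reproducible under the seed.
#'
#' @param dataset_ids vector of ids (non-empty).
#' @param n number of draws (> 0).
#' @param seed integer seed.
#' @return vector of sampled ids (a multiset).
#' @export
bootstrap_sample <- function(dataset_ids, n = length(dataset_ids), seed = 1L) {
  assert_that(length(dataset_ids) > 0, "dataset must be non-empty")
  assert_that(n > 0, "n must be > 0")
  with_seed(seed, dataset_ids[sample.int(length(dataset_ids), n, replace = TRUE)])
}

one_cycle_lr <- function(step, total, peak, warmup = 0.3) {
  w <- max(1, floor(warmup * total))
  if (step <= w) return(peak * step / w)
  frac <- (step - w) / max(1, total - w)
  peak * 0.5 * (1 + cos(pi * frac))
}

adamw_update <- function(P, grads, state, lr, wd, decay_names,
                         b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (nm %in% decay_names) upd <- upd + wd * P[[nm]]
    P[[nm]] <- P[[nm]] - lr * upd
  }
  list(P = P, state = state)
}

as_target_array <- function(target) {
  if (inherits(target, "volume")) target$data else target
}

#' Train one weak learner on a bootstrap bag
#'
#' Iterates the bag with batch size 1 under AdamW, a one-cycle learning rate
#' and stochastic weight averaging of tail-epoch weights. Deterministic given
#' the seed.
#'
#' @param bag list of observations, each `list(image, target, protocol)` with
#'   a preprocessed image array, canonical integer target and
#'   [protocol_spec()].
#' @param model_cfg a [model_config()].
#' @param loss_cfg a [loss_config()].
#' @param train_cfg a [train_config()].
#' @param seed seed for initialization and epoch shuffling (default from
#'   `train_cfg`).
#' @return a `seg_model` checkpoint with elements `trace` (per-step loss),
#'   `swa_info` and the configs.
#' @export
train_weak_learner <- function(bag, model_cfg, loss_cfg = loss_config(),
                               train_cfg = train_config(), seed = NULL) {
  assert_that(length(bag) > 0, "bag must be non-empty")
  seed <- seed %||% train_cfg$seed
  model <- build_model(model_config(model_cfg$depth, model_cfg$base_channels,
                                    model_cfg$n_classes, seed = seed))
  P <- model$params
  class_names <- names(canonical_classes())[seq_len(model_cfg$n_classes)]
  decay_names <- grep("\\.W$", names(P), value = TRUE)
  state <- list(m = lapply(P, function(p) p * 0),
                v = lapply(P, function(p) p * 0), t = 0L)
  total_steps <- train_cfg$epochs * length(bag)
  trace <- numeric(total_steps)
  step <- 0L
  swa_from <- max(1L, ceiling(train_cfg$swa_start * train_cfg$epochs))
  swa_sum <- NULL
  swa_n <- 0L
  for (epoch in seq_len(train_cfg$epochs)) {
    ord <- with_seed(seed + 7919L * epoch,
                     sample.int(length(bag), length(bag)))
    for (i in ord) {
      step <- step + 1L
      obs <- bag[[i]]
      x <- obs$image
      tgt <- as_target_array(obs$target)
      if (train_cfg$augment) {
        rec <- with_seed(seed + 104729L * step,
                         random_tta_record(dim(x), tta_config(seed = seed)))
        x <- tta_apply(x, rec)
        tgt <- array(as.integer(tta_apply(tgt, rec, method = "nearest")),
                     dim = dim(tgt))
      }
      if (length(dim(x)) == 3) dim(x) <- c(1L, dim(x))
      pn <- params_as_nodes(P)
      out <- unet_forward(model$config, pn, ad_const(x))
      loss <- observation_loss_node(out$prob, tgt, obs$protocol %||% protocol_spec(),
                                    loss_cfg, class_names)
      if (!is.finite(loss$value))
        stopf("non-finite loss at step %d (lr %.2g, observation %d)",
              step, one_cycle_lr(step, total_steps, train_cfg$peak_lr,
                                 train_cfg$warmup), i)
      trace[step] <- loss$value
      ad_backward(loss)
      grads <- lapply(pn, function(n) n$grad)
      lr <- one_cycle_lr(step, total_steps, train_cfg$peak_lr, train_cfg$warmup)
      res <- adamw_update(P, grads, state, lr, train_cfg$weight_decay,
                          decay_names)
      P <- res$P; state <- res$state
    }
    if (epoch >= swa_from) {
      swa_sum <- if (is.null(swa_sum)) P else
        mapply(`+`, swa_sum, P, SIMPLIFY = FALSE)
      swa_n <- swa_n + 1L
    }
  }
  if (swa_n > 0) P <- lapply(swa_sum, function(p) p / swa_n)
  model$params <- P
  model$trace <- trace
  model$swa_info <- list(from_epoch = swa_from, n_averaged = swa_n)
  model$loss_cfg <- loss_cfg
  model$train_cfg <- train_cfg
  model
}

#' Train a bagged ensemble
#'
#' Trains `n_models` weak learners on independent bootstrap bags (seeds
#' `seed + 1 .. seed + E`) and returns the ensemble with its manifest.
#'
#' @param dataset list of observations (see [train_weak_learner()]).
#' @param model_cfg a [model_config()].
#' @param loss_cfg a [loss_config()].
#' @param train_cfg a [train_config()].
#' @return an `ensemble`: members, bags, configs, and a manifest data.frame.
#' @export
train_ensemble <- function(dataset, model_cfg, loss_cfg = loss_config(),
                           train_cfg = train_config()) {
  E <- train_cfg$n_models
  n <- train_cfg$bootstrap_n %||% length(dataset)
  bags <- lapply(seq_len(E), function(e)
    bootstrap_sample(seq_along(dataset), n, seed = train_cfg$seed + e))
  members <- vector("list", E)
  for (e in seq_len(E)) {
    members[[e]] <- train_weak_learner(dataset[bags[[e]]], model_cfg, loss_cfg,
                                       train_cfg, seed = train_cfg$seed + e)
  }
  manifest <- data.frame(member = seq_len(E),
                         seed = train_cfg$seed + seq_len(E),
                         bag = vapply(bags, function(b)
                           paste(b, collapse = ","), ""))
  structure(list(members = members, bags = bags, model_cfg = model_cfg,
                 loss_cfg = loss_cfg, train_cfg = train_cfg,
                 manifest = manifest),
            class = "ensemble")
}

#' Global magnitude pruning
#'
#' Zeroes the globally smallest-magnitude convolution weights so the zero
#' fraction over prunable weights is at least `sparsity` (within one weight).
#' Biases and normalization parameters are untouched.
#'
#' @param model a `seg_model`.
#' @param sparsity fraction of prunable weights to zero, in \[0, 1).
#' @return the pruned model.
#' @export
prune_magnitude <- function(model, sparsity = 0.70) {
  assert_that(sparsity >= 0, "sparsity must be >= 0")
  if (sparsity >= 1) stopf("sparsity must be < 1")
  if (sparsity == 0) return(model)
  wn <- grep("\\.W$", names(model$params), value = TRUE)
  all_w <- unlist(lapply(model$params[wn], as.numeric))
  k <- ceiling(sparsity * length(all_w))
  thr <- sort(abs(all_w), partial = k)[k]
  for (nm in wn) {
    W <- model$params[[nm]]
    W[abs(W) <= thr] <- 0
    model$params[[nm]] <- W
  }
  model
}

#' Fraction of prunable weights that are exactly zero
#'
#' @param model a `seg_model`.
#' @return scalar in \[0, 1\].
#' @export
prune_zero_fraction <- function(model) {
  wn <- grep("\\.W$", names(model$params), value = TRUE)
  all_w <- unlist(lapply(model$params[wn], as.numeric))
  mean(all_w == 0)
}
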