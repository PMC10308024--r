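# Protocol-aware focal Tversky loss.
#
# The base loss per class is L = (1 - TP/(TP + beta*FN + alpha*FP))^gamma on
# soft confusion counts (sums of probability mass). Each training observation
# carries a protocol describing which canonical classes its rater actually
# drew: merge groups (e.g. CA2+CA3 scored as one class) and optional
# undifferentiated HEAD/TAIL regions inside which any subfield prediction is
# scored as hippocampus rather than penalized.

#' Canonical class labels
#'
#' Background plus the five hippocampal subfields and the optional
#' undifferentiated head/tail classes, with their integer label ids.
#' @export
canonical_classes <- function() {
  c(BG = 0L, DG = 1L, CA1 = 2L, CA2 = 3L, CA3 = 4L, SUB = 5L,
    HEAD = 6L, TAIL = 7L)
}

subfield_classes <- function() c("DG", "CA1", "CA2", "CA3", "SUB")

#' Loss configuration
#'
#' @param alpha false-positive weight (default 0.3).
#' @param beta false-negative weight (default 0.7).
#' @param gamma focal exponent (default 0.75; configurable).
#' @param class_aggregation `"mean"` or `"sum"` over scored classes.
#' @return a `loss_config` list.
#' @export
loss_config <- function(alpha = 0.3, beta = 0.7, gamma = 0.75,
                        class_aggregation = c("mean", "sum")) {
  assert_that(alpha >= 0 && beta >= 0, "alpha and beta must be >= 0")
  assert_that(gamma > 0, "gamma must be > 0")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 class_aggregation = match.arg(class_aggregation)),
            class = "loss_config")
}

#' Segmentation protocol specification
#'
#' Describes how one rater's observation maps onto the canonical classes.
#'
#' @param merge_groups list of character vectors of canonical subfield classes
#'   scored as a single class (e.g. `list(c("CA2", "CA3"))`). Groups must be
#'   disjoint.
#' @param head_tail if `TRUE`, the observation has undifferentiated HEAD/TAIL
#'   labels: inside them, subfield predictions are pooled into the head/tail
#'   class instead of being penalized.
#' @return a `protocol_spec` object.
#' @export
protocol_spec <- function(merge_groups = list(), head_tail = FALSE) {
  known <- names(canonical_classes())
  for (g in merge_groups) {
    bad <- setdiff(g, known)
    if (length(bad) > 0)
      stopf("protocol references unknown canonical class: %s",
            paste(bad, collapse = ", "))
    assert_that(length(g) >= 2, "merge groups need at least two classes")
  }
  all_m <- unlist(merge_groups)
  assert_that(!anyDuplicated(all_m), "merge groups must be disjoint")
  structure(list(merge_groups = merge_groups, head_tail = isTRUE(head_tail)),
            class = "protocol_spec")
}

# Emitted classes of a protocol given the model's class names: each element is
# the set of canonical classes collapsed into that output channel.
protocol_channels <- function(protocol, class_names) {
  groups <- list()
  used <- character(0)
  for (g in protocol$merge_groups) {
    memb <- intersect(class_names, g)
    if (length(memb) == 0)
      stopf("merge group (%s) has no member channel", paste(g, collapse = ","))
    groups[[paste(memb, collapse = "-")]] <- memb
    used <- c(used, memb)
  }
  for (cn in setdiff(class_names, used)) groups[[cn]] <- cn
  # keep canonical ordering by first member
  ord <- order(match(vapply(groups, `[`, "", 1), class_names))
  groups[ord]
}

#' Focal Tversky loss from confusion counts
#'
#' `L = (1 - TP / (TP + beta * FN + alpha * FP))^gamma`, evaluated per class.
#'
#' @param counts data.frame or list with numeric elements `TP`, `FP`, `FN`
#'   (soft counts, one entry per class).
#' @param cfg a [loss_config()].
#' @return numeric vector of per-class losses in \[0, 1\]; `NA` for classes
#'   whose counts are all zero (skipped, not an error).
#' @export
focal_tversky <- function(counts, cfg = loss_config()) {
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN
  assert_that(all(c(TP, FP, FN) >= 0), "confusion counts must be >= 0")
  den <- TP + cfg$beta * FN + cfg$alpha * FP
  out <- ifelse(den > 0, (1 - TP / den)^cfg$gamma, NA_real_)
  out
}

# ---- channel-space transforms (array + autodiff versions) -------------------

#' Merge prediction channels according to a protocol
#'
#' Probabilities of classes inside one merge group are summed into a single
#' channel; the result remains a distribution.
#'
#' @param scores array (C, D, H, W) of class probabilities with channel names
#'   in `class_names` order.
#' @param protocol a [protocol_spec()].
#' @param class_names canonical names of the score channels.
#' @return array (K, D, H, W) with an attribute `channels` (list mapping each
#'   output channel to its canonical members).
#' @export
merge_predictions <- function(scores, protocol,
                              class_names = rownames_or_default(scores)) {
  groups <- protocol_channels(protocol, class_names)
  node <- ad_merge_channels(ad_const(scores), groups, class_names)
  out <- node$value
  attr(out, "channels") <- groups
  out
}

rownames_or_default <- function(scores) {
  cn <- attr(scores, "class_names")
  cn %||% names(canonical_classes())[seq_len(dim(scores)[1])]
}

ad_merge_channels <- function(x, groups, class_names) {
  dm <- dim(x$value)
  C <- dm[1]; N <- prod(dm[-1])
  K <- length(groups)
  xm <- matrix(x$value, C, N)
  y <- matrix(0, K, N)
  idx <- lapply(groups, function(g) match(g, class_names))
  for (k in seq_len(K)) {
    ik <- idx[[k]]
    y[k, ] <- if (length(ik) == 1) xm[ik, ] else .colSums(xm[ik, , drop = FALSE], length(ik), N)
  }
  ad_node(array(y, dim = c(K, dm[-1])), list(x), function(g) {
    gm <- matrix(g, K, N)
    gx <- matrix(0, C, N)
    for (k in seq_len(K)) for (i in idx[[k]]) gx[i, ] <- gx[i, ] + gm[k, ]
    list(array(gx, dim = dm))
  })
}

# Pool subfield probability mass into the head/tail channel inside head/tail
# target voxels, and zero the subfield channels there, so subfield predictions
# inside those regions contribute TP of 'hippocampus' rather than FP. Linear,
# hence exactly differentiable.
ad_head_tail_pool <- function(x, channels, target_ids) {
  dm <- dim(x$value)
  K <- dm[1]; N <- prod(dm[-1])
  chan_names <- names(channels)
  sub_idx <- which(vapply(channels, function(g) any(g %in% subfield_classes()),
                          logical(1)))
  masks <- list()
  for (cap in c("HEAD", "TAIL")) {
    k <- which(vapply(channels, function(g) cap %in% g, logical(1)))
    if (length(k) == 1) {
      cap_id <- canonical_classes()[[cap]]
      m <- which(as.integer(target_ids) == cap_id)
      if (length(m) > 0) masks[[cap]] <- list(k = k, vox = m)
    }
  }
  if (length(masks) == 0) return(x)
  xm <- matrix(x$value, K, N)
  y <- xm
  for (mk in masks) {
    pool <- .colSums(xm[sub_idx, mk$vox, drop = FALSE], length(sub_idx),
                     length(mk$vox))
    y[mk$k, mk$vox] <- y[mk$k, mk$vox] + pool
    y[sub_idx, mk$vox] <- 0
  }
  ad_node(array(y, dim = dm), list(x), function(g) {
    gm <- matrix(g, K, N)
    gx <- gm
    for (mk in masks) {
      gx[sub_idx, mk$vox] <- matrix(gm[mk$k, mk$vox], length(sub_idx),
                                    length(mk$vox), byrow = TRUE)
    }
    list(array(gx, dim = dm))
  })
}

#' Apply the head/tail scoring rule
#'
#' Inside voxels whose target is the undifferentiated HEAD or TAIL class, all
#' subfield prediction channels are pooled into that class's channel (so a
#' subfield prediction there counts as a true positive of 'hippocampus', not a
#' false positive); outside, predictions are scored normally. Identity when
#' the protocol has no head/tail classes.
#'
#' @param scores probability array (K, D, H, W) in protocol channel space (see
#'   [merge_predictions()]).
#' @param target integer array of canonical target labels.
#' @param protocol a [protocol_spec()].
#' @param class_names canonical names of the score channels before merging.
#' @return list with transformed `scores` and unchanged `target`.
#' @export
apply_head_tail_rule <- function(scores, target, protocol,
                                 class_names = rownames_or_default(scores)) {
  channels <- attr(scores, "channels") %||%
    protocol_channels(protocol_spec(), class_names)
  if (!protocol$head_tail) return(list(scores = scores, target = target))
  node <- ad_head_tail_pool(ad_const(scores), channels, target)
  out <- node$value
  attr(out, "channels") <- channels
  list(scores = out, target = target)
}

# ---- the loss node ----------------------------------------------------------

# p: probability node (K, ...) in protocol channel space; Y: one-hot constant
# matrix (K x N). Classes with TP + FN = 0 (absent from the ground truth) are
# skipped in the aggregation.
ad_focal_tversky <- function(p, Y, cfg) {
  dm <- dim(p$value)
  K <- dm[1]; N <- prod(dm[-1])
  pm <- matrix(p$value, K, N)
  TP <- .rowSums(pm * Y, K, N)
  Pk <- .rowSums(pm, K, N)
  Yk <- .rowSums(Y, K, N)
  FP <- Pk - TP
  FN <- Yk - TP
  scored <- which(Yk > 0)
  if (length(scored) == 0) stopf("no scoreable class in observation")
  den <- TP + cfg$beta * FN + cfg$alpha * FP
  base <- 1 - TP / den
  Lk <- base^cfg$gamma
  agg <- if (cfg$class_aggregation == "mean") mean(Lk[scored]) else sum(Lk[scored])
  w_out <- if (cfg$class_aggregation == "mean") 1 / length(scored) else 1
  ad_node(agg, list(p), function(g) {
    g <- as.numeric(g)
    gx <- matrix(0, K, N)
    for (k in scored) {
      b <- max(base[k], 1e-6)  # clamp: gamma < 1 has infinite slope at 0
      coefo <- g * w_out * cfg$gamma * b^(cfg$gamma - 1)
      y <- Y[k, ]
      # dTI/dp = (y*den - TP*(y - beta*y + alpha*(1-y))) / den^2
      dTI <- (y * den[k] - TP[k] * (y - cfg$beta * y + cfg$alpha * (1 - y))) /
        den[k]^2
      gx[k, ] <- -coefo * dTI
    }
    list(array(gx, dim = dm))
  })
}

one_hot_channels <- function(target_ids, channels) {
  cc <- canonical_classes()
  K <- length(channels)
  N <- length(target_ids)
  Y <- matrix(0, K, N)
  t_int <- as.integer(target_ids)
  for (k in seq_len(K)) {
    ids <- cc[channels[[k]]]
    Y[k, ] <- as.numeric(t_int %in% ids)
  }
  Y
}

# Full per-observation loss on the tape (used by training).
observation_loss_node <- function(p, target, protocol, cfg, class_names) {
  groups <- protocol_channels(protocol, class_names)
  pm <- ad_merge_channels(p, groups, class_names)
  if (protocol$head_tail) pm <- ad_head_tail_pool(pm, groups, target)
  Y <- one_hot_channels(target, groups)
  ad_focal_tversky(pm, Y, cfg)
}

#' Per-observation protocol-modulated loss
#'
#' Applies the protocol's class merging and head/tail rule to the prediction,
#' one-hot encodes the target in the resulting channel space, and aggregates
#' the per-class focal Tversky losses.
#'
#' @param scores probability array (C, D, H, W) over canonical classes.
#' @param target integer array of canonical labels, same spatial grid.
#' @param protocol a [protocol_spec()].
#' @param cfg a [loss_config()].
#' @param class_names canonical names of the score channels.
#' @return scalar loss.
#' @export
observation_loss <- function(scores, target, protocol = protocol_spec(),
                             cfg = loss_config(),
                             class_names = rownames_or_default(scores)) {
  assert_that(all(dim(scores)[-1] == dim(target)),
              "scores and target shapes do not match")
  node <- observation_loss_node(ad_const(scores), target, protocol, cfg,
                                class_names)
  node$value
}
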