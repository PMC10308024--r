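test_that("focal Tversky matches its closed form", {
  cfg <- loss_config()  # alpha 0.3, beta 0.7, gamma 0.75
  # perfect prediction
  expect_equal(focal_tversky(list(TP = 5, FP = 0, FN = 0), cfg), 0)
  # zero true positives
  expect_equal(focal_tversky(list(TP = 0, FP = 2, FN = 1), cfg), 1)
  # worked value: TI = 2/(2 + 0.7 + 0.3) = 2/3, L = (1/3)^0.75
  expect_equal(focal_tversky(list(TP = 2, FP = 1, FN = 1), cfg),
               (1 / 3)^0.75, tolerance = 1e-12)
  # all-zero counts are skipped (NA), not an error
  expect_true(is.na(focal_tversky(list(TP = 0, FP = 0, FN = 0), cfg)))
  # vectorized over classes, always in [0,1]
  set.seed(1)
  counts <- list(TP = runif(20, 0, 5), FP = runif(20, 0, 5),
                 FN = runif(20, 0, 5))
  L <- focal_tversky(counts, cfg)
  expect_true(all(L >= 0 & L <= 1))
})

random_scores <- function(K, dims) {
  x <- array(runif(K * prod(dims)), dim = c(K, dims))
  sweep(x, 2:4, apply(x, 2:4, sum), "/")
}

test_that("merging sums probability mass and is swap-invariant", {
  set.seed(2)
  cls <- c("BG", "DG", "CA1", "CA2", "CA3", "SUB")
  p <- random_scores(6, c(4, 4, 4))
  pr <- protocol_spec(merge_groups = list(c("CA2", "CA3")))
  m <- merge_predictions(p, pr, cls)
  expect_equal(dim(m)[1], 5)
  expect_equal(m[4, , , ], p[4, , , ] + p[5, , , ])
  # still a distribution
  expect_true(all(abs(apply(m, 2:4, sum) - 1) < 1e-12))
  # identity protocol: unchanged
  expect_equal(merge_predictions(p, protocol_spec(), cls), p,
               ignore_attr = TRUE)
  # loss invariant to swapping CA2 <-> CA3 probability mass
  tgt <- array(sample(0:5, 64, TRUE), dim = c(4, 4, 4))
  p_swap <- p; p_swap[4, , , ] <- p[5, , , ]; p_swap[5, , , ] <- p[4, , , ]
  expect_equal(observation_loss(p, tgt, pr, class_names = cls),
               observation_loss(p_swap, tgt, pr, class_names = cls))
})

test_that("head/tail rule pools subfield predictions inside the caps", {
  cls <- c("BG", "DG", "CA1", "CA2", "CA3", "SUB", "HEAD", "TAIL")
  cc <- canonical_classes()
  # 5^3 toy: head region in the first two slices, DG body behind
  tgt <- array(0L, dim = c(5, 5, 5))
  tgt[, 1:2, ] <- cc[["HEAD"]]
  tgt[, 3:5, ] <- cc[["DG"]]
  # prediction: DG everywhere
  p <- array(0, dim = c(8, 5, 5, 5)); p[2, , , ] <- 1
  pr <- protocol_spec(head_tail = TRUE)
  # with the rule: DG inside HEAD counts as TP of 'hippocampus' -> only the
  # HEAD/TAIL channel itself is imperfect through the DG channel outside
  L_rule <- observation_loss(p, tgt, pr, class_names = cls)
  L_norule <- observation_loss(p, tgt, protocol_spec(), class_names = cls)
  expect_lt(L_rule, L_norule)
  # perfect prediction of DG body + anything-subfield in head scores 0 on
  # both scored classes
  scores <- merge_predictions(p, pr, cls)
  ht <- apply_head_tail_rule(scores, tgt, pr, cls)
  K <- dim(ht$scores)[1]
  pm <- matrix(ht$scores, K, 125)
  head_ch <- which(vapply(attr(ht$scores, "channels"),
                          function(g) "HEAD" %in% g, logical(1)))
  expect_true(all(pm[head_ch, as.integer(tgt) == cc[["HEAD"]]] == 1))
  # DG outside the hippocampus still penalized: background target, DG pred
  tgt_bg <- array(0L, dim = c(5, 5, 5))
  expect_gt(observation_loss(p, tgt_bg, pr, class_names = cls), 0.4)
  # protocol without head/tail: identity
  s2 <- random_scores(8, c(5, 5, 5))
  expect_equal(apply_head_tail_rule(s2, tgt, protocol_spec(), cls)$scores, s2,
               ignore_attr = TRUE)
})

test_that("alpha = beta = 0.5, gamma = 1 reduces to one-minus-soft-Dice", {
  set.seed(3)
  cls <- c("BG", "DG", "CA1")
  cfg <- loss_config(alpha = 0.5, beta = 0.5, gamma = 1)
  for (i in 1:20) {
    p <- random_scores(3, c(3, 3, 3))
    tgt <- array(sample(0:2, 27, TRUE), dim = c(3, 3, 3))
    L <- observation_loss(p, tgt, protocol_spec(), cfg, cls)
    # brute-force soft Dice per class
    dice_c <- vapply(0:2, function(k) {
      y <- as.numeric(tgt == k)
      pk <- as.numeric(p[k + 1, , , ])
      2 * sum(pk * y) / (sum(pk) + sum(y))
    }, numeric(1))
    scored <- vapply(0:2, function(k) any(tgt == k), logical(1))
    expect_equal(L, mean(1 - dice_c[scored]), tolerance = 1e-12)
  }
})

test_that("perfect one-hot prediction yields zero loss", {
  tgt <- tiny_phantom()$labels$data
  K <- 6
  p <- array(0, dim = c(K, dim(tgt)))
  for (k in 0:(K - 1)) p[k + 1, , , ][tgt == k] <- 1
  expect_equal(observation_loss(p, tgt, protocol_spec(),
                                class_names = names(canonical_classes())[1:6]),
               0)
})

test_that("merging never increases loss for within-group confusions", {
  set.seed(4)
  cls <- c("BG", "DG", "CA1", "CA2", "CA3", "SUB")
  pr <- protocol_spec(merge_groups = list(c("CA2", "CA3")))
  for (i in 1:10) {
    tgt <- array(sample(c(0L, 3L, 4L), 64, TRUE), dim = c(4, 4, 4))
    # confusions only within the merge group: predict CA3 mass where CA2 is
    p <- array(0, dim = c(6, 4, 4, 4))
    mix <- runif(1, 0.2, 0.8)
    p[1, , , ][tgt == 0] <- 1
    p[4, , , ][tgt == 3] <- mix;      p[5, , , ][tgt == 3] <- 1 - mix
    p[4, , , ][tgt == 4] <- 1 - mix;  p[5, , , ][tgt == 4] <- mix
    L_merged <- observation_loss(p, tgt, pr, class_names = cls)
    L_full <- observation_loss(p, tgt, protocol_spec(), class_names = cls)
    expect_lte(L_merged, L_full + 1e-12)
  }
})
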