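test_that("best_agglomeration assigns by maximal overlap", {
  lab <- random_labels(8, 8, 5, 11)
  # perfect superpixels: identity grouping
  a <- best_agglomeration(lab, lab)
  expect_equal(unname(a$assignment), as.integer(names(a$assignment)))

  # 60/40 overlap goes to the majority segment
  sp <- matrix(1L, 10, 10)
  gold <- matrix(2L, 10, 10)
  gold[, 1:6] <- 1L
  a2 <- best_agglomeration(sp, gold)
  expect_equal(unname(a2$assignment), 1L)

  # two superpixels majority-overlapping the same gold segment share a group
  sp3 <- matrix(rep(1:2, each = 50), 10, 10)
  gold3 <- matrix(7L, 10, 10)
  a3 <- best_agglomeration(sp3, gold3)
  expect_equal(unname(a3$assignment), c(1L, 1L) * 7L)
  expect_equal(length(a3$groups), 1L)

  # superpixel overlapping only unlabeled gold: warned, group 0
  gold4 <- matrix(c(rep(1L, 50), rep(0L, 50)), 10, 10)
  expect_warning(a4 <- best_agglomeration(sp3, gold4), "unassigned")
  expect_equal(unname(a4$assignment["2"]), 0L)
})

test_that("merge labels follow the should/don't/don't-know rule", {
  # groups {1,2} and {3,4} on a 2x2 grid of segments
  lab <- matrix(0L, 4, 4)
  lab[1:2, 1:2] <- 1L; lab[1:2, 3:4] <- 2L
  lab[3:4, 1:2] <- 3L; lab[3:4, 3:4] <- 4L
  gold <- matrix(0L, 4, 4)
  gold[1:2, ] <- 10L; gold[3:4, ] <- 20L
  rag <- build_rag(lab, list(matrix(0.5, 4, 4)))
  astar <- best_agglomeration(lab, gold)
  expect_equal(merge_label(rag, 1, 2, astar), 1L)    # same group
  expect_equal(merge_label(rag, 1, 3, astar), -1L)   # different groups
  expect_equal(merge_label(rag, 1, 2, gold), 1L)
  expect_equal(merge_label(rag, 1, 3, gold), -1L)
  # a region straddling two gold segments: don't know (gold reference)
  gold2 <- gold; gold2[1:2, 1] <- 30L   # segment 1 now mixes gold 30 and 10
  expect_equal(merge_label(rag, 1, 2, gold2), 0L)
  expect_error(merge_label(rag, 1, 4, astar), "no edge")
})

test_that("flat learning labels every decisive initial edge", {
  lab <- random_labels(10, 10, 6, 13)
  cues <- random_cues(dim(lab), 1, 13)
  rag <- build_rag(lab, cues)
  # superpixels identical to gold: everything is a boundary
  ts <- flat_learning(rag, best_agglomeration(lab, lab))
  expect_true(all(ts$labels == -1L))
  expect_lte(length(ts$labels), nrow(rag_edges(rag)))

  # one gold segment: everything merges
  gold1 <- matrix(1L, 10, 10)
  ts2 <- flat_learning(rag, best_agglomeration(lab, gold1))
  expect_true(all(ts2$labels == 1L))
  expect_equal(length(ts2$labels), nrow(rag_edges(rag)))
})

test_that("fit_policy trains probabilistic classifiers on all backends", {
  set.seed(7)
  n <- 120
  x <- cbind(a = c(runif(n / 2, 0, 0.4), runif(n / 2, 0.6, 1)),
             b = runif(n))
  y <- rep(c(1L, -1L), each = n / 2)
  ts <- training_set(x, y)
  for (type in c("forest", "bagged_logistic", "logistic")) {
    pol <- fit_policy(ts, classifier_spec(type = type), seed = 5)
    p <- predict(pol, x)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(mean((p > 0.5) == (y == 1L)), 1)   # linearly separable
    # reproducible given the seed
    pol2 <- fit_policy(ts, classifier_spec(type = type), seed = 5)
    expect_equal(predict(pol2, x), p)
  }
  # duplicating every example leaves the decision function almost unchanged
  pol1 <- fit_policy(ts, classifier_spec(type = "logistic"), seed = 5)
  ts2 <- bind_training_sets(ts, ts)
  pol3 <- fit_policy(ts2, classifier_spec(type = "logistic"), seed = 5)
  expect_equal(predict(pol3, x), predict(pol1, x), tolerance = 0.05)

  expect_error(fit_policy(training_set(x[1:10, ], rep(1L, 10))), "single class")
})

test_that("gala_epoch terminates at the best agglomeration with pure labels", {
  # 4 superpixels, reference groups {1,2} and {3,4}
  lab <- matrix(0L, 4, 4)
  lab[1:2, 1:2] <- 1L; lab[1:2, 3:4] <- 2L
  lab[3:4, 1:2] <- 3L; lab[3:4, 3:4] <- 4L
  gold <- matrix(0L, 4, 4)
  gold[1:2, ] <- 10L; gold[3:4, ] <- 20L
  cue <- matrix(0.5, 4, 4)
  astar <- best_agglomeration(lab, gold)
  rag <- build_rag(lab, list(cue))
  ts <- gala_epoch(rag, astar, mean_boundary_policy(), seed = 1)
  expect_equal(length(rag_nodes(rag)), 2L)
  expect_true(all(ts$provenance$label != 0L))
  seg <- current_segmentation(rag)
  expect_equal(vi(seg, gold)$total, 0)

  # single reference group: exactly n - 1 merges
  gold1 <- matrix(1L, 4, 4)
  rag2 <- build_rag(lab, list(cue))
  ts2 <- gala_epoch(rag2, best_agglomeration(lab, gold1), mean_boundary_policy())
  expect_equal(sum(ts2$labels == 1L), 3L)
  expect_equal(length(rag_nodes(rag2)), 1L)

  # determinism: identical example sequence under the same policy and seed
  ph <- tiny_phantom(seed = 2)
  astar3 <- best_agglomeration(ph$superpixels, ph$gold)
  r1 <- build_rag(ph$superpixels, ph$cues)
  r2 <- build_rag(ph$superpixels, ph$cues)
  e1 <- gala_epoch(r1, astar3, mean_boundary_policy(), seed = 9)
  e2 <- gala_epoch(r2, astar3, mean_boundary_policy(), seed = 9)
  expect_identical(e1$provenance, e2$provenance)
  expect_equal(e1$features, e2$features)
  # no 'don't know' labels ever occur against the best agglomeration
  expect_true(all(e1$provenance$label %in% c(-1L, 1L)))
})

test_that("gala_train with 0 epochs is flat learning plus a single fit", {
  ph <- tiny_phantom(seed = 3)
  fit0 <- gala_train(ph$superpixels, ph$cues, ph$gold, epochs = 0, seed = 4)
  expect_true(all(fit0$training_set$provenance$source == "flat"))
  rag <- build_rag(ph$superpixels, ph$cues)
  flat_ts <- flat_learning(rag, fit0$astar)
  expect_equal(fit0$training_set$labels, flat_ts$labels)

  # each epoch's concatenated set strictly contains the previous one
  fit2 <- gala_train(ph$superpixels, ph$cues, ph$gold, epochs = 2, seed = 4)
  counts <- fit2$epoch_summary$n_examples
  expect_equal(length(counts), 3L)
  expect_true(all(counts > 0L))
  expect_equal(length(fit2$training_set$labels),
               sum(abs(fit2$training_set$provenance$label[fit2$training_set$provenance$kept]) > 0))
})

test_that("a learned policy ranks true merges above false ones on held-out data", {
  tr <- tiny_phantom(seed = 5)
  te <- tiny_phantom(seed = 6)
  fit <- gala_train(tr$superpixels, tr$cues, tr$gold, epochs = 2, seed = 5)
  rag <- build_rag(te$superpixels, te$cues)
  astar <- best_agglomeration(te$superpixels, te$gold)
  ed <- rag_edges(rag)
  lab <- mapply(function(u, v) merge_label(rag, u, v, astar), ed$u, ed$v)
  sc <- policy_score(fit$policy, rag, cbind(ed$u, ed$v))
  pos <- sc[lab == 1L]; neg <- sc[lab == -1L]
  auc <- mean(outer(pos, neg, `<`) + 0.5 * outer(pos, neg, `==`))
  expect_gt(auc, 0.95)
})

test_that("lash labels carry the sign of the Rand index change", {
  # 1x6 strip: gold [1 1 1 1 2 2], superpixels [1 1 2 2 3 3]
  sp <- matrix(c(1L, 1L, 2L, 2L, 3L, 3L), 1, 6)
  gold <- matrix(c(1L, 1L, 1L, 1L, 2L, 2L), 1, 6)
  cue <- matrix(0.5, 1, 6)
  rag <- build_rag(sp, list(cue))
  # direct RI oracle: merging within gold 1 raises RI, across gold lowers it
  seg_base <- sp
  seg_12 <- matrix(c(1L, 1L, 1L, 1L, 3L, 3L), 1, 6)
  seg_23 <- matrix(c(1L, 1L, 2L, 2L, 2L, 2L), 1, 6)
  expect_gt(rand_index(seg_12, gold), rand_index(seg_base, gold))
  expect_lt(rand_index(seg_23, gold), rand_index(seg_base, gold))

  ts <- lash_epoch(rag, gold, mean_boundary_policy(), seed = 1)
  prov <- ts$provenance
  lab12 <- prov$label[(prov$u == 1 & prov$v == 2)]
  expect_equal(lab12, 1L)
  # merges proceed regardless of label: ends fully merged
  expect_equal(length(rag_nodes(rag)), 1L)
  # the cross-gold merge it was forced to make is labeled -1
  expect_true(any(prov$label == -1L))
})

test_that("labels against A* and against gold agree when both are decisive", {
  ph <- tiny_phantom(seed = 7)
  rag <- build_rag(ph$superpixels, ph$cues)
  astar <- best_agglomeration(ph$superpixels, ph$gold)
  ed <- rag_edges(rag)
  for (i in seq_len(nrow(ed))) {
    la <- merge_label(rag, ed$u[i], ed$v[i], astar)
    lg <- merge_label(rag, ed$u[i], ed$v[i], ph$gold)
    if (la != 0L && lg != 0L) expect_equal(la, lg)
  }
})
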