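test_that("histogram features recover location and moments", {
  cfg <- feature_config(bins = 10L, n_quantiles = 3L)
  # constant 0.5: all quantiles inside the bin containing 0.5, zero moments
  m <- matrix(c(1, 1, 2, 2), 2, 2, byrow = TRUE)
  rag <- build_rag(m, list(matrix(0.5, 2, 2)), bins = 10L)
  f <- histogram_features(agglearn:::node_stats(rag, 1)[[1]], cfg)
  expect_true(all(f[c("q25", "q5", "q75")] >= 0.5 & f[c("q25", "q5", "q75")] <= 0.6))
  expect_equal(unname(f["mean"]), 0.5)
  expect_equal(unname(f[c("cm2", "cm3", "cm4")]), c(0, 0, 0))

  # 1000 uniform samples, 25 bins: median within 0.5 +/- 0.05 and close to
  # the direct order-statistic median of the same sample
  set.seed(4)
  v <- runif(1000)
  lab <- matrix(1L, 40, 25)
  rag2 <- build_rag(lab, list(matrix(v, 40, 25)), bins = 25L)
  f2 <- histogram_features(agglearn:::node_stats(rag2, 1)[[1]],
                           feature_config(bins = 25L, n_quantiles = 9L))
  expect_lt(abs(f2[["q5"]] - 0.5), 0.05)
  expect_lt(abs(f2[["q5"]] - median(v)), 1 / 25)

  # quantiles non-decreasing for arbitrary inputs
  for (seed in 1:5) {
    set.seed(seed)
    lab3 <- matrix(1L, 6, 6)
    rag3 <- build_rag(lab3, list(matrix(runif(36), 6, 6)))
    q <- histogram_features(agglearn:::node_stats(rag3, 1)[[1]],
                            feature_config(n_quantiles = 9L))[1:9]
    expect_true(all(diff(q) >= 0))
  }
})

test_that("Jensen-Shannon divergence has its closed-form values", {
  p <- numeric(25); p[1] <- 1
  q <- numeric(25); q[25] <- 1
  expect_equal(jsd(p, q), 1)                       # disjoint: 1 bit
  # closed form: H(M) - (H(P) + H(Q))/2 with M = (3/4, 1/4)
  expect_equal(jsd(c(0.5, 0.5), c(1, 0)),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)) - 0.5,
               tolerance = 1e-12)
  expect_equal(round(jsd(c(0.5, 0.5), c(1, 0)), 4), 0.3113)
  expect_equal(jsd(p, p), 0)
  for (seed in 1:10) {
    set.seed(seed)
    a <- runif(25); b <- runif(25)
    expect_equal(jsd(a, b), jsd(b, a))
    expect_gte(jsd(a, b), 0)
    expect_lte(jsd(a, b), 1)
  }
})

test_that("pair features are symmetric, schema-stable, and null for twins", {
  lab <- random_labels(10, 10, 6, 21)
  cues <- random_cues(dim(lab), 2, 21)
  rag <- build_rag(lab, cues)
  cfg <- feature_config()
  ed <- rag_edges(rag)
  len <- NULL
  for (i in seq_len(nrow(ed))) {
    fuv <- pair_features(rag, ed$u[i], ed$v[i], cfg)
    fvu <- pair_features(rag, ed$v[i], ed$u[i], cfg)
    expect_identical(fuv, fvu)
    len <- c(len, length(fuv))
  }
  expect_equal(length(unique(len)), 1L)
  # schema length survives merges
  merge_nodes(rag, ed$u[1], ed$v[1])
  ed2 <- rag_edges(rag)
  expect_equal(length(pair_features(rag, ed2$u[1], ed2$v[1], cfg)), len[1])

  # identical cue distributions in u and v: zero moment differences and JSD
  m <- matrix(c(1, 1, 2, 2), 2, 2, byrow = TRUE)
  r <- build_rag(m, list(matrix(c(0.2, 0.2, 0.8, 0.8), 2, 2)))
  f <- pair_features(r, 1, 2)
  expect_equal(unname(f[c("dcm2_ch1", "dcm3_ch1", "dcm4_ch1", "jsd_ch1")]),
               c(0, 0, 0, 0))
})

test_that("cached features equal features on a freshly built merged RAG", {
  cfg <- feature_config()
  for (seed in 1:4) {
    set.seed(seed + 300)
    lab <- random_labels(9, 9, 7, seed + 30)
    cues <- random_cues(dim(lab), 2, seed + 60)
    rag <- build_rag(lab, cues)
    for (k in 1:3) {
      ed <- rag_edges(rag)
      if (nrow(ed) == 0L) break
      i <- sample.int(nrow(ed), 1)
      merge_nodes(rag, ed$u[i], ed$v[i])
    }
    fresh <- build_rag(current_segmentation(rag), cues)
    ed <- rag_edges(rag)
    for (i in seq_len(nrow(ed))) {
      expect_equal(pair_features(rag, ed$u[i], ed$v[i], cfg),
                   pair_features(fresh, ed$u[i], ed$v[i], cfg),
                   tolerance = 1e-9)
    }
  }
})

test_that("orientation features measure relative elongation angles", {
  # two horizontal bars side by side on the same row: collinear, all ~0
  m <- matrix(2L, 7, 12)
  m[4, 1:5] <- 1L
  m <- m; m2 <- m
  lab <- matrix(3L, 7, 12)
  lab[4, 1:5] <- 1L
  lab[4, 8:12] <- 2L
  rag <- build_rag(lab, list(matrix(0.5, 7, 12)), midlevel = TRUE)
  # 1 and 2 are not adjacent; angles only need node stats
  f <- orientation_features(rag, 1, 2)
  expect_lt(max(abs(f)), 1e-9)

  # identical horizontal bar above another: axes parallel (0), both
  # perpendicular to the vertical centroid line (pi/2)
  lab2 <- matrix(3L, 9, 9)
  lab2[2, 2:8] <- 1L
  lab2[7, 2:8] <- 2L
  rag2 <- build_rag(lab2, list(matrix(0.5, 9, 9)), midlevel = TRUE)
  f2 <- orientation_features(rag2, 1, 2)
  expect_equal(unname(f2["angle_axes"]), 0)
  expect_equal(unname(f2["angle_small_centroid"]), pi / 2)
  expect_equal(unname(f2["angle_large_centroid"]), pi / 2)

  # rotating the whole image by 90 degrees leaves relative angles unchanged
  lab3 <- t(lab2)[, rev(seq_len(nrow(lab2)))]
  lab3 <- matrix(as.integer(lab3), nrow(lab3), ncol(lab3))
  rag3 <- build_rag(lab3, list(matrix(0.5, 9, 9)), midlevel = TRUE)
  expect_equal(orientation_features(rag3, 1, 2), f2, tolerance = 1e-9)

  # single-pixel region: sentinel pi/4
  lab4 <- matrix(3L, 5, 5)
  lab4[2, 2] <- 1L
  lab4[4, 2:4] <- 2L
  rag4 <- build_rag(lab4, list(matrix(0.5, 5, 5)), midlevel = TRUE)
  f4 <- orientation_features(rag4, 1, 2)
  expect_equal(unname(f4["angle_axes"]), pi / 4)
})

test_that("convex hull features measure convexity", {
  # solid rectangle: ratio exactly 1
  lab <- matrix(2L, 10, 10)
  lab[3:6, 3:8] <- 1L
  rag <- build_rag(lab, list(matrix(0.5, 10, 10)), midlevel = TRUE)
  f <- convex_hull_features(rag, 1, 2)
  expect_equal(unname(f["convexity_small"]), 1)

  # L-shape of three 10x10 cells of a 2x2 block: the hull is the pentagon
  # cutting the missing corner, area 350, so the ratio is 300/350 = 6/7
  lab2 <- matrix(3L, 22, 22)
  lab2[1:20, 1:10] <- 1L
  lab2[11:20, 11:20] <- 1L
  lab2[1:10, 11:20] <- 2L
  rag2 <- build_rag(lab2, list(matrix(0.5, 22, 22)), midlevel = TRUE)
  f2 <- convex_hull_features(rag2, 1, 2)
  expect_equal(unname(f2["convexity_large"]), 300 / 350, tolerance = 1e-9)

  # two distant small squares: union ratio far below individual ratios
  lab3 <- matrix(3L, 9, 30)
  lab3[4:6, 1:3] <- 1L
  lab3[4:6, 28:30] <- 2L
  rag3 <- build_rag(lab3, list(matrix(0.5, 9, 30)), midlevel = TRUE)
  f3 <- convex_hull_features(rag3, 1, 2)
  expect_equal(unname(f3["convexity_small"]), 1)
  expect_lt(unname(f3["convexity_union"]), 0.4)
})
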