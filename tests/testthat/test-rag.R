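test_that("build_rag creates exactly the face-adjacency graph", {
  # two-region strip
  m <- matrix(c(1, 1, 2, 2), 2, 2, byrow = TRUE)
  rag <- build_rag(m, list(matrix(0.5, 2, 2)))
  expect_equal(rag_nodes(rag), c(1L, 2L))
  expect_equal(as.matrix(rag_edges(rag)), cbind(u = 1L, v = 2L))

  # 2x2 with four labels: no diagonal edges
  m2 <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  r2 <- build_rag(m2, list(matrix(0.5, 2, 2)))
  ed <- rag_edges(r2)
  expect_equal(as.matrix(ed),
               cbind(u = c(1L, 1L, 2L, 3L), v = c(2L, 3L, 4L, 4L)))
  expect_false(has_edge(r2, 1, 4))
  expect_false(has_edge(r2, 2, 3))

  # single region: one node, zero edges
  r3 <- build_rag(matrix(1L, 3, 3), list(matrix(0.1, 3, 3)))
  expect_equal(rag_nodes(r3), 1L)
  expect_equal(nrow(rag_edges(r3)), 0L)
})

test_that("build_rag edge set matches brute force on random volumes", {
  for (seed in 1:6) {
    lab <- random_labels(8, 9, sample(3:7, 1), seed)
    rag <- build_rag(lab, random_cues(dim(lab), 1, seed))
    expect_equal(unname(as.matrix(rag_edges(rag))), unname(bf_edges(lab)),
                 info = paste("seed", seed))
    # adjacency symmetric
    ed <- rag_edges(rag)
    for (i in seq_len(nrow(ed))) {
      expect_true(ed$v[i] %in% rag_neighbors(rag, ed$u[i]))
      expect_true(ed$u[i] %in% rag_neighbors(rag, ed$v[i]))
    }
  }
})

test_that("build_rag validates its inputs", {
  m <- matrix(c(1, 1, 2, 2), 2, 2)
  expect_error(build_rag(m, list(matrix(0.5, 3, 3))), "shape")
  expect_error(build_rag(matrix(0L, 2, 2), list(matrix(0.5, 2, 2))),
               "no non-zero")
  expect_error(build_rag(m, list(matrix(1.5, 2, 2))), "outside")
  expect_silent(build_rag(m, list(matrix(1.5, 2, 2)), clamp = TRUE))
  expect_error(build_rag(m, list()), "non-empty")
})

test_that("boundary_pixels returns the two-sided boundary", {
  m <- matrix(c(1, 1, 2, 2), 2, 2, byrow = TRUE)
  rag <- build_rag(m, list(matrix(0.5, 2, 2)))
  expect_equal(sort(attr(boundary_pixels(rag, 1, 2), "index")), 1:4)

  m2 <- rbind(matrix(1L, 2, 3), matrix(2L, 1, 3))
  r2 <- build_rag(m2, list(matrix(0.5, 3, 3)))
  expect_equal(sort(attr(boundary_pixels(r2, 1, 2), "index")),
               bf_boundary(m2, 1L, 2L))
  expect_equal(length(attr(boundary_pixels(r2, 1, 2), "index")), 6L)

  m3 <- matrix(c(1, 2, 2, 3), 2, 2, byrow = TRUE)   # 1 and 3 share no face
  r3 <- build_rag(m3, list(matrix(0.5, 2, 2)))
  expect_error(boundary_pixels(r3, 1, 3), "no edge")
})

test_that("ridge mode bridges 0-labeled watershed lines", {
  m <- rbind(matrix(1L, 1, 3), matrix(0L, 1, 3), matrix(2L, 1, 3))
  cue <- matrix(0.5, 3, 3)
  thick <- build_rag(m, list(cue))
  expect_equal(nrow(rag_edges(thick)), 0L)   # no direct contact
  ridge <- build_rag(m, list(cue), boundary_mode = "ridge")
  expect_true(has_edge(ridge, 1, 2))
  # the boundary is the line pixels (middle row)
  expect_equal(sort(attr(boundary_pixels(ridge, 1, 2), "index")),
               which(m == 0L))
})

test_that("merge_nodes unions neighbors and conserves pixels", {
  # chain 1-2-3: merging (1,2) leaves two nodes, one edge to 3
  m <- matrix(rep(1:3, each = 2), 1, 6)
  rag <- build_rag(m, list(matrix(0.2, 1, 6)))
  w <- merge_nodes(rag, 1, 2)
  expect_equal(w, 1L)
  expect_equal(rag_nodes(rag), c(1L, 3L))
  expect_equal(as.matrix(rag_edges(rag)), cbind(u = 1L, v = 3L))

  # square graph: merged node adjacent to both former neighbors
  m2 <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  r2 <- build_rag(m2, list(matrix(0.5, 2, 2)))
  merge_nodes(r2, 1, 2)
  expect_setequal(rag_neighbors(r2, 1), c(3L, 4L))

  expect_error(merge_nodes(r2, 3, 3), "itself")
  lab <- random_labels(6, 6, 5, 7)
  r3 <- build_rag(lab, list(random_cues(dim(lab), 1, 7)[[1]]))
  nonadj <- NULL
  ids <- rag_nodes(r3)
  for (u in ids) for (v in ids) {
    if (u < v && !has_edge(r3, u, v)) nonadj <- c(u, v)
  }
  if (!is.null(nonadj)) expect_error(merge_nodes(r3, nonadj[1], nonadj[2]), "no edge")
})

test_that("cached statistics survive random merge sequences (recompute oracle)", {
  for (seed in 1:5) {
    set.seed(seed + 100)
    lab <- random_labels(sample(6:12, 1), sample(6:12, 1), sample(4:9, 1), seed)
    cues <- random_cues(dim(lab), 2, seed + 50)
    rag <- build_rag(lab, cues)
    n_merges <- sample(1:4, 1)
    mass0 <- sum(vapply(rag_nodes(rag), function(id) {
      agglearn:::node_stats(rag, id)[[1]]$n
    }, numeric(1)))
    for (k in seq_len(n_merges)) {
      ed <- rag_edges(rag)
      if (nrow(ed) == 0L) break
      i <- sample.int(nrow(ed), 1)
      n_before <- length(rag_nodes(rag))
      merge_nodes(rag, ed$u[i], ed$v[i])
      expect_equal(length(rag_nodes(rag)), n_before - 1L)
    }
    # recompute oracle: a fresh RAG built from the merged segmentation must
    # agree on every node and edge statistic
    seg <- current_segmentation(rag)
    fresh <- build_rag(seg, cues)
    expect_setequal(rag_nodes(rag), rag_nodes(fresh))
    expect_equal(sum(vapply(rag_nodes(rag), function(id) {
      agglearn:::node_stats(rag, id)[[1]]$n
    }, numeric(1))), mass0)
    for (id in rag_nodes(rag)) {
      a <- agglearn:::node_stats(rag, id)
      b <- agglearn:::node_stats(fresh, id)
      for (ch in 1:2) {
        expect_equal(a[[ch]]$hist, b[[ch]]$hist)
        expect_equal(a[[ch]]$mean, b[[ch]]$mean, tolerance = 1e-9)
        expect_equal(a[[ch]]$cm4, b[[ch]]$cm4, tolerance = 1e-9)
      }
    }
    ed <- rag_edges(rag)
    for (i in seq_len(nrow(ed))) {
      a <- agglearn:::edge_stats(rag, ed$u[i], ed$v[i])
      b <- agglearn:::edge_stats(fresh, ed$u[i], ed$v[i])
      expect_equal(a[[1]]$hist, b[[1]]$hist)
      expect_equal(a[[1]]$mean, b[[1]]$mean, tolerance = 1e-9)
    }
  }
})

test_that("current_segmentation relabels consistently", {
  lab <- random_labels(7, 7, 5, 9)
  cues <- random_cues(dim(lab), 1, 9)
  rag <- build_rag(lab, cues)
  expect_equal(current_segmentation(rag), lab)  # ids already node ids

  # full merge: constant non-zero volume
  repeat {
    ed <- rag_edges(rag)
    if (nrow(ed) == 0L) break
    merge_nodes(rag, ed$u[1], ed$v[1])
  }
  seg <- current_segmentation(rag)
  expect_equal(length(unique(as.integer(seg))), 1L)
  expect_true(all(seg > 0L))

  m <- matrix(c(1, 1, 2, 2), 2, 2, byrow = TRUE)
  r <- build_rag(m, list(matrix(0.5, 2, 2)))
  merge_nodes(r, 1, 2)
  expect_equal(unique(as.integer(current_segmentation(r))), 1L)
})
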