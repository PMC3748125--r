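# Independent brute-force oracles and small fixture generators.  Everything
# here is deliberately naive: double loops over pixels and pairs, so the
# package's incremental/vectorized paths are checked against first
# principles.

# all face-adjacent pixel index pairs of an array, by explicit loops
bf_neighbor_pairs <- function(dims) {
  nd <- length(dims)
  co <- arrayInd(seq_len(prod(dims)), dims)
  a <- integer(0); b <- integer(0)
  for (i in seq_len(nrow(co))) {
    for (k in seq_len(nd)) {
      nb <- co[i, ]
      nb[k] <- nb[k] + 1L
      if (nb[k] <= dims[k]) {
        j <- sum((nb - 1L) * cumprod(c(1L, dims[-nd]))) + 1L
        a <- c(a, i); b <- c(b, j)
      }
    }
  }
  list(a = a, b = b)
}

# brute-force RAG edge set: sorted unique label pairs across adjacent pixels
bf_edges <- function(labels) {
  np <- bf_neighbor_pairs(dim(labels))
  la <- labels[np$a]; lb <- labels[np$b]
  keep <- la != lb & la > 0L & lb > 0L
  if (!any(keep)) return(matrix(integer(0), 0L, 2L))
  e <- unique(cbind(pmin(la[keep], lb[keep]), pmax(la[keep], lb[keep])))
  e[order(e[, 1L], e[, 2L]), , drop = FALSE]
}

# brute-force two-sided boundary pixel set of a label pair
bf_boundary <- function(labels, u, v) {
  np <- bf_neighbor_pairs(dim(labels))
  la <- labels[np$a]; lb <- labels[np$b]
  hit <- (la == u & lb == v) | (la == v & lb == u)
  sort(unique(c(np$a[hit], np$b[hit])))
}

# O(n^2) pair-counting Rand and adjusted Rand
bf_pair_metrics <- function(s, u) {
  s <- as.integer(s); u <- as.integer(u)
  n <- length(s)
  agree <- 0; same_s <- 0; same_u <- 0; same_both <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ss <- s[i] == s[j]; uu <- u[i] == u[j]
      agree <- agree + (ss == uu)
      same_s <- same_s + ss; same_u <- same_u + uu
      same_both <- same_both + (ss && uu)
    }
  }
  np <- n * (n - 1) / 2
  expected <- same_s * same_u / np
  maxi <- (same_s + same_u) / 2
  ari <- if (abs(maxi - expected) < 1e-12) 1 else (same_both - expected) / (maxi - expected)
  list(ri = agree / np, ari = ari)
}

# direct VI from the joint label table (independent of contingency())
bf_vi <- function(s, u) {
  tab <- table(as.integer(s), as.integer(u))
  p <- tab / sum(tab)
  ps <- rowSums(p); pu <- colSums(p)
  h <- function(x) { x <- x[x > 0]; -sum(x * log2(x)) }
  hj <- h(as.numeric(p))
  list(under = hj - h(ps), over = hj - h(pu), total = 2 * hj - h(ps) - h(pu))
}

# seeded random label volume: Voronoi of k random sites on an ny x nx grid
random_labels <- function(ny, nx, k, seed) {
  set.seed(seed)
  sy <- runif(k, 1, ny); sx <- runif(k, 1, nx)
  co <- arrayInd(seq_len(ny * nx), c(ny, nx))
  d2 <- outer(co[, 1L], sy, `-`)^2 + outer(co[, 2L], sx, `-`)^2
  matrix(max.col(-d2, ties.method = "first"), ny, nx)
}

random_cues <- function(dims, n_channels, seed) {
  set.seed(seed)
  lapply(seq_len(n_channels), function(i) array(runif(prod(dims)), dim = dims))
}

# rescan-all-edges agglomeration oracle: at every step score every current
# edge, take the global minimum (ties: smallest id pair), merge while below
# the threshold.  Same primitives, independent control flow.
bf_agglomerate <- function(rag, policy, threshold) {
  hist <- list()
  repeat {
    ed <- rag_edges(rag)
    if (nrow(ed) == 0L) break
    sc <- policy_score(policy, rag, cbind(ed$u, ed$v))
    ord <- order(sc, ed$u, ed$v)
    i <- ord[1L]
    if (sc[i] >= threshold) break
    w <- merge_nodes(rag, ed$u[i], ed$v[i])
    hist[[length(hist) + 1L]] <- c(ed$u[i], ed$v[i], w)
  }
  do.call(rbind, hist)
}

# tiny ready-made phantom for training tests (cached per session)
tiny_phantom <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 1L, shape = c(64L, 64L), n_segments = 6L, spacing = 8L) {
    key <- paste(seed, paste(shape, collapse = "x"), n_segments, spacing)
    if (is.null(cache[[key]])) {
      cache[[key]] <- make_phantom(phantom_spec(
        shape = shape, n_segments = n_segments,
        superpixel_spacing = spacing, seed = seed))
    }
    cache[[key]]
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a
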