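# Internal utilities: face-neighbor index pairs, a binary min-heap, separable
# Gaussian blur, and small numeric helpers shared across modules.

#' @importFrom stats filter rnorm runif
#' @importFrom utils head tail
NULL

# All face-adjacent (a, b) linear-index pairs of an array with dimensions
# `dims`, along every axis.  Face connectivity only: 4-connectivity in 2D,
# 6-connectivity in 3D.
neighbor_pairs <- function(dims) {
  nd <- length(dims)
  idx <- array(seq_len(prod(dims)), dim = dims)
  a <- integer(0)
  b <- integer(0)
  for (k in seq_len(nd)) {
    if (dims[k] < 2L) next
    args_a <- rep(list(quote(expr = )), nd)
    args_b <- args_a
    args_a[[k]] <- seq_len(dims[k] - 1L)
    args_b[[k]] <- seq.int(2L, dims[k])
    ia <- do.call(`[`, c(list(idx), args_a, list(drop = FALSE)))
    ib <- do.call(`[`, c(list(idx), args_b, list(drop = FALSE)))
    a <- c(a, as.integer(ia))
    b <- c(b, as.integer(ib))
  }
  list(a = a, b = b)
}

# Binary min-heap over lexicographic keys (score, u, v); payload carries the
# two node-version stamps used for lazy invalidation.  Closure-free
# environment with preallocated vectors, grown by doubling.
heap_new <- function(capacity = 256L) {
  h <- new.env(parent = emptyenv())
  h$s  <- numeric(capacity)
  h$u  <- integer(capacity)
  h$v  <- integer(capacity)
  h$vu <- integer(capacity)
  h$vv <- integer(capacity)
  h$n  <- 0L
  h
}

heap_size <- function(h) h$n

.heap_less <- function(h, i, j) {
  si <- h$s[i]; sj <- h$s[j]
  if (si != sj) return(si < sj)
  if (h$u[i] != h$u[j]) return(h$u[i] < h$u[j])
  h$v[i] < h$v[j]
}

.heap_swap <- function(h, i, j) {
  for (f in c("s", "u", "v", "vu", "vv")) {
    tmp <- h[[f]][i]
    h[[f]][i] <- h[[f]][j]
    h[[f]][j] <- tmp
  }
}

heap_push <- function(h, s, u, v, vu = 0L, vv = 0L) {
  n <- h$n + 1L
  if (n > length(h$s)) {
    grow <- length(h$s)
    h$s  <- c(h$s,  numeric(grow))
    h$u  <- c(h$u,  integer(grow))
    h$v  <- c(h$v,  integer(grow))
    h$vu <- c(h$vu, integer(grow))
    h$vv <- c(h$vv, integer(grow))
  }
  h$n <- n
  h$s[n] <- s; h$u[n] <- u; h$v[n] <- v; h$vu[n] <- vu; h$vv[n] <- vv
  i <- n
  while (i > 1L) {
    p <- i %/% 2L
    if (.heap_less(h, i, p)) { .heap_swap(h, i, p); i <- p } else break
  }
  invisible(h)
}

heap_pop <- function(h) {
  if (h$n == 0L) return(NULL)
  out <- list(s = h$s[1L], u = h$u[1L], v = h$v[1L], vu = h$vu[1L], vv = h$vv[1L])
  .heap_swap(h, 1L, h$n)
  h$n <- h$n - 1L
  i <- 1L
  repeat {
    l <- 2L * i; r <- l + 1L
    m <- i
    if (l <= h$n && .heap_less(h, l, m)) m <- l
    if (r <= h$n && .heap_less(h, r, m)) m <- r
    if (m == i) break
    .heap_swap(h, i, m)
    i <- m
  }
  out
}

# Separable Gaussian blur with replicate padding; works on matrices and 3D
# arrays.  sigma = 0 is the identity.
gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(x)
  nd <- length(d)
  for (ax in seq_len(nd)) {
    perm <- c(ax, setdiff(seq_len(nd), ax))
    y <- aperm(x, perm)
    dp <- dim(y)
    m <- matrix(y, nrow = dp[1L])
    # replicate-pad rows, filter column-wise, trim
    m <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(nrow(m), r), , drop = FALSE])
    f <- stats::filter(m, k, sides = 2)
    f <- f[(r + 1L):(r + dp[1L]), , drop = FALSE]
    y <- array(as.numeric(f), dim = dp)
    x <- aperm(y, order(perm))
  }
  x
}

# Connected components of a logical mask under face connectivity; returns an
# integer array, 0 outside the mask, components numbered from 1.
mask_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  on <- which(mask)
  if (length(on) == 0L) return(lab)
  np <- neighbor_pairs(d)
  keep <- mask[np$a] & mask[np$b]
  # map pixel index -> vertex id within the mask
  vid <- integer(prod(d))
  vid[on] <- seq_along(on)
  g <- igraph::graph_from_edgelist(
    cbind(vid[np$a[keep]], vid[np$b[keep]]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(on) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[on] <- as.integer(comp)
  lab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

edge_key <- function(u, v) {
  if (u < v) paste0(u, "|", v) else paste0(v, "|", u)
}
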