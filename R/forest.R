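# A small, seeded random forest (binary classification with probability
# averaging).  No CRAN/Bioconductor tree learner is available in this
# toolchain, so the ensemble the merge policy needs is implemented here:
# bootstrap-bagged CART trees with per-node feature subsampling, grown on
# globally quantile-binned features (histogram splits), Gini criterion, and
# Laplace-smoothed leaf probabilities.

# Quantile binning: per-feature breakpoints; bin b means value <= breaks[b].
.rf_bins <- function(x, n_bins) {
  p <- ncol(x)
  breaks <- vector("list", p)
  B <- matrix(1L, nrow(x), p)
  for (j in seq_len(p)) {
    qs <- unique(stats::quantile(x[, j], probs = seq_len(n_bins - 1L) / n_bins,
                                 names = FALSE, type = 1L))
    qs <- qs[qs < max(x[, j])]          # splitting at the max sends nothing right
    breaks[[j]] <- qs
    if (length(qs)) B[, j] <- findInterval(x[, j], qs) + 1L
  }
  list(B = B, breaks = breaks)
}

# Grow one tree on bootstrap rows `idx`.  Arrays, not recursion-heavy
# structures: node k stores a feature/threshold or a leaf probability.
.rf_tree <- function(B, breaks, y, idx, mtry, min_node, max_depth) {
  max_nodes <- 4L * length(idx) + 8L
  feat <- integer(max_nodes); thr <- numeric(max_nodes)
  left <- integer(max_nodes); right <- integer(max_nodes)
  prob <- rep(NA_real_, max_nodes); leaf <- logical(max_nodes)
  n_nodes <- 1L
  stack <- list(list(node = 1L, rows = idx, depth = 0L))
  p <- ncol(B)
  while (length(stack)) {
    it <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    rows <- it$rows; k <- it$node
    m <- length(rows)
    ypos <- sum(y[rows])
    if (m < min_node || ypos == 0L || ypos == m || it$depth >= max_depth) {
      leaf[k] <- TRUE
      prob[k] <- (ypos + 1) / (m + 2)
      next
    }
    gini_parent <- 2 * ypos * (m - ypos) / m
    best <- list(score = gini_parent - 1e-12)
    for (j in sample.int(p, mtry)) {
      nb <- length(breaks[[j]])
      if (nb == 0L) next
      bj <- B[rows, j]
      cnt_tot <- tabulate(bj, nbins = nb + 1L)
      cnt_pos <- tabulate(bj[y[rows] == 1L], nbins = nb + 1L)
      mL <- cumsum(cnt_tot)[seq_len(nb)]
      pL <- cumsum(cnt_pos)[seq_len(nb)]
      mR <- m - mL; pR <- ypos - pL
      ok <- mL > 0L & mR > 0L
      if (!any(ok)) next
      score <- rep(Inf, nb)
      score[ok] <- 2 * pL[ok] * (mL[ok] - pL[ok]) / mL[ok] +
                   2 * pR[ok] * (mR[ok] - pR[ok]) / mR[ok]
      b <- which.min(score)
      if (score[b] < best$score) best <- list(score = score[b], j = j, b = b)
    }
    if (is.null(best$j)) {
      leaf[k] <- TRUE
      prob[k] <- (ypos + 1) / (m + 2)
      next
    }
    go_left <- B[rows, best$j] <= best$b
    feat[k] <- best$j
    thr[k] <- breaks[[best$j]][best$b]
    left[k] <- n_nodes + 1L
    right[k] <- n_nodes + 2L
    n_nodes <- n_nodes + 2L
    stack[[length(stack) + 1L]] <- list(node = left[k], rows = rows[go_left],
                                        depth = it$depth + 1L)
    stack[[length(stack) + 1L]] <- list(node = right[k], rows = rows[!go_left],
                                        depth = it$depth + 1L)
  }
  keep <- seq_len(n_nodes)
  list(feat = feat[keep], thr = thr[keep], left = left[keep],
       right = right[keep], prob = prob[keep], leaf = leaf[keep])
}

# Fit the forest.  y01 is 0/1; every randomness comes from the caller's RNG
# state (seed it before calling).
rf_fit <- function(x, y01, n_trees = 30L, mtry = NULL, min_node = 5L,
                   max_depth = 12L, n_bins = 32L) {
  x <- as.matrix(x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  bb <- .rf_bins(x, n_bins)
  n <- nrow(x)
  trees <- lapply(seq_len(n_trees), function(t) {
    idx <- sample.int(n, n, replace = TRUE)
    # both classes in every bootstrap
    if (sum(y01[idx]) == 0L) idx <- c(idx, sample(which(y01 == 1L), 1L))
    if (sum(y01[idx]) == length(idx)) idx <- c(idx, sample(which(y01 == 0L), 1L))
    .rf_tree(bb$B, bb$breaks, y01, idx, mtry, min_node, max_depth)
  })
  structure(list(trees = trees, p = ncol(x)), class = "agglearn_rf")
}

# Average leaf probabilities across trees.
rf_predict <- function(model, x) {
  x <- as.matrix(x)
  n <- nrow(x)
  acc <- numeric(n)
  for (tr in model$trees) {
    nd <- rep(1L, n)
    repeat {
      open <- which(!tr$leaf[nd])
      if (!length(open)) break
      f <- tr$feat[nd[open]]
      goL <- x[cbind(open, f)] <= tr$thr[nd[open]]
      nd[open] <- ifelse(goL, tr$left[nd[open]], tr$right[nd[open]])
    }
    acc <- acc + tr$prob[nd]
  }
  acc / length(model$trees)
}
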