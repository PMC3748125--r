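# Hierarchical agglomeration: apply a policy to a RAG, merging the
# minimum-score edge while that score is below the threshold.  The policy is
# local, so after a merge only the edges incident to the merged node are
# rescored; stale priority-queue entries are discarded lazily via node
# version stamps.  The merge history is a dendrogram that can be cut at any
# threshold without re-running the agglomeration.

#' Agglomerate a RAG under a policy
#'
#' Repeatedly merges the edge of minimum policy score while that score is
#' strictly below `threshold` (so `threshold = 0` performs no merges;
#' `0.5` is the canonical operating point of a calibrated learned policy).
#' Ties are broken by the smallest `(u, v)` id pair.  The RAG is mutated.
#'
#' @param rag a `"rag"`.
#' @param policy a `"merge_policy"` whose feature schema matches the RAG.
#' @param threshold merge-score cutoff in `[0, 1]`.
#' @param monotone if `TRUE`, recorded history scores are clamped to the
#'   running maximum, yielding a strict hierarchy for threshold cuts.
#' @return list with `segmentation` (label volume) and `history` (a
#'   `"merge_history"`: tibble of `step, u, v, merged, score` with the
#'   initial node count as attribute).
#' @export
agglomerate <- function(rag, policy, threshold = 0.5, monotone = FALSE) {
  stopifnot(threshold >= 0, threshold <= 1)
  ed <- rag_edges(rag)
  h <- heap_new(max(64L, 2L * nrow(ed)))
  sc <- policy_score(policy, rag, cbind(ed$u, ed$v))
  for (i in seq_len(nrow(ed))) {
    heap_push(h, sc[i], ed$u[i], ed$v[i],
              node_version(rag, ed$u[i]), node_version(rag, ed$v[i]))
  }
  n0 <- rag$n_nodes
  su <- integer(0); sv <- integer(0); sm <- integer(0); ss <- numeric(0)
  running_max <- -Inf
  while (rag$n_nodes > 1L) {
    e <- heap_pop(h)
    if (is.null(e) || e$s >= threshold) break
    if (!has_edge(rag, e$u, e$v)) next
    if (node_version(rag, e$u) != e$vu || node_version(rag, e$v) != e$vv) next
    w <- merge_nodes(rag, e$u, e$v)
    k <- length(su) + 1L
    su[k] <- e$u; sv[k] <- e$v; sm[k] <- w
    running_max <- max(running_max, e$s)
    ss[k] <- if (monotone) running_max else e$s
    nb <- rag_neighbors(rag, w)
    if (length(nb)) {
      sw <- policy_score(policy, rag, cbind(w, nb))
      for (j in seq_along(nb)) {
        heap_push(h, sw[j], min(w, nb[j]), max(w, nb[j]),
                  node_version(rag, min(w, nb[j])),
                  node_version(rag, max(w, nb[j])))
      }
    }
  }
  history <- tibble::tibble(step = seq_along(su), u = su, v = sv,
                            merged = sm, score = ss)
  attr(history, "n_initial_nodes") <- n0
  class(history) <- c("merge_history", class(history))
  list(segmentation = current_segmentation(rag), history = history)
}

#' @export
print.merge_history <- function(x, ...) {
  cat(sprintf("<merge_history> %d merge(s) from %d initial node(s)\n",
              nrow(x), attr(x, "n_initial_nodes") %||% NA_integer_))
  NextMethod()
}

#' Cut a merge history at a threshold
#'
#' Replays, in recorded order, the merges whose recorded score is strictly
#' below the threshold.  For a monotone history this equals a fresh
#' [agglomerate()] run at the same threshold; it enables ODS/OIS threshold
#' sweeps from a single saved run.
#'
#' @param history a `"merge_history"`.
#' @param superpixels the superpixel volume the history was produced from.
#' @param threshold cut level in `[0, 1]`.
#' @return a label volume.
#' @export
cut_history <- function(history, superpixels, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  superpixels <- validate_label_volume(superpixels)
  ids <- segment_ids(superpixels)
  # union-find over node ids; merged id = min(u, v) by construction
  parent <- new.env(parent = emptyenv())
  find <- function(i) {
    ci <- as.character(i)
    p <- parent[[ci]]
    if (is.null(p) || p == i) return(i)
    r <- find(p)
    parent[[ci]] <- r
    r
  }
  keep <- history$score < threshold
  for (k in which(keep)) {
    ru <- find(history$u[k]); rv <- find(history$v[k])
    if (ru == rv) next
    m <- history$merged[k]
    parent[[as.character(ru)]] <- m
    parent[[as.character(rv)]] <- m
    parent[[as.character(m)]] <- m
  }
  map <- integer(max(ids))
  for (id in ids) map[id] <- find(id)
  out <- superpixels
  pos <- superpixels > 0L
  out[pos] <- map[superpixels[pos]]
  out
}
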