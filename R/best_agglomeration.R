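# Best agglomeration A*: the grouping of superpixels obtained by assigning
# each superpixel to the gold-standard segment with which it shares the most
# overlap.  This is the best segmentation achievable given the superpixels,
# and the reference the active training loop terminates against.

#' Best agglomeration of superpixels given a gold standard
#'
#' Assigns every superpixel to the gold segment of maximal pixel overlap
#' (ties broken by the smallest gold id, with a message).  Gold label 0 is
#' ignored as unlabeled; a superpixel overlapping only gold-0 pixels is
#' placed in a dedicated "unassigned" group (group id 0) with a warning.
#'
#' @param superpixels,gold label volumes of identical shape; `gold` must
#'   contain at least one positive segment.
#' @return an object of class `"best_agglomeration"`: list with `assignment`
#'   (named integer vector, superpixel id -> group id) and `groups` (list of
#'   integer superpixel-id vectors, named by group id).
#' @export
best_agglomeration <- function(superpixels, gold) {
  superpixels <- validate_label_volume(superpixels)
  gold <- validate_label_volume(gold)
  if (!identical(dim(superpixels), dim(gold))) {
    stop("superpixels and gold must have the same shape", call. = FALSE)
  }
  pos <- superpixels > 0L & gold > 0L
  sp <- superpixels[pos]
  gd <- gold[pos]
  sp_ids <- segment_ids(superpixels)
  gd_ids <- sort(unique(gd))
  ov <- Matrix::sparseMatrix(i = match(sp, sp_ids), j = match(gd, gd_ids),
                             x = 1, dims = c(length(sp_ids), length(gd_ids)))
  ov <- as.matrix(ov)
  assignment <- integer(length(sp_ids))
  names(assignment) <- sp_ids
  ties <- 0L
  for (i in seq_along(sp_ids)) {
    row <- ov[i, ]
    if (all(row == 0)) { assignment[i] <- 0L; next }
    best <- which(row == max(row))
    if (length(best) > 1L) ties <- ties + 1L
    assignment[i] <- gd_ids[best[1L]]          # columns ascend: smallest id wins
  }
  if (ties > 0L) {
    message(sprintf("best_agglomeration: %d overlap tie(s) broken by smallest gold id", ties))
  }
  if (any(assignment == 0L)) {
    warning(sprintf(
      "%d superpixel(s) overlap only unlabeled (gold 0) pixels; placed in 'unassigned' group 0",
      sum(assignment == 0L)), call. = FALSE)
  }
  groups <- lapply(split(sp_ids, assignment), as.integer)
  structure(list(assignment = assignment, groups = groups),
            class = "best_agglomeration")
}

#' @export
print.best_agglomeration <- function(x, ...) {
  cat(sprintf("<best_agglomeration> %d superpixels -> %d group(s)\n",
              length(x$assignment), length(x$groups)))
  invisible(x)
}

#' Segmentation induced by a best agglomeration
#'
#' @param ref a [best_agglomeration()].
#' @param superpixels the superpixel volume it was computed from.
#' @return label volume where every superpixel carries its group id.
#' @export
apply_agglomeration <- function(ref, superpixels) {
  superpixels <- validate_label_volume(superpixels)
  ids <- as.integer(names(ref$assignment))
  map <- integer(max(ids))
  map[ids] <- ref$assignment
  out <- superpixels
  pos <- superpixels > 0L
  out[pos] <- map[superpixels[pos]]
  out
}

# Groups of a reference, split into connected components of the given
# (initial) RAG.  A gold segment's superpixels need not be mutually
# reachable by merges; an agglomeration can only realize the
# connectivity-refined grouping, so the training epoch terminates against
# this refinement.  Labels are unaffected: two components of one group are
# never adjacent, so no edge distinguishes the two references.
refine_reference <- function(ref, rag) {
  sp_ids <- as.integer(names(ref$assignment))
  vid <- integer(max(sp_ids))
  vid[sp_ids] <- seq_along(sp_ids)
  ed <- rag_edges(rag)
  g <- igraph::graph_from_edgelist(cbind(vid[ed$u], vid[ed$v]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(sp_ids) - igraph::vcount(g)))
  assignment <- integer(length(sp_ids))
  names(assignment) <- sp_ids
  next_id <- 0L
  for (grp in ref$groups) {
    sub <- igraph::induced_subgraph(g, vid[grp])
    comp <- igraph::components(sub)$membership
    assignment[as.character(grp)] <- next_id + as.integer(comp)
    next_id <- next_id + max(comp)
  }
  groups <- lapply(split(sp_ids, assignment), as.integer)
  structure(list(assignment = assignment, groups = groups),
            class = "best_agglomeration")
}

# Reference group ids touched by a node.  For a volume reference, the set of
# positive gold labels under the node's pixels; for a best agglomeration,
# the groups of its member superpixels.
.node_groups <- function(rag, id, ref) {
  if (inherits(ref, "best_agglomeration")) {
    unique(ref$assignment[as.character(node_superpixels(rag, id))])
  } else {
    g <- ref[node_pixels(rag, id)]
    unique(g[g > 0L])
  }
}

#' Merge label of an edge against a reference
#'
#' `+1` ("should merge") when both regions lie inside one common reference
#' group, `-1` ("don't merge") when each region lies inside a different
#' group, and `0` ("don't know") when either region mixes groups (or touches
#' none, for a gold-volume reference).
#'
#' @param rag a `"rag"`.
#' @param u,v ids of two adjacent nodes.
#' @param ref a [best_agglomeration()] or a gold label volume.
#' @return integer `+1`, `-1` or `0`.
#' @export
merge_label <- function(rag, u, v, ref) {
  .get_edge(rag, u, v)
  gu <- .node_groups(rag, u, ref)
  gv <- .node_groups(rag, v, ref)
  if (length(gu) != 1L || length(gv) != 1L) return(0L)
  if (gu == gv) 1L else -1L
}
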