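# Region adjacency graph over a superpixel label volume, with merge semantics
# and boundary bookkeeping.  The graph is an environment (reference
# semantics): merges mutate it in place, as agglomeration requires.
#
# Per-node and per-edge statistics are derived from stored pixel-index sets
# and cached; a node's cache is invalidated whenever the node changes (its
# `version` stamp increments), so cached values are always exactly equal to a
# recompute from raw pixels.

#' Build a region adjacency graph from superpixels and cue maps
#'
#' One node per distinct non-zero superpixel id; an edge between two nodes
#' exactly when a pixel of one region is face-adjacent (4-connectivity in 2D,
#' 6-connectivity in 3D) to a pixel of the other.  Each edge records its
#' boundary pixel set; each node its member pixels.
#'
#' @param superpixels label volume (see [validate_label_volume()]).
#' @param cues list of numeric arrays in `[0, 1]`, same shape as
#'   `superpixels`; at least one.  The first channel is conventionally the
#'   boundary probability map.
#' @param bins histogram bin count over `[0, 1]` used for all cached
#'   histograms (default 25; 10 and 25 are the conventional choices).
#' @param boundary_mode `"thick"` (default): the boundary of an edge is the
#'   two-sided set of region pixels with a face neighbor in the other region.
#'   `"ridge"`: for superpixel maps with 0-labeled watershed lines, the
#'   boundary is the set of 0-pixels face-adjacent to both regions (edges are
#'   also created through such line pixels; direct-contact pairs fall back to
#'   thick pixels).
#' @param clamp if `TRUE`, cue values outside `[0, 1]` are clamped into
#'   range; if `FALSE` (default) they are an error.
#' @param midlevel keep 2D mid-level bookkeeping (pixel coordinates for
#'   second moments and convex hulls).  2D only; off by default to bound
#'   memory in 3D.
#' @return an object of class `"rag"`.
#' @export
build_rag <- function(superpixels, cues, bins = 25L,
                      boundary_mode = c("thick", "ridge"),
                      clamp = FALSE, midlevel = FALSE) {
  boundary_mode <- match.arg(boundary_mode)
  superpixels <- validate_label_volume(superpixels)
  if (!is.list(cues) || length(cues) == 0L) {
    stop("`cues` must be a non-empty list of arrays", call. = FALSE)
  }
  d <- dim(superpixels)
  cues <- lapply(seq_along(cues), function(i) {
    ci <- cues[[i]]
    if (!identical(dim(ci), d)) {
      stop(sprintf("cue %d shape does not match the superpixel volume", i),
           call. = FALSE)
    }
    ci <- as.numeric(ci)
    if (any(ci < 0 | ci > 1)) {
      if (clamp) ci <- pmin(1, pmax(0, ci))
      else stop(sprintf("cue %d has values outside [0, 1] (set clamp = TRUE to clamp)", i),
                call. = FALSE)
    }
    array(ci, dim = d)
  })
  if (midlevel && length(d) != 2L) {
    stop("midlevel bookkeeping is 2D-only", call. = FALSE)
  }

  rag <- new.env(parent = emptyenv())
  class(rag) <- "rag"
  rag$labels <- superpixels
  rag$dims <- d
  rag$cues <- cues
  rag$n_channels <- length(cues)
  rag$cfg <- list(bins = as.integer(bins), boundary_mode = boundary_mode,
                  midlevel = midlevel)
  rag$nodes <- new.env(parent = emptyenv())
  rag$edges <- new.env(parent = emptyenv())
  rag$adj <- new.env(parent = emptyenv())

  ids <- segment_ids(superpixels)
  pos <- which(superpixels > 0L)
  by_id <- split(pos, superpixels[pos])
  for (id_chr in names(by_id)) {
    id <- as.integer(id_chr)
    rag$nodes[[id_chr]] <- list(sp = id, px = as.integer(by_id[[id_chr]]),
                                version = 0L, stats = NULL, coords = NULL)
    rag$adj[[id_chr]] <- integer(0)
  }
  rag$n_nodes <- length(ids)

  np <- neighbor_pairs(d)
  la <- superpixels[np$a]
  lb <- superpixels[np$b]

  add_boundary <- function(u, v, pix) {
    key <- edge_key(u, v)
    e <- rag$edges[[key]]
    if (is.null(e)) {
      rag$edges[[key]] <- list(bpx = pix, stats = NULL)
      cu <- as.character(u); cv <- as.character(v)
      rag$adj[[cu]] <- c(rag$adj[[cu]], v)
      rag$adj[[cv]] <- c(rag$adj[[cv]], u)
    } else {
      e$bpx <- c(e$bpx, pix)
      rag$edges[[key]] <- e
    }
  }

  # direct face contact between two positive labels
  contact <- which(la != lb & la > 0L & lb > 0L)
  if (length(contact)) {
    cu <- pmin(la[contact], lb[contact])
    cv <- pmax(la[contact], lb[contact])
    pair_key <- paste0(cu, "|", cv)
    for (grp in split(seq_along(contact), pair_key)) {
      i <- contact[grp]
      u <- min(la[i[1L]], lb[i[1L]]); v <- max(la[i[1L]], lb[i[1L]])
      add_boundary(u, v, c(np$a[i], np$b[i]))
    }
  }

  if (boundary_mode == "ridge") {
    # edges bridged by 0-labeled line pixels; the line pixel is the boundary
    zi <- which((la == 0L) != (lb == 0L))
    if (length(zi)) {
      zero_px <- ifelse(la[zi] == 0L, np$a[zi], np$b[zi])
      lab_px  <- ifelse(la[zi] == 0L, lb[zi], la[zi])
      for (grp in split(seq_along(zi), zero_px)) {
        labs <- sort(unique(lab_px[grp]))
        if (length(labs) < 2L) next
        p0 <- zero_px[grp[1L]]
        for (i in seq_len(length(labs) - 1L)) {
          for (j in seq.int(i + 1L, length(labs))) {
            add_boundary(labs[i], labs[j], p0)
          }
        }
      }
    }
  }

  # deduplicate boundary pixels collected from multiple contact faces
  for (key in ls(rag$edges)) {
    e <- rag$edges[[key]]
    e$bpx <- sort(unique(e$bpx))
    rag$edges[[key]] <- e
  }
  for (id in ls(rag$adj)) rag$adj[[id]] <- sort(unique(rag$adj[[id]]))
  rag
}

#' @export
print.rag <- function(x, ...) {
  cat(sprintf("<rag> %s | %d nodes, %d edges, %d cue channel(s), %s boundaries\n",
              paste(x$dims, collapse = "x"), x$n_nodes,
              length(ls(x$edges)), x$n_channels, x$cfg$boundary_mode))
  invisible(x)
}

#' Node ids of a RAG
#' @param rag a `"rag"`.
#' @return sorted integer vector of current node ids.
#' @export
rag_nodes <- function(rag) sort(as.integer(ls(rag$nodes)))

#' Edge list of a RAG
#' @param rag a `"rag"`.
#' @return tibble with integer columns `u < v`, one row per edge.
#' @export
rag_edges <- function(rag) {
  keys <- ls(rag$edges)
  if (length(keys) == 0L) return(tibble::tibble(u = integer(0), v = integer(0)))
  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- tibble::tibble(u = vapply(parts, function(p) as.integer(p[1L]), 1L),
                        v = vapply(parts, function(p) as.integer(p[2L]), 1L))
  dplyr::arrange(out, .data$u, .data$v)
}

#' @rdname rag_edges
#' @param u,v node ids.
#' @export
has_edge <- function(rag, u, v) !is.null(rag$edges[[edge_key(u, v)]])

#' Neighbors of a node
#' @inheritParams has_edge
#' @param id node id.
#' @return integer vector of adjacent node ids.
#' @export
rag_neighbors <- function(rag, id) {
  a <- rag$adj[[as.character(id)]]
  if (is.null(a)) stop(sprintf("node %d not in graph", id), call. = FALSE)
  a
}

.get_node <- function(rag, id) {
  nd <- rag$nodes[[as.character(id)]]
  if (is.null(nd)) stop(sprintf("node %d not in graph", id), call. = FALSE)
  nd
}

.get_edge <- function(rag, u, v) {
  e <- rag$edges[[edge_key(u, v)]]
  if (is.null(e)) {
    stop(sprintf("no edge between nodes %d and %d", u, v), call. = FALSE)
  }
  e
}

#' Boundary pixels of an edge
#'
#' The set of pixels realizing the boundary between two adjacent regions.  In
#' `"thick"` mode these are the pixels of either region with at least one
#' face neighbor in the other region; in `"ridge"` mode, the 0-labeled line
#' pixels adjacent to both.
#'
#' @inheritParams has_edge
#' @return integer matrix of pixel coordinates, one row per pixel, columns in
#'   (z,)y,x axis order (1-based); the linear indices are attached as
#'   attribute `"index"`.
#' @export
boundary_pixels <- function(rag, u, v) {
  e <- .get_edge(rag, u, v)
  out <- arrayInd(e$bpx, rag$dims)
  attr(out, "index") <- e$bpx
  out
}

# ---- cached statistics ----------------------------------------------------

# Histogram + moment summary of cue values at `px` for every channel.
.compute_stats <- function(rag, px) {
  bins <- rag$cfg$bins
  lapply(rag$cues, function(cue) {
    v <- cue[px]
    n <- length(v)
    bin <- pmin(bins, floor(v * bins) + 1L)
    m <- mean(v)
    ctr <- v - m
    list(n = n,
         hist = tabulate(bin, nbins = bins),
         mean = m,
         cm2 = mean(ctr^2), cm3 = mean(ctr^3), cm4 = mean(ctr^4))
  })
}

# Per-channel stats of a node, cached until the node's version changes.
node_stats <- function(rag, id) {
  key <- as.character(id)
  nd <- .get_node(rag, id)
  if (is.null(nd$stats)) {
    nd$stats <- .compute_stats(rag, nd$px)
    rag$nodes[[key]] <- nd
  }
  nd$stats
}

# Per-channel stats of an edge's boundary pixels, cached until the boundary
# pixel set changes.
edge_stats <- function(rag, u, v) {
  key <- edge_key(u, v)
  e <- .get_edge(rag, u, v)
  if (is.null(e$stats)) {
    e$stats <- .compute_stats(rag, e$bpx)
    rag$edges[[key]] <- e
  }
  e$stats
}

node_pixels <- function(rag, id) .get_node(rag, id)$px

node_version <- function(rag, id) .get_node(rag, id)$version

node_superpixels <- function(rag, id) .get_node(rag, id)$sp

# Pixel coordinates of a 2D node (rows = pixels, cols = y,x), cached.
node_coords <- function(rag, id) {
  key <- as.character(id)
  nd <- .get_node(rag, id)
  if (is.null(nd$coords)) {
    nd$coords <- arrayInd(nd$px, rag$dims)
    rag$nodes[[key]] <- nd
  }
  nd$coords
}

# ---- merging --------------------------------------------------------------

#' Merge two adjacent nodes
#'
#' Replaces `u` and `v` by a single node (id `min(u, v)`) whose pixel set is
#' the union; the merged node's neighbor set is the union of the two neighbor
#' sets, and edges to a common neighbor pool their boundary pixels.  The
#' `(u, v)` boundary is absorbed into the merged interior.
#'
#' @inheritParams has_edge
#' @return the surviving node id, invisibly.
#' @export
merge_nodes <- function(rag, u, v) {
  if (u == v) stop("cannot merge a node with itself", call. = FALSE)
  .get_edge(rag, u, v)      # errors if missing
  w <- min(u, v); l <- max(u, v)
  cw <- as.character(w); cl <- as.character(l)
  nw <- rag$nodes[[cw]]; nl <- rag$nodes[[cl]]

  nw$sp <- c(nw$sp, nl$sp)
  nw$px <- c(nw$px, nl$px)
  nw$version <- nw$version + 1L
  nw$stats <- NULL
  nw$coords <- NULL
  rag$nodes[[cw]] <- nw

  rm(list = edge_key(u, v), envir = rag$edges)
  for (x in rag$adj[[cl]]) {
    if (x == w) next
    cx <- as.character(x)
    el <- rag$edges[[edge_key(l, x)]]
    rm(list = edge_key(l, x), envir = rag$edges)
    kw <- edge_key(w, x)
    ew <- rag$edges[[kw]]
    if (is.null(ew)) {
      rag$edges[[kw]] <- list(bpx = el$bpx, stats = NULL)
      rag$adj[[cw]] <- c(rag$adj[[cw]], x)
      rag$adj[[cx]] <- c(rag$adj[[cx]], w)
    } else {
      # a pixel can border both u and v; union, not concatenation
      rag$edges[[kw]] <- list(bpx = sort(unique(c(ew$bpx, el$bpx))), stats = NULL)
    }
    rag$adj[[cx]] <- setdiff(rag$adj[[cx]], l)
  }
  rag$adj[[cw]] <- sort(setdiff(rag$adj[[cw]], c(w, l)))
  rm(list = cl, envir = rag$nodes)
  rm(list = cl, envir = rag$adj)
  rag$n_nodes <- rag$n_nodes - 1L
  invisible(w)
}

#' Segmentation induced by the current RAG
#'
#' Relabels every pixel of the original superpixel volume with the id of the
#' node that now owns its superpixel.  Pixels labeled 0 in the input stay 0.
#'
#' @param rag a `"rag"`, possibly after merges.
#' @param original the superpixel volume the RAG was built from; defaults to
#'   the volume stored in the RAG.
#' @return a label volume.
#' @export
current_segmentation <- function(rag, original = NULL) {
  original <- if (is.null(original)) rag$labels else validate_label_volume(original)
  ids <- segment_ids(original)
  map <- integer(max(ids))
  for (key in ls(rag$nodes)) {
    nd <- rag$nodes[[key]]
    map[nd$sp] <- as.integer(key)
  }
  missing <- ids[map[ids] == 0L]
  if (length(missing)) {
    stop(sprintf("superpixel id(s) absent from the RAG: %s",
                 paste(utils::head(missing, 5L), collapse = ", ")), call. = FALSE)
  }
  out <- original
  pos <- original > 0L
  out[pos] <- map[original[pos]]
  out
}
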