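# Seeded synthetic phantoms: gold segmentations (Voronoi mosaics in 2D/3D,
# tube bundles in 3D), noisy cue maps, and watershed superpixels.  These
# stand in for a proofread gold standard plus pixel-classifier probability
# maps, so the whole pipeline is testable without any external data.  Every
# draw is fixed by the spec's seed.

#' Phantom specification
#'
#' @param shape image shape, (y, x) or (z, y, x).
#' @param n_segments number of gold segments (>= 2).
#' @param geometry `"voronoi"` (2D/3D mosaic of convex-ish cells) or
#'   `"tubes"` (3D only: elongated processes spanning the z extent,
#'   mimicking neurites).
#' @param blur_sigma Gaussian blur applied to the boundary indicator when
#'   synthesizing the boundary cue (pixels).
#' @param noise_sd marginal standard deviation of the additive Gaussian cue
#'   noise.
#' @param noise_corr correlation length (Gaussian smoothing sigma, pixels)
#'   of the boundary-cue noise field.  Pixel-classifier errors are blotchy,
#'   not iid speckle: errors correlated at about the receptive-field scale
#'   survive region averaging, as real probability-map errors do.  0 = iid.
#' @param superpixel_spacing marker grid spacing for the watershed
#'   oversegmentation (smaller = denser superpixels).
#' @param n_texture_cues number of per-segment "texture" cue channels
#'   (region-intensity channels that give the moment/JSD features signal).
#' @param seed integer seed fixing every random draw.
#' @return a `"phantom_spec"` list.
#' @export
phantom_spec <- function(shape = c(128L, 128L), n_segments = 12L,
                         geometry = c("voronoi", "tubes"), blur_sigma = 1,
                         noise_sd = 0.1, noise_corr = 4, superpixel_spacing = 8L,
                         n_texture_cues = 1L, seed = 0L) {
  geometry <- match.arg(geometry)
  shape <- as.integer(shape)
  stopifnot(length(shape) %in% c(2L, 3L), all(shape > 0L), n_segments >= 1L,
            blur_sigma >= 0, noise_sd >= 0, noise_corr >= 0,
            superpixel_spacing >= 2L)
  if (geometry == "tubes" && length(shape) != 3L) {
    stop("tube phantoms are 3D-only", call. = FALSE)
  }
  structure(list(shape = shape, n_segments = as.integer(n_segments),
                 geometry = geometry, blur_sigma = blur_sigma,
                 noise_sd = noise_sd, noise_corr = noise_corr,
                 superpixel_spacing = as.integer(superpixel_spacing),
                 n_texture_cues = as.integer(n_texture_cues),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# coordinates of all pixels as a matrix, one row per linear index
.grid_coords <- function(dims) arrayInd(seq_len(prod(dims)), dims)

#' Generate a gold-standard phantom segmentation
#'
#' `"voronoi"`: each pixel takes the label of the nearest of `n_segments`
#' uniformly drawn sites (Euclidean distance, ties to the smallest site
#' id), giving a partition into connected convex cells.  `"tubes"`: sites
#' random-walk through z, so each z-slice is a Voronoi mosaic of slowly
#' drifting centers — elongated processes spanning the full z extent.
#'
#' @param spec a [phantom_spec()].
#' @return a label volume with ids `1..n_segments`.
#' @export
make_gold <- function(spec) {
  d <- spec$shape
  if (spec$geometry == "voronoi" && spec$n_segments < 2L) {
    stop("voronoi phantoms need n_segments >= 2", call. = FALSE)
  }
  if (prod(d) < spec$n_segments) stop("more segments than pixels", call. = FALSE)
  set.seed(spec$seed)
  if (spec$geometry == "voronoi") {
    sites <- sapply(d, function(dk) stats::runif(spec$n_segments, 0.5, dk + 0.5))
    if (is.null(dim(sites))) sites <- matrix(sites, nrow = spec$n_segments)
    co <- .grid_coords(d)
    d2 <- matrix(0, nrow(co), spec$n_segments)
    for (k in seq_along(d)) {
      d2 <- d2 + outer(co[, k], sites[, k], `-`)^2
    }
    lab <- max.col(-d2, ties.method = "first")
    return(validate_label_volume(array(as.integer(lab), dim = d)))
  }
  # tubes: centers drift in (y, x) along z
  nz <- d[1L]; ny <- d[2L]; nx <- d[3L]
  cy <- stats::runif(spec$n_segments, 1, ny)
  cx <- stats::runif(spec$n_segments, 1, nx)
  out <- array(0L, dim = d)
  co <- .grid_coords(c(ny, nx))
  step_sd <- max(0.5, min(ny, nx) / 40)
  for (z in seq_len(nz)) {
    d2 <- outer(co[, 1L], cy, `-`)^2 + outer(co[, 2L], cx, `-`)^2
    out[z, , ] <- array(as.integer(max.col(-d2, ties.method = "first")),
                        dim = c(ny, nx))
    cy <- pmin(ny, pmax(1, cy + stats::rnorm(spec$n_segments, 0, step_sd)))
    cx <- pmin(nx, pmax(1, cx + stats::rnorm(spec$n_segments, 0, step_sd)))
  }
  validate_label_volume(.repair_connectivity(out))
}

# Center drift can momentarily split a region; reassign every non-dominant
# connected component to its most frequent neighboring segment until each
# segment is a single component.
.repair_connectivity <- function(lab) {
  np <- neighbor_pairs(dim(lab))
  repeat {
    fixed <- TRUE
    for (id in segment_ids(lab)) {
      comp <- mask_components(lab == id)
      if (max(comp) <= 1L) next
      fixed <- FALSE
      sizes <- tabulate(comp[comp > 0L])
      for (c_id in setdiff(seq_len(max(comp)), which.max(sizes))) {
        inc <- comp == c_id
        touch <- c(lab[np$b[inc[np$a]]], lab[np$a[inc[np$b]]])
        touch <- touch[touch != id & touch > 0L]
        if (length(touch) == 0L) next
        lab[inc] <- as.integer(names(sort(table(touch), decreasing = TRUE))[1L])
      }
    }
    if (fixed) return(lab)
  }
}

#' Synthesize a boundary-probability cue from a gold segmentation
#'
#' The two-sided boundary indicator of the gold segments, Gaussian-blurred
#' by `blur_sigma`, plus seeded Gaussian noise of sd `noise_sd`, clipped to
#' `[0, 1]`.  At `noise_sd = 0` the cue is exactly the blurred indicator.
#'
#' @param gold a gold label volume.
#' @param spec a [phantom_spec()] (blur, noise and seed are read from it).
#' @param seed_offset offset added to the spec seed so different channels
#'   draw independent noise.
#' @return numeric array in `[0, 1]`, same shape as `gold`.
#' @export
make_boundary_cue <- function(gold, spec, seed_offset = 1L) {
  b <- gauss_blur(boundary_indicator(gold) * 1.0, spec$blur_sigma)
  b <- pmin(1, b)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed + seed_offset)
    w <- array(stats::rnorm(length(b)), dim = dim(gold))
    corr <- spec$noise_corr %||% 0
    if (corr > 0) w <- gauss_blur(w, corr)
    w <- w / stats::sd(w) * spec$noise_sd     # restore the marginal sd
    b <- b + w
  }
  array(pmin(1, pmax(0, b)), dim = dim(gold))
}

#' Synthesize a per-segment texture cue
#'
#' Each gold segment receives a constant intensity drawn uniformly in
#' `[0.15, 0.85]`, plus Gaussian noise, clipped to `[0, 1]`.  Emulates
#' cytoplasm/texture channels so histogram, moment and Jensen-Shannon
#' features carry region-identity signal.
#'
#' @inheritParams make_boundary_cue
#' @export
make_texture_cue <- function(gold, spec, seed_offset = 2L) {
  set.seed(spec$seed + seed_offset)
  ids <- segment_ids(gold)
  level <- stats::runif(max(ids), 0.15, 0.85)
  tx <- level[gold]
  tx <- tx + stats::rnorm(length(tx), 0, spec$noise_sd)
  array(pmin(1, pmax(0, tx)), dim = dim(gold))
}

# backward/forward neighbor table: row = pixel linear index, one column per
# signed axis direction, 0 where out of bounds
neighbor_matrix <- function(dims) {
  n <- prod(dims)
  nd <- length(dims)
  idx <- array(seq_len(n), dims)
  out <- matrix(0L, n, 2L * nd)
  for (k in seq_len(nd)) {
    args_a <- rep(list(quote(expr = )), nd)
    args_b <- args_a
    args_a[[k]] <- seq_len(dims[k] - 1L)
    args_b[[k]] <- seq.int(2L, dims[k])
    ia <- as.integer(do.call(`[`, c(list(idx), args_a, list(drop = FALSE))))
    ib <- as.integer(do.call(`[`, c(list(idx), args_b, list(drop = FALSE))))
    out[ib, 2L * k - 1L] <- ia   # backward neighbor
    out[ia, 2L * k] <- ib        # forward neighbor
  }
  out
}

# Seeded watershed by level-quantized immersion: the cue is discretized into
# `n_levels` equal-width levels and marker fronts flood outward level by
# level, claiming adjacent unlabeled pixels whose level has been reached.
# Fully vectorized; deterministic (fixed axis-direction priority); every
# region is connected and no line pixels remain.
watershed_flood <- function(cue, marker_idx, dims, n_levels = 256L) {
  n <- prod(dims)
  nbm <- neighbor_matrix(dims)
  nbm[nbm == 0L] <- n + 1L           # dummy neighbor that is never labeled
  lab <- integer(n + 1L)
  lab[marker_idx] <- seq_along(marker_idx)
  lvl <- pmin(n_levels, floor(as.numeric(cue) * n_levels) + 1L)
  cuev <- c(as.numeric(cue), Inf)      # dummy neighbor is never preferred
  for (l in seq_len(n_levels)) {
    if (!any(lab[seq_len(n)] == 0L)) break
    repeat {
      # claim every reached pixel from its steepest-descent labeled
      # neighbor: the front coming up its own side of a ridge wins
      nb_lab <- matrix(lab[nbm], n)
      nb_val <- matrix(cuev[nbm], n)
      nb_val[nb_lab == 0L] <- Inf
      sel <- lab[seq_len(n)] == 0L & lvl <= l & rowSums(nb_lab > 0L) > 0L
      if (!any(sel)) break
      pick <- max.col(-nb_val[sel, , drop = FALSE], ties.method = "first")
      lab[which(sel)] <- nb_lab[cbind(which(sel), pick)]
    }
  }
  array(lab[seq_len(n)], dim = dims)
}

#' Watershed superpixels of a cue map
#'
#' Marker-based watershed oversegmentation: markers are placed at the
#' lowest-cue pixel of every cell of a `superpixel_spacing`-spaced grid
#' (after a light smoothing of the cue), then flooded in increasing cue
#' order.  Every marker yields one connected superpixel; no watershed-line
#' (0) pixels are produced.
#'
#' @param cue numeric array in `[0, 1]` (typically the boundary cue).
#' @param spec a [phantom_spec()].
#' @return a label volume of superpixels numbered from 1.
#' @export
make_superpixels <- function(cue, spec) {
  d <- dim(cue)
  smooth <- gauss_blur(cue, 1)
  co <- .grid_coords(d)
  cell <- rep(0L, nrow(co))
  mult <- 1L
  for (k in seq_along(d)) {
    ck <- (co[, k] - 1L) %/% spec$superpixel_spacing
    cell <- cell + ck * mult
    mult <- mult * (1L + max(ck))
  }
  ord <- order(cell, smooth, seq_len(nrow(co)))
  first <- ord[!duplicated(cell[ord])]
  marker_idx <- sort(first)
  watershed_flood(cue, marker_idx, d)
}

#' Generate a complete phantom
#'
#' Gold segmentation, boundary cue (channel 1), optional texture cues, and
#' watershed superpixels, all from one seeded spec.
#'
#' @param spec a [phantom_spec()].
#' @return list with `gold`, `cues` (list of arrays), `superpixels`, and
#'   the `spec`.
#' @export
make_phantom <- function(spec) {
  gold <- make_gold(spec)
  cues <- list(make_boundary_cue(gold, spec, seed_offset = 1L))
  if (spec$n_texture_cues > 0L) {
    for (j in seq_len(spec$n_texture_cues)) {
      cues[[j + 1L]] <- make_texture_cue(gold, spec, seed_offset = 1L + j)
    }
  }
  sp <- make_superpixels(cues[[1L]], spec)
  list(gold = gold, cues = cues, superpixels = sp, spec = spec)
}

#' Pinch-error phantom (2D dumbbell)
#'
#' Two lobes joined by a one-pixel-wide neck form a single gold segment
#' against a background segment: the dominant failure mode of boundary-sum
#' features, where the evidence for a true merge lives on a tiny boundary.
#'
#' @param shape 2D shape (y, x).
#' @param lobe half-width of each lobe.
#' @return a gold label volume with segment 1 = dumbbell, 2 = background.
#' @export
make_pinch_gold <- function(shape = c(32L, 64L), lobe = 10L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L)
  cy <- (shape[1L] + 1L) %/% 2L
  x1 <- shape[2L] %/% 4L
  x2 <- shape[2L] - x1
  out <- array(2L, dim = shape)
  co <- .grid_coords(shape)
  in1 <- abs(co[, 1L] - cy) <= lobe & abs(co[, 2L] - x1) <= lobe
  in2 <- abs(co[, 1L] - cy) <= lobe & abs(co[, 2L] - x2) <= lobe
  neck <- co[, 1L] == cy & co[, 2L] > x1 & co[, 2L] < x2
  out[in1 | in2 | neck] <- 1L
  out
}
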