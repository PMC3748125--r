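# Feature map phi(G, u, v): the fixed-length descriptor of a candidate merge,
# assembled from cached region/edge statistics.  The schema is a function of
# the configuration only, never of region sizes, so one classifier serves
# every scale of the agglomeration.

#' Feature configuration
#'
#' @param bins histogram bin count over `[0, 1]` (10 or 25 conventionally;
#'   other values are permitted).  Must match the bin count of the RAG the
#'   features are computed on.
#' @param n_quantiles 3 (quartiles) or 9 (deciles), interpolated from the
#'   histogram bins.
#' @param use_moments include mean and central moments 2..4 plus their
#'   absolute between-region differences.
#' @param use_jsd include the Jensen-Shannon divergence (base-2 logs, hence
#'   in `[0, 1]` bits) between the two region histograms.
#' @param use_midlevel_2d include 2D orientation and convex-hull features
#'   (requires a RAG built with `midlevel = TRUE`).
#' @param channels integer vector of cue channels to use; `NULL` = all.
#' @return a `"feature_config"` list.
#' @export
feature_config <- function(bins = 25L, n_quantiles = 3L, use_moments = TRUE,
                           use_jsd = TRUE, use_midlevel_2d = FALSE,
                           channels = NULL) {
  if (!n_quantiles %in% c(3L, 9L)) {
    stop("n_quantiles must be 3 or 9", call. = FALSE)
  }
  if (!bins %in% c(10L, 25L)) {
    message(sprintf("note: non-standard histogram bin count %d", bins))
  }
  structure(list(bins = as.integer(bins), n_quantiles = as.integer(n_quantiles),
                 use_moments = isTRUE(use_moments), use_jsd = isTRUE(use_jsd),
                 use_midlevel_2d = isTRUE(use_midlevel_2d),
                 channels = if (is.null(channels)) NULL else as.integer(channels)),
            class = "feature_config")
}

quantile_probs <- function(cfg) {
  if (cfg$n_quantiles == 3L) c(0.25, 0.5, 0.75) else seq(0.1, 0.9, by = 0.1)
}

# Quantiles by linear interpolation of cumulative histogram bin mass.  Bin i
# covers ((i-1)/B, i/B]; the CDF is piecewise linear through the bin edges.
hist_quantiles <- function(counts, probs) {
  B <- length(counts)
  n <- sum(counts)
  Fi <- c(0, cumsum(counts) / n)
  vapply(probs, function(p) {
    i <- which(Fi >= p - 1e-15)[1L] - 1L   # bin index whose upper edge reaches p
    if (i < 1L) i <- 1L
    lo <- Fi[i]; hi <- Fi[i + 1L]
    frac <- if (hi > lo) (p - lo) / (hi - lo) else 1
    (i - 1L + frac) / B
  }, numeric(1L))
}

#' Histogram-derived features of one statistics block
#'
#' Quantiles (by linear interpolation of the cumulative histogram), pixel
#' count, mean, and central moments 2..4 of one channel of a region or
#' boundary statistics block.
#'
#' @param stats one channel's cached statistics (as produced internally by a
#'   RAG): a list with `n`, `hist`, `mean`, `cm2`, `cm3`, `cm4`.
#' @param cfg a [feature_config()].
#' @return named numeric vector.
#' @export
histogram_features <- function(stats, cfg = feature_config()) {
  if (is.null(stats$n) || stats$n == 0L) stop("empty statistics block", call. = FALSE)
  probs <- quantile_probs(cfg)
  q <- hist_quantiles(stats$hist, probs)
  names(q) <- paste0("q", sub("^0\\.", "", formatC(probs, format = "g")))
  c(q, n = stats$n, mean = stats$mean,
    cm2 = stats$cm2, cm3 = stats$cm3, cm4 = stats$cm4)
}

#' Jensen-Shannon divergence between two histograms
#'
#' Base-2 logarithms, so the value is in `[0, 1]` bits; symmetric; 0 iff the
#' normalized histograms are equal.
#'
#' @param p,q non-negative count or probability vectors of equal length.
#' @return divergence in bits.
#' @export
jsd <- function(p, q) {
  stopifnot(length(p) == length(q))
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  ent <- function(x) {
    x <- x[x > 0]
    -sum(x * log2(x))
  }
  d <- ent(m) - (ent(p) + ent(q)) / 2
  max(0, d)   # clip tiny negative rounding
}

# Ordered feature schema for a configuration and channel count; memoized,
# since it is consulted on every feature evaluation.
.schema_cache <- new.env(parent = emptyenv())

feature_schema <- function(cfg, n_channels, ndim = 2L) {
  key <- paste(cfg$bins, cfg$n_quantiles, cfg$use_moments, cfg$use_jsd,
               cfg$use_midlevel_2d, paste(cfg$channels, collapse = ","),
               n_channels, ndim, sep = "/")
  hit <- .schema_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- .feature_schema_build(cfg, n_channels, ndim)
  .schema_cache[[key]] <- out
  out
}

.feature_schema_build <- function(cfg, n_channels, ndim = 2L) {
  chans <- cfg$channels %||% seq_len(n_channels)
  probs <- quantile_probs(cfg)
  qn <- paste0("q", sub("^0\\.", "", formatC(probs, format = "g")))
  blk <- function(prefix, ch, source) {
    nm <- c(qn, if (cfg$use_moments) c("mean", "cm2", "cm3", "cm4") else "mean")
    tibble::tibble(name = paste0(prefix, "_ch", ch, "_", nm),
                   channel = ch, source = source)
  }
  rows <- list(tibble::tibble(
    name = c("n_edge", "n_small", "n_large"),
    channel = NA_integer_,
    source = c("edge", "region_u", "region_v")))
  for (ch in chans) {
    rows <- c(rows, list(blk("edge", ch, "edge"),
                         blk("small", ch, "region_u"),
                         blk("large", ch, "region_v")))
    if (cfg$use_moments) {
      rows <- c(rows, list(tibble::tibble(
        name = paste0("dcm", 2:4, "_ch", ch), channel = ch, source = "pair")))
    }
    if (cfg$use_jsd) {
      rows <- c(rows, list(tibble::tibble(
        name = paste0("jsd_ch", ch), channel = ch, source = "pair")))
    }
  }
  if (cfg$use_midlevel_2d && ndim == 2L) {
    rows <- c(rows, list(tibble::tibble(
      name = c("angle_axes", "angle_small_centroid", "angle_large_centroid",
               "convexity_small", "convexity_large", "convexity_union"),
      channel = NA_integer_, source = "pair")))
  }
  dplyr::bind_rows(rows)
}

.block_values <- function(stats, cfg) {
  probs <- quantile_probs(cfg)
  q <- hist_quantiles(stats$hist, probs)
  if (cfg$use_moments) c(q, stats$mean, stats$cm2, stats$cm3, stats$cm4)
  else c(q, stats$mean)
}

#' Feature vector of a candidate merge
#'
#' Concatenates, per cue channel: boundary (edge) histogram features, the two
#' region histogram features, absolute central-moment differences between the
#' regions, and the Jensen-Shannon divergence between their histograms; plus
#' pixel counts and, when enabled on 2D data, orientation and convex-hull
#' features.  The two region blocks are ordered smaller-region-first (ties by
#' node id) and differences are absolute, so the vector is exactly symmetric
#' in `u` and `v`.
#'
#' @param rag a `"rag"`; its histogram bin count must match `cfg$bins`.
#' @param u,v ids of two adjacent nodes.
#' @param cfg a [feature_config()].
#' @return named numeric vector following [feature_config()]'s schema.
#' @export
pair_features <- function(rag, u, v, cfg = feature_config()) {
  if (rag$cfg$bins != cfg$bins) {
    stop(sprintf("RAG histograms use %d bins but the feature config wants %d",
                 rag$cfg$bins, cfg$bins), call. = FALSE)
  }
  es <- edge_stats(rag, u, v)
  su <- node_stats(rag, u)
  sv <- node_stats(rag, v)
  nu <- su[[1L]]$n; nv <- sv[[1L]]$n
  if (nu > nv || (nu == nv && u > v)) {          # smaller region first
    tmp <- su; su <- sv; sv <- tmp
    tmp <- u; u <- v; v <- tmp
    tmp <- nu; nu <- nv; nv <- tmp
  }
  chans <- cfg$channels %||% seq_len(rag$n_channels)
  out <- c(es[[1L]]$n, nu, nv)
  for (ch in chans) {
    e1 <- es[[ch]]; u1 <- su[[ch]]; v1 <- sv[[ch]]
    out <- c(out, .block_values(e1, cfg), .block_values(u1, cfg),
             .block_values(v1, cfg))
    if (cfg$use_moments) {
      out <- c(out, abs(u1$cm2 - v1$cm2), abs(u1$cm3 - v1$cm3),
               abs(u1$cm4 - v1$cm4))
    }
    if (cfg$use_jsd) out <- c(out, jsd(u1$hist, v1$hist))
  }
  if (cfg$use_midlevel_2d && length(rag$dims) == 2L) {
    out <- c(out, orientation_features(rag, u, v), convex_hull_features(rag, u, v))
  }
  sch <- feature_schema(cfg, rag$n_channels, length(rag$dims))
  stats::setNames(out, sch$name)
}

# ---- 2D mid-level features ------------------------------------------------

# Principal-axis direction of a 2D point cloud from its second-moment
# (covariance) matrix; NULL when degenerate (single pixel or isotropic).
.principal_axis <- function(coords) {
  if (nrow(coords) < 2L) return(NULL)
  cv <- stats::cov(coords)
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[1L] - ev$values[2L] <= 1e-12 * max(ev$values[1L], 1e-300)) {
    return(NULL)   # isotropic: orientation undefined
  }
  ev$vectors[, 1L]
}

# Acute angle between two axial (undirected) unit directions, in [0, pi/2].
.axial_angle <- function(a, b) {
  d <- abs(sum(a * b))
  acos(max(-1, min(1, d)))
}

#' Orientation features of a candidate merge (2D)
#'
#' Estimates each region's orientation from its second-moment matrix and
#' returns three angles in `[0, pi/2]`: between the two principal
#' orientations, and between each orientation and the segment connecting the
#' two centroids.  Degenerate orientations (single-pixel or isotropic
#' regions) contribute the `pi/4` sentinel.
#'
#' @inheritParams pair_features
#' @return named numeric vector of three angles (radians).
#' @export
orientation_features <- function(rag, u, v) {
  if (length(rag$dims) != 2L) stop("orientation features are 2D-only", call. = FALSE)
  nu <- node_stats(rag, u)[[1L]]$n
  nv <- node_stats(rag, v)[[1L]]$n
  if (nu > nv || (nu == nv && u > v)) { tmp <- u; u <- v; v <- tmp }
  cu <- node_coords(rag, u)
  cv <- node_coords(rag, v)
  au <- .principal_axis(cu)
  av <- .principal_axis(cv)
  cen <- colMeans(cv) - colMeans(cu)
  axc <- if (sqrt(sum(cen^2)) > 1e-12) cen / sqrt(sum(cen^2)) else NULL
  sentinel <- pi / 4
  c(angle_axes = if (!is.null(au) && !is.null(av)) .axial_angle(au, av) else sentinel,
    angle_small_centroid = if (!is.null(au) && !is.null(axc)) .axial_angle(au, axc) else sentinel,
    angle_large_centroid = if (!is.null(av) && !is.null(axc)) .axial_angle(av, axc) else sentinel)
}

# Convex hull area of a pixel set, treating each pixel as a unit square (the
# hull is taken over the four pixel corners), so a solid rectangle has hull
# area exactly equal to its pixel count.
.hull_area <- function(coords) {
  pts <- rbind(cbind(coords[, 1L] - 0.5, coords[, 2L] - 0.5),
               cbind(coords[, 1L] - 0.5, coords[, 2L] + 0.5),
               cbind(coords[, 1L] + 0.5, coords[, 2L] - 0.5),
               cbind(coords[, 1L] + 0.5, coords[, 2L] + 0.5))
  h <- grDevices::chull(pts)
  if (length(h) < 3L) return(0)
  x <- pts[h, 1L]; y <- pts[h, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

#' Convex-hull (convexity) features of a candidate merge (2D)
#'
#' Ratios of region area to convex-hull area for each region and for their
#' union, as a measure of region convexity.  A convex region scores 1; hulls
#' degenerate to ratio 1 as a fallback.
#'
#' @inheritParams pair_features
#' @return named numeric vector of three ratios in `(0, 1]`.
#' @export
convex_hull_features <- function(rag, u, v) {
  if (length(rag$dims) != 2L) stop("convex-hull features are 2D-only", call. = FALSE)
  nu <- node_stats(rag, u)[[1L]]$n
  nv <- node_stats(rag, v)[[1L]]$n
  if (nu > nv || (nu == nv && u > v)) { tmp <- u; u <- v; v <- tmp; tmp <- nu; nu <- nv; nv <- tmp }
  cu <- node_coords(rag, u)
  cv <- node_coords(rag, v)
  ratio <- function(n, a) if (a > 0) min(1, n / a) else 1
  c(convexity_small = ratio(nu, .hull_area(cu)),
    convexity_large = ratio(nv, .hull_area(cv)),
    convexity_union = ratio(nu + nv, .hull_area(rbind(cu, cv))))
}
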