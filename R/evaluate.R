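# Region-based segmentation evaluation: variation of information (in bits)
# with its false-merge/false-split decomposition and per-segment breakdown,
# Rand and adjusted Rand indices, segmentation covering, and ODS/OIS
# threshold selection.  Everything is computed from one contingency table.

#' Contingency table of two segmentations
#'
#' Joint pixel counts over (candidate segment, reference segment).  Pixels
#' whose reference label is in `ignore_labels` (default `{0}`: unlabeled
#' gold) are excluded; a candidate label 0 is treated as a real segment
#' unless it is also listed there.
#'
#' @param s candidate label volume.
#' @param u reference label volume of identical shape.
#' @param ignore_labels reference labels to exclude.
#' @return object of class `"contingency_table"`: list with sparse count
#'   matrix `m` (rows = candidate segments, columns = reference segments),
#'   id vectors `s_ids`, `u_ids`, and total pixel count `n`.
#' @export
contingency <- function(s, u, ignore_labels = 0L) {
  s <- validate_label_volume(s, require_nonzero = FALSE)
  u <- validate_label_volume(u, require_nonzero = FALSE)
  if (!identical(dim(s), dim(u))) {
    stop("segmentations must have the same shape", call. = FALSE)
  }
  keep <- !(u %in% ignore_labels)
  if (!any(keep)) stop("no pixels remain after excluding ignored labels", call. = FALSE)
  sv <- s[keep]; uv <- u[keep]
  s_ids <- sort(unique(sv)); u_ids <- sort(unique(uv))
  m <- Matrix::sparseMatrix(i = match(sv, s_ids), j = match(uv, u_ids), x = 1,
                            dims = c(length(s_ids), length(u_ids)))
  structure(list(m = m, s_ids = s_ids, u_ids = u_ids, n = length(sv)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> %d candidate x %d reference segment(s), %d pixel(s)\n",
              length(x$s_ids), length(x$u_ids), x$n))
  invisible(x)
}

.as_table <- function(x, u = NULL, ignore_labels = 0L) {
  if (inherits(x, "contingency_table")) return(x)
  contingency(x, u, ignore_labels)
}

#' Variation of information between two segmentations
#'
#' VI(S, U) = H(S|U) + H(U|S) in bits (base-2 logs, 0 log 0 := 0): a metric
#' on partitions.  H(U|S), the "under" term, counts false merges (how much
#' reference information a candidate segment mixes); H(S|U), the "over"
#' term, counts false splits.  A total of 1 bit means each reference
#' segment is, on average, split into two equal fragments (or vice versa).
#'
#' @param x a [contingency()] table, or a candidate label volume.
#' @param u reference label volume (when `x` is a volume).
#' @param ignore_labels reference labels to exclude (when `x` is a volume).
#' @return object of class `"vi_report"`: list with `under`, `over`,
#'   `total` (bits) and per-segment `breakdown` (see [vi_breakdown()]).
#' @export
vi <- function(x, u = NULL, ignore_labels = 0L) {
  tab <- .as_table(x, u, ignore_labels)
  br <- vi_breakdown(tab)
  under <- sum(br$cand$p * br$cand$h)   # H(U|S): over candidate segments
  over <- sum(br$ref$p * br$ref$h)      # H(S|U): over reference segments
  structure(list(under = under, over = over, total = under + over,
                 breakdown = br), class = "vi_report")
}

#' @export
print.vi_report <- function(x, ...) {
  cat(sprintf("<vi_report> total %.4f bits = under (false merge) %.4f + over (false split) %.4f\n",
              x$total, x$under, x$over))
  invisible(x)
}

#' Per-segment VI breakdown
#'
#' Decomposes each VI term into per-segment contributions: the over term
#' H(S|U) equals the sum over reference segments u of p(u) H(S|U=u), and
#' symmetrically for candidate segments.  Plotting conditional entropy
#' against segment mass localizes which segments dominate the distance.
#'
#' @inheritParams vi
#' @return list of two tibbles (`ref`, `cand`), each with columns `id`
#'   (segment id), `p` (probability mass), `h` (conditional entropy, bits)
#'   and `contribution = p * h`, sorted by contribution descending.
#' @export
vi_breakdown <- function(x, u = NULL, ignore_labels = 0L) {
  tab <- .as_table(x, u, ignore_labels)
  m <- tab$m / tab$n
  one_side <- function(mm, ids) {
    mass <- Matrix::colSums(mm)
    h <- vapply(seq_along(ids), function(j) {
      p <- mm[, j] / mass[j]
      p <- p[p > 0]
      -sum(p * log2(p))
    }, numeric(1L))
    out <- tibble::tibble(id = ids, p = as.numeric(mass), h = h,
                          contribution = as.numeric(mass) * h)
    dplyr::arrange(out, dplyr::desc(.data$contribution), .data$id)
  }
  list(ref = one_side(m, tab$u_ids),           # H(S | U = u) per reference segment
       cand = one_side(Matrix::t(m), tab$s_ids))  # H(U | S = s) per candidate segment
}

#' Split-VI curve along a merge history
#'
#' One (false-merge, false-split) point per threshold: the under term
#' H(U|S) and over term H(S|U) of the cut segmentation against the gold
#' standard.  Merging can only move a point rightward (under grows or
#' holds) and downward (over shrinks or holds), mirroring the
#' precision-recall tradeoff.
#'
#' @param history a `"merge_history"` from [agglomerate()].
#' @param superpixels the superpixel volume the history started from.
#' @param gold reference label volume.
#' @param thresholds ascending numeric thresholds in `[0, 1]`.
#' @param ignore_labels reference labels to exclude.
#' @return tibble with columns `threshold`, `under`, `over`, `total`.
#' @export
split_vi_curve <- function(history, superpixels, gold,
                           thresholds = seq(0, 1, by = 0.1),
                           ignore_labels = 0L) {
  stopifnot(!is.unsorted(thresholds))
  rows <- lapply(thresholds, function(t) {
    seg <- cut_history(history, superpixels, t)
    v <- vi(seg, gold, ignore_labels)
    tibble::tibble(threshold = t, under = v$under, over = v$over, total = v$total)
  })
  dplyr::bind_rows(rows)
}

#' Rand index
#'
#' Proportion of pixel pairs on which the two segmentations agree (same
#' segment in both, or different segments in both), via pair counting on
#' the contingency table.
#'
#' @inheritParams vi
#' @return value in `[0, 1]`.
#' @export
rand_index <- function(x, u = NULL, ignore_labels = 0L) {
  tab <- .as_table(x, u, ignore_labels)
  n <- tab$n
  if (n < 2L) stop("Rand index needs at least 2 pixels", call. = FALSE)
  sum_a2 <- sum(Matrix::rowSums(tab$m)^2)
  sum_b2 <- sum(Matrix::colSums(tab$m)^2)
  sum_n2 <- sum(tab$m@x^2)
  1 - (0.5 * (sum_a2 + sum_b2) - sum_n2) / choose(n, 2)
}

#' Adjusted Rand error
#'
#' `1 - ARI`, where ARI is the Rand index corrected for chance under the
#' permutation model.  0 for identical segmentations; chance level is 1;
#' values above 1 are possible since ARI can be negative.
#'
#' @inheritParams vi
#' @return non-negative real.
#' @export
adjusted_rand_error <- function(x, u = NULL, ignore_labels = 0L) {
  tab <- .as_table(x, u, ignore_labels)
  n <- tab$n
  if (n < 2L) stop("adjusted Rand index needs at least 2 pixels", call. = FALSE)
  c2 <- function(v) sum(v * (v - 1) / 2)
  sum_nij <- c2(tab$m@x)
  sum_a <- c2(Matrix::rowSums(tab$m))
  sum_b <- c2(Matrix::colSums(tab$m))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (abs(maxi - expected) < .Machine$double.eps) {
    message("adjusted_rand_error: degenerate table (max index equals expectation); returning 0")
    return(0)
  }
  1 - (sum_nij - expected) / (maxi - expected)
}

#' Segmentation covering
#'
#' Size-weighted mean, over the segments of one partition, of the best
#' intersection-over-union with any segment of the other.
#'
#' @inheritParams vi
#' @param direction `"ref"`: cover the reference segments by candidate
#'   segments (the usual convention); `"cand"`: the transpose.
#' @return value in `[0, 1]`.
#' @export
covering <- function(x, u = NULL, direction = c("ref", "cand"),
                     ignore_labels = 0L) {
  direction <- match.arg(direction)
  tab <- .as_table(x, u, ignore_labels)
  m <- as.matrix(tab$m)
  if (direction == "cand") m <- t(m)
  a <- rowSums(m)   # candidate sizes (rows cover the columns)
  b <- colSums(m)   # covered segment sizes
  best <- vapply(seq_along(b), function(j) {
    iou <- m[, j] / (a + b[j] - m[, j])
    max(iou)
  }, numeric(1L))
  sum(b / tab$n * best)
}

#' ODS / OIS threshold selection
#'
#' ODS (optimal dataset scale): the single threshold optimizing the mean
#' score across images.  OIS (optimal image scale): the mean of each
#' image's own optimum.  OIS is always at least as good as ODS.  Ties are
#' broken by the smallest threshold.
#'
#' @param curves tibble with columns `image`, `threshold`, `score`; every
#'   image must share the same threshold grid.
#' @param direction `"min"` for distances (VI), `"max"` for similarities
#'   (Rand, covering).
#' @return list with `ods_threshold`, `ods_score`, `ois_score`.
#' @export
ods_ois <- function(curves, direction = c("min", "max")) {
  direction <- match.arg(direction)
  stopifnot(all(c("image", "threshold", "score") %in% names(curves)))
  if (nrow(curves) == 0L) stop("empty curves", call. = FALSE)
  grids <- split(curves$threshold, curves$image)
  g1 <- sort(grids[[1L]])
  if (!all(vapply(grids, function(g) identical(sort(g), g1), logical(1L)))) {
    stop("all images must share the same threshold grid", call. = FALSE)
  }
  sgn <- if (direction == "min") 1 else -1
  mean_by_t <- curves |>
    dplyr::group_by(.data$threshold) |>
    dplyr::summarise(score = mean(.data$score), .groups = "drop") |>
    dplyr::arrange(.data$threshold)
  i <- which.min(sgn * mean_by_t$score)   # first index wins ties: smallest t
  per_image <- curves |>
    dplyr::group_by(.data$image) |>
    dplyr::summarise(best = .data$score[which.min(sgn * .data$score)],
                     .groups = "drop")
  list(ods_threshold = mean_by_t$threshold[i],
       ods_score = mean_by_t$score[i],
       ois_score = mean(per_image$best))
}
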