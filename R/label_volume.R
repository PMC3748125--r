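#' Validate a label volume
#'
#' A label volume is a 2D matrix or 3D array of non-negative integer segment
#' ids with axes in (z,)y,x order.  Id 0 is reserved for background or
#' watershed-line pixels and owns no region; every positive id present must
#' label at least one pixel (trivially true for arrays).  Indexing follows R
#' convention (1-based).
#'
#' @param x matrix or 3D array of non-negative integers.
#' @param require_nonzero error if no positive label is present.
#' @return `x`, as an integer array, invisibly usable downstream.
#' @export
validate_label_volume <- function(x, require_nonzero = TRUE) {
  if (is.null(dim(x)) || !(length(dim(x)) %in% c(2L, 3L))) {
    stop("label volume must be a 2D matrix or 3D array", call. = FALSE)
  }
  if (any(is.na(x))) stop("label volume contains NA", call. = FALSE)
  if (any(x < 0)) stop("label volume contains negative ids", call. = FALSE)
  if (any(x != round(x))) stop("label volume ids must be integers", call. = FALSE)
  storage.mode(x) <- "integer"
  if (require_nonzero && !any(x > 0L)) {
    stop("label volume has no non-zero labels", call. = FALSE)
  }
  x
}

#' Distinct positive segment ids of a label volume
#' @param x label volume.
#' @return sorted integer vector of ids > 0.
#' @export
segment_ids <- function(x) sort(unique(as.integer(x[x > 0L])))

#' Renumber segments consecutively from 1
#'
#' Zero pixels are preserved.  Useful after cutting a merge history or
#' reading labels produced elsewhere.
#'
#' @param x label volume.
#' @return label volume with ids 1..k in order of first appearance of the
#'   sorted original ids.
#' @export
relabel_consecutive <- function(x) {
  x <- validate_label_volume(x, require_nonzero = FALSE)
  ids <- segment_ids(x)
  if (length(ids) == 0L) return(x)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  pos <- x > 0L
  x[pos] <- map[x[pos]]
  x
}

#' Tabulate segment sizes
#' @param x label volume.
#' @return tibble with columns `id` and `n_pixels`.
#' @export
segment_sizes <- function(x) {
  x <- validate_label_volume(x)
  tab <- table(as.integer(x[x > 0L]))
  tibble::tibble(id = as.integer(names(tab)), n_pixels = as.integer(tab))
}

# Boundary indicator: TRUE for pixels having a face neighbor with a different
# positive label (or any differing label when `include_zero`); used by the
# phantom generator and by boundary-mode bookkeeping.
boundary_indicator <- function(labels, include_zero = FALSE) {
  d <- dim(labels)
  np <- neighbor_pairs(d)
  la <- labels[np$a]
  lb <- labels[np$b]
  diffp <- la != lb
  if (!include_zero) diffp <- diffp & la > 0L & lb > 0L
  out <- array(FALSE, dim = d)
  out[np$a[diffp]] <- TRUE
  out[np$b[diffp]] <- TRUE
  out
}
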