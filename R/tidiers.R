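# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a VI report
#'
#' @param x a [vi()] report.
#' @param ... unused.
#' @return tibble with one row per segment and side: `side` (`"ref"` =
#'   false-split direction, `"cand"` = false-merge direction), `id`, `p`,
#'   `h`, `contribution`.
#' @export
tidy.vi_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$breakdown$ref, side = "ref", .before = 1L),
    dplyr::mutate(x$breakdown$cand, side = "cand", .before = 1L))
}

#' @rdname tidy.vi_report
#' @export
glance.vi_report <- function(x, ...) {
  tibble::tibble(vi_under = x$under, vi_over = x$over, vi_total = x$total,
                 n_ref_segments = nrow(x$breakdown$ref),
                 n_cand_segments = nrow(x$breakdown$cand))
}

#' Tidy a trained agglomeration fit
#'
#' @param x a [gala_train()] / [lash_train()] result.
#' @param ... unused.
#' @return the per-epoch example-count summary tibble.
#' @export
tidy.gala_fit <- function(x, ...) x$epoch_summary

#' @rdname tidy.gala_fit
#' @export
glance.gala_fit <- function(x, ...) {
  tibble::tibble(epochs = x$epochs,
                 n_examples = length(x$training_set$labels),
                 n_merge = sum(x$training_set$labels == 1L),
                 n_boundary = sum(x$training_set$labels == -1L),
                 label_source = x$label_source,
                 classifier = x$spec$type)
}

#' Tidy a learned merge policy
#'
#' @param x a `"classifier_policy"`.
#' @param ... unused.
#' @return for logistic backends, a tibble of ensemble-averaged
#'   coefficients (positive values push toward merging); for the forest
#'   backend, per-feature split counts (an importance proxy).
#' @export
tidy.classifier_policy <- function(x, ...) {
  if (x$spec$type == "forest") {
    used <- unlist(lapply(x$forest$trees, function(tr) tr$feat[!tr$leaf]))
    cnt <- tabulate(used, nbins = nrow(x$schema))
    return(tibble::tibble(term = x$schema$name, n_splits = cnt))
  }
  tibble::tibble(term = c("(Intercept)", x$schema$name),
                 estimate = rowMeans(x$beta))
}

#' @rdname tidy.classifier_policy
#' @export
glance.classifier_policy <- function(x, ...) {
  nf <- if (x$spec$type == "forest") length(x$forest$trees) else length(x$fits)
  tibble::tibble(classifier = x$spec$type, n_fits = nf,
                 n_features = nrow(x$schema), n_train = x$n_train,
                 seed = x$seed)
}
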