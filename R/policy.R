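# Merge policies.  A policy assigns every RAG edge a score in [0, 1], read
# as the estimated probability that the edge is a true boundary: low scores
# merge first, and agglomeration proceeds while score < threshold.  A
# learned policy is feature map + probabilistic classifier; its score is
# 1 - P(merge).

#' Classifier specification
#'
#' The classifier behind a learned policy is configuration, not code: any
#' backend exposing fit / predict-probability works.  Three are provided:
#' `"forest"` (default), a seeded random forest with probability averaging
#' (bagged CART trees, per-node feature subsampling, histogram splits);
#' `"bagged_logistic"`, a seeded bootstrap ensemble of ridge-penalized
#' logistic fits; and `"logistic"`, a single deterministic ridge-logistic
#' fit.
#'
#' @param type backend name.
#' @param n_bags ensemble size (trees, or logistic bags).
#' @param sample_fraction bootstrap sample fraction per logistic bag.
#' @param lambda ridge penalty (logistic backends).
#' @param alpha elastic-net mixing (0 = ridge; logistic backends).
#' @param mtry features tried per forest split (default `sqrt(p)`).
#' @param min_node minimum node size to attempt a forest split.
#' @param max_depth maximum forest tree depth.
#' @param n_bins quantile bins per feature for forest histogram splits.
#' @return a `"classifier_spec"` list.
#' @export
classifier_spec <- function(type = c("forest", "bagged_logistic", "logistic"),
                            n_bags = 30L, sample_fraction = 0.8,
                            lambda = 1e-4, alpha = 0, mtry = NULL,
                            min_node = 5L, max_depth = 12L, n_bins = 32L) {
  type <- match.arg(type)
  structure(list(type = type, n_bags = as.integer(n_bags),
                 sample_fraction = sample_fraction, lambda = lambda,
                 alpha = alpha, mtry = mtry, min_node = as.integer(min_node),
                 max_depth = as.integer(max_depth), n_bins = as.integer(n_bins)),
            class = "classifier_spec")
}

.fit_glmnet <- function(x, y01, spec) {
  # fit a short descending lambda path ending at the requested penalty;
  # predictions are taken at the requested value
  glmnet::glmnet(x, y01, family = "binomial", alpha = spec$alpha,
                 lambda = c(spec$lambda * c(100, 10), spec$lambda),
                 standardize = TRUE)
}

#' Fit a merge policy from a training set
#'
#' Trains the configured probabilistic classifier on the accumulated
#' `(feature, label)` examples and wraps it, together with the feature
#' schema/configuration that produced the features, into a policy whose
#' edge score is `1 - P(merge)`.
#'
#' @param train a `"training_set"` (from [flat_learning()], [gala_epoch()],
#'   [lash_epoch()] or [bind_training_sets()]).
#' @param spec a [classifier_spec()].
#' @param seed integer seed fixing every random draw of the fit.
#' @return an object of classes `"classifier_policy"`, `"merge_policy"`.
#' @export
fit_policy <- function(train, spec = classifier_spec(), seed = 0L) {
  stopifnot(inherits(train, "training_set"))
  x <- train$features
  y <- train$labels
  if (length(unique(y)) < 2L) {
    stop(paste0("training set contains a single class (all ", y[1L],
                "); provide a volume whose edges include both true and false merges"),
         call. = FALSE)
  }
  y01 <- as.integer(y == 1L)
  set.seed(seed)
  fits <- NULL
  forest <- NULL
  beta <- NULL
  if (spec$type == "forest") {
    forest <- rf_fit(x, y01, n_trees = spec$n_bags, mtry = spec$mtry,
                     min_node = spec$min_node, max_depth = spec$max_depth,
                     n_bins = spec$n_bins)
  } else {
    fits <- if (spec$type == "logistic") {
      list(.fit_glmnet(x, y01, spec))
    } else {
      lapply(seq_len(spec$n_bags), function(b) {
        idx <- sample.int(nrow(x), size = max(2L, round(spec$sample_fraction * nrow(x))),
                          replace = TRUE)
        # guarantee both classes in every bag
        if (length(unique(y01[idx])) < 2L) {
          idx <- c(idx, sample(which(y01 != y01[idx[1L]]), 1L))
        }
        .fit_glmnet(x[idx, , drop = FALSE], y01[idx], spec)
      })
    }
    # dense coefficients (intercept first) at the final (requested) lambda,
    # read off the fitted path directly: avoids predict.glmnet's per-call
    # overhead and its interpolation when the path stops early
    beta <- vapply(fits, function(f) {
      k <- ncol(f$beta)
      c(f$a0[k], as.numeric(f$beta[, k]))
    }, numeric(ncol(x) + 1L))
    if (is.null(dim(beta))) beta <- matrix(beta, ncol = length(fits))
  }
  structure(list(fits = fits, beta = beta, forest = forest, spec = spec,
                 feature_cfg = train$feature_cfg,
                 schema = train$schema,
                 label_source = train$label_source %||% "astar",
                 n_train = nrow(x), seed = seed,
                 version = "agglearn-policy-1"),
            class = c("classifier_policy", "merge_policy"))
}

#' Predicted merge probability for feature rows
#'
#' @param object a fitted `"classifier_policy"`.
#' @param features numeric matrix (rows = candidate merges) following the
#'   policy's feature schema.
#' @param ... unused.
#' @return numeric vector of `P(merge)` in `[0, 1]`.
#' @export
predict.classifier_policy <- function(object, features, ...) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  if (ncol(features) != nrow(object$schema)) {
    stop(sprintf("feature schema mismatch: policy expects %d features, got %d",
                 nrow(object$schema), ncol(features)), call. = FALSE)
  }
  if (object$spec$type == "forest") {
    return(rf_predict(object$forest, features))
  }
  eta <- cbind(1, features) %*% object$beta
  pmin(1, pmax(0, rowMeans(stats::plogis(eta))))
}

#' Mean-boundary baseline policy
#'
#' Scores an edge by the mean boundary-cue value over its boundary pixels —
#' the classic untrained agglomeration baseline.
#'
#' @param channel index of the boundary cue channel (default 1).
#' @return an object of classes `"mean_boundary_policy"`, `"merge_policy"`.
#' @export
mean_boundary_policy <- function(channel = 1L) {
  structure(list(channel = as.integer(channel)),
            class = c("mean_boundary_policy", "merge_policy"))
}

#' Random baseline policy
#'
#' Scores every query with an independent uniform draw; reproducible when
#' the surrounding loop seeds the RNG.  One of the initial-policy options
#' for the first training epoch.
#'
#' @return an object of classes `"random_policy"`, `"merge_policy"`.
#' @export
random_policy <- function() {
  structure(list(), class = c("random_policy", "merge_policy"))
}

#' Score RAG edges under a policy
#'
#' @param policy a `"merge_policy"`.
#' @param rag a `"rag"`.
#' @param edges two-column integer matrix of node-id pairs (one row per
#'   edge), or `NULL` for all current edges.
#' @return numeric vector of scores in `[0, 1]`, one per edge row.
#' @export
policy_score <- function(policy, rag, edges = NULL) {
  if (is.null(edges)) {
    ed <- rag_edges(rag)
    edges <- cbind(ed$u, ed$v)
  }
  if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2L)
  if (nrow(edges) == 0L) return(numeric(0))
  UseMethod("policy_score")
}

#' @export
policy_score.mean_boundary_policy <- function(policy, rag, edges = NULL) {
  vapply(seq_len(nrow(edges)), function(i) {
    edge_stats(rag, edges[i, 1L], edges[i, 2L])[[policy$channel]]$mean
  }, numeric(1L))
}

#' @export
policy_score.random_policy <- function(policy, rag, edges = NULL) {
  stats::runif(nrow(edges))
}

#' @export
policy_score.classifier_policy <- function(policy, rag, edges = NULL) {
  if (policy$feature_cfg$bins != rag$cfg$bins) {
    stop("policy feature schema mismatch: histogram bin counts differ", call. = FALSE)
  }
  expect_ch <- policy$feature_cfg$channels %||% NULL
  if (!is.null(expect_ch) && max(expect_ch) > rag$n_channels) {
    stop(sprintf("policy uses cue channel(s) %s but the RAG has %d channel(s)",
                 paste(expect_ch, collapse = ","), rag$n_channels), call. = FALSE)
  }
  fx <- t(vapply(seq_len(nrow(edges)), function(i) {
    pair_features(rag, edges[i, 1L], edges[i, 2L], policy$feature_cfg)
  }, numeric(nrow(policy$schema))))
  1 - predict(policy, fx)
}

#' @export
print.merge_policy <- function(x, ...) {
  if (inherits(x, "classifier_policy")) {
    nf <- if (x$spec$type == "forest") length(x$forest$trees) else length(x$fits)
    cat(sprintf("<classifier_policy> %s (%d fit(s)), %d features, %d training examples\n",
                x$spec$type, nf, nrow(x$schema), x$n_train))
  } else {
    cat(sprintf("<%s>\n", class(x)[1L]))
  }
  invisible(x)
}
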