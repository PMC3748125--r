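# Training-data generation: flat learning on the initial graph, the active
# agglomerative (GALA) epoch that labels candidate merges against the best
# agglomeration while merging only the true ones, and the LASH variant in
# which every proposed merge proceeds and labels are the sign of the
# Rand-index change.

#' Construct a training set from raw examples
#'
#' Mostly useful for experimenting with [fit_policy()] on hand-made data;
#' the pipeline builds its training sets via [flat_learning()],
#' [gala_epoch()] and [lash_epoch()].
#'
#' @param features numeric matrix, one row per example.
#' @param labels vector of `+1` / `-1` merge labels.
#' @param feature_cfg the [feature_config()] the features follow.
#' @param schema optional schema tibble; defaults to one synthesized from
#'   the matrix column names.
#' @return a `"training_set"`.
#' @export
training_set <- function(features, labels, feature_cfg = feature_config(),
                         schema = NULL) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels), all(labels %in% c(-1L, 1L)))
  if (is.null(schema)) {
    nm <- colnames(features) %||% paste0("f", seq_len(ncol(features)))
    schema <- tibble::tibble(name = nm, channel = NA_integer_, source = "pair")
  }
  prov <- tibble::tibble(epoch = 0L, u = NA_integer_, v = NA_integer_,
                         label = as.integer(labels), source = "manual",
                         kept = TRUE)
  structure(list(features = features, labels = as.integer(labels),
                 provenance = prov, feature_cfg = feature_cfg,
                 schema = schema, label_source = "manual"),
            class = "training_set")
}

.make_training_set <- function(feat_list, labels, prov, cfg, rag, label_source) {
  keep <- labels != 0L
  features <- if (any(keep)) do.call(rbind, feat_list[keep]) else
    matrix(numeric(0), 0L, 0L)
  ts <- structure(list(features = features, labels = as.integer(labels[keep]),
                       provenance = prov, feature_cfg = cfg,
                       schema = feature_schema(cfg, rag$n_channels, length(rag$dims)),
                       label_source = label_source),
                  class = "training_set")
  ts
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> %d example(s): %d merge (+1), %d boundary (-1)%s\n",
              length(x$labels), sum(x$labels == 1L), sum(x$labels == -1L),
              if (any(x$provenance$label == 0L))
                sprintf(" (+%d 'don't know' recorded, excluded)",
                        sum(x$provenance$label == 0L)) else ""))
  invisible(x)
}

#' Concatenate training sets
#'
#' Training data accumulated across epochs is pooled by concatenation; the
#' feature schemas must agree.
#'
#' @param ... `"training_set"` objects.
#' @return a `"training_set"`.
#' @export
bind_training_sets <- function(...) {
  sets <- list(...)
  sets <- sets[!vapply(sets, is.null, logical(1L))]
  stopifnot(length(sets) > 0L)
  base <- sets[[1L]]
  for (s in sets[-1L]) {
    if (!identical(s$schema$name, base$schema$name)) {
      stop("cannot bind training sets with different feature schemas", call. = FALSE)
    }
  }
  structure(list(
    features = do.call(rbind, lapply(sets, `[[`, "features")),
    labels = unlist(lapply(sets, `[[`, "labels")),
    provenance = dplyr::bind_rows(lapply(sets, `[[`, "provenance")),
    feature_cfg = base$feature_cfg, schema = base$schema,
    label_source = base$label_source), class = "training_set")
}

#' Flat learning: label every edge of the initial graph
#'
#' One training example per edge of the unmerged RAG whose label against the
#' reference is decisive (+1 or -1); no merges are performed.  This is the
#' bootstrap training set for the first active epoch.
#'
#' @param rag the initial (unmerged) `"rag"`.
#' @param ref a [best_agglomeration()] or a gold label volume.
#' @param cfg a [feature_config()].
#' @return a `"training_set"`.
#' @export
flat_learning <- function(rag, ref, cfg = feature_config()) {
  ed <- rag_edges(rag)
  n <- nrow(ed)
  labels <- integer(n)
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    labels[i] <- merge_label(rag, ed$u[i], ed$v[i], ref)
    if (labels[i] != 0L) feats[[i]] <- pair_features(rag, ed$u[i], ed$v[i], cfg)
  }
  if (!any(labels != 0L)) {
    stop("degenerate training volume: no edge has a decisive (+1/-1) label",
         call. = FALSE)
  }
  prov <- tibble::tibble(epoch = 0L, u = ed$u, v = ed$v, label = labels,
                         source = "flat", kept = labels != 0L)
  .make_training_set(feats, labels, prov, cfg, rag,
                     if (inherits(ref, "best_agglomeration")) "astar" else "gold")
}

#' One active (GALA) training epoch
#'
#' Repeatedly pops the policy's best remaining unseen edge, records the
#' feature vector and its label against the reference, merges the pair only
#' when the label is +1 (a refused edge is not revisited until one of its
#' endpoints changes), and terminates exactly when the RAG grouping equals
#' the connectivity-refined best agglomeration.  The RAG is mutated.
#'
#' @param rag a freshly built (unmerged) `"rag"` — each epoch restarts from
#'   the initial graph.
#' @param ref the [best_agglomeration()] the epoch terminates against.
#' @param policy the current `"merge_policy"` guiding the merge order.
#' @param cfg a [feature_config()].
#' @param epoch epoch index recorded in the provenance.
#' @param seed optional seed (only consulted by stochastic policies).
#' @param label_source `"astar"` (default): labels are computed against
#'   `ref`, which guarantees no "don't know" labels and clean termination.
#'   `"gold"`: labels are computed against the `gold` volume literally;
#'   0-labeled edges are recorded in the provenance but excluded from the
#'   returned examples, and the epoch ends when the queue empties.
#' @param gold gold label volume (required when `label_source = "gold"`).
#' @return a `"training_set"` for this epoch.
#' @export
gala_epoch <- function(rag, ref, policy, cfg = feature_config(), epoch = 1L,
                       seed = NULL, label_source = c("astar", "gold"),
                       gold = NULL) {
  label_source <- match.arg(label_source)
  if (label_source == "gold" && is.null(gold)) {
    stop("label_source = 'gold' requires the gold volume", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  refined <- refine_reference(ref, rag)
  target <- length(refined$groups)
  lref <- if (label_source == "gold") gold else refined

  ed <- rag_edges(rag)
  h <- heap_new(max(64L, 2L * nrow(ed)))
  sc <- policy_score(policy, rag, cbind(ed$u, ed$v))
  for (i in seq_len(nrow(ed))) {
    heap_push(h, sc[i], ed$u[i], ed$v[i],
              node_version(rag, ed$u[i]), node_version(rag, ed$v[i]))
  }

  feats <- list(); labels <- integer(0)
  pu <- integer(0); pv <- integer(0); pops <- 0L
  while (rag$n_nodes > target) {
    e <- heap_pop(h)
    if (is.null(e)) break
    if (!has_edge(rag, e$u, e$v)) next
    if (node_version(rag, e$u) != e$vu || node_version(rag, e$v) != e$vv) next
    pops <- pops + 1L
    lab <- merge_label(rag, e$u, e$v, lref)
    feats[[pops]] <- pair_features(rag, e$u, e$v, cfg)
    labels[pops] <- lab
    pu[pops] <- e$u; pv[pops] <- e$v
    if (lab == 1L) {
      w <- merge_nodes(rag, e$u, e$v)
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
  }
  if (label_source == "astar" && rag$n_nodes != target) {
    stop(sprintf(paste0(
      "gala_epoch: queue exhausted with %d nodes but %d reference groups ",
      "remain; the reference is inconsistent with the graph"),
      rag$n_nodes, target), call. = FALSE)
  }
  prov <- tibble::tibble(epoch = as.integer(epoch), u = pu, v = pv,
                         label = labels, source = "epoch", kept = labels != 0L)
  .make_training_set(feats, labels, prov, cfg, rag, label_source)
}

#' One LASH training epoch
#'
#' Follows the policy to completion: every proposed merge proceeds (while
#' its score is below `stop_threshold`), and each merge is labeled by the
#' sign of the change in Rand index against the gold standard that the
#' merge causes.  Zero-change merges are recorded but excluded.  Per the
#' LASH protocol, only the last epoch's data is used for the final fit (see
#' [lash_train()]).  The RAG is mutated.
#'
#' @inheritParams gala_epoch
#' @param gold gold label volume.
#' @param stop_threshold stop once the best remaining score reaches this
#'   value (default 1: merge to a single node).
#' @return a `"training_set"`.
#' @export
lash_epoch <- function(rag, gold, policy, cfg = feature_config(), epoch = 1L,
                       seed = NULL, stop_threshold = 1) {
  if (!is.null(seed)) set.seed(seed)
  gold <- validate_label_volume(gold)

  # per-node counts of positive gold labels under the node's pixels
  gcount <- new.env(parent = emptyenv())
  for (id in rag_nodes(rag)) {
    g <- gold[node_pixels(rag, id)]
    g <- g[g > 0L]
    gcount[[as.character(id)]] <- if (length(g)) table(g) else table(integer(0))
  }
  delta_pairs <- function(u, v) {
    cu <- gcount[[as.character(u)]]; cv <- gcount[[as.character(v)]]
    common <- intersect(names(cu), names(cv))
    same <- if (length(common)) sum(as.numeric(cu[common]) * as.numeric(cv[common])) else 0
    2 * same - sum(cu) * sum(cv)      # sign of the Rand-index change
  }

  ed <- rag_edges(rag)
  h <- heap_new(max(64L, 2L * nrow(ed)))
  sc <- policy_score(policy, rag, cbind(ed$u, ed$v))
  for (i in seq_len(nrow(ed))) {
    heap_push(h, sc[i], ed$u[i], ed$v[i],
              node_version(rag, ed$u[i]), node_version(rag, ed$v[i]))
  }
  feats <- list(); labels <- integer(0)
  pu <- integer(0); pv <- integer(0); pops <- 0L
  while (rag$n_nodes > 1L) {
    e <- heap_pop(h)
    if (is.null(e) || e$s >= stop_threshold) break
    if (!has_edge(rag, e$u, e$v)) next
    if (node_version(rag, e$u) != e$vu || node_version(rag, e$v) != e$vv) next
    pops <- pops + 1L
    d <- delta_pairs(e$u, e$v)
    lab <- if (d > 0) 1L else if (d < 0) -1L else 0L
    feats[[pops]] <- pair_features(rag, e$u, e$v, cfg)
    labels[pops] <- lab
    pu[pops] <- e$u; pv[pops] <- e$v
    cu <- gcount[[as.character(e$u)]]; cv <- gcount[[as.character(e$v)]]
    w <- merge_nodes(rag, e$u, e$v)
    merged <- table(rep(c(names(cu), names(cv)), c(cu, cv)))
    gcount[[as.character(w)]] <- merged
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
  prov <- tibble::tibble(epoch = as.integer(epoch), u = pu, v = pv,
                         label = labels, source = "lash", kept = labels != 0L)
  .make_training_set(feats, labels, prov, cfg, rag, "gold")
}

#' Train a merge policy by active agglomerative learning
#'
#' Computes the best agglomeration of the superpixels given the gold
#' standard, bootstraps with flat learning, then runs `epochs` active
#' epochs, each guided by the policy trained on all data accumulated so far
#' (data from all epochs is concatenated).
#'
#' @param superpixels,gold label volumes of identical shape.
#' @param cues list of cue arrays in `[0, 1]` (boundary probability first).
#' @param epochs number of active epochs (0 = flat learning only).
#' @param spec a [classifier_spec()].
#' @param cfg a [feature_config()]; its bin count is used to build the RAGs.
#' @param seed master seed; every stochastic step derives from it.
#' @param init_policy policy guiding epoch 1: `"flat"` (classifier fit on
#'   the flat-learning set; fastest convergence), `"mean"` (mean boundary)
#'   or `"random"`.
#' @param label_source see [gala_epoch()].
#' @param keep_flat retain the flat-learning examples in the concatenated
#'   training set (default `TRUE`).
#' @param boundary_mode,clamp passed to [build_rag()].
#' @return an object of class `"gala_fit"`: list with `policy` (the final
#'   [fit_policy()] result), `training_set`, `astar`, and a per-epoch
#'   `epoch_summary` tibble.
#' @export
gala_train <- function(superpixels, cues, gold, epochs = 5L,
                       spec = classifier_spec(), cfg = feature_config(),
                       seed = 0L, init_policy = c("flat", "mean", "random"),
                       label_source = c("astar", "gold"), keep_flat = TRUE,
                       boundary_mode = "thick", clamp = FALSE) {
  init_policy <- match.arg(init_policy)
  label_source <- match.arg(label_source)
  fresh_rag <- function() build_rag(superpixels, cues, bins = cfg$bins,
                                    boundary_mode = boundary_mode, clamp = clamp,
                                    midlevel = cfg$use_midlevel_2d)
  rag0 <- fresh_rag()
  astar <- best_agglomeration(superpixels, gold)
  flat_ref <- if (label_source == "gold") gold else astar
  flat_ts <- flat_learning(rag0, flat_ref, cfg)
  policy <- switch(init_policy,
                   flat = fit_policy(flat_ts, spec, seed = seed),
                   mean = mean_boundary_policy(),
                   random = random_policy())
  all_ts <- if (keep_flat) flat_ts else NULL
  summaries <- list(tibble::tibble(
    epoch = 0L, source = "flat", n_examples = length(flat_ts$labels),
    n_merge = sum(flat_ts$labels == 1L), n_boundary = sum(flat_ts$labels == -1L)))

  if (epochs == 0L && !keep_flat) all_ts <- flat_ts
  for (e in seq_len(epochs)) {
    rag <- fresh_rag()
    ts_e <- gala_epoch(rag, astar, policy, cfg, epoch = e, seed = seed + e,
                       label_source = label_source, gold = gold)
    all_ts <- if (is.null(all_ts)) ts_e else bind_training_sets(all_ts, ts_e)
    policy <- fit_policy(all_ts, spec, seed = seed)
    summaries[[length(summaries) + 1L]] <- tibble::tibble(
      epoch = e, source = "epoch", n_examples = length(ts_e$labels),
      n_merge = sum(ts_e$labels == 1L), n_boundary = sum(ts_e$labels == -1L))
  }
  if (epochs == 0L) {
    all_ts <- flat_ts
    policy <- if (inherits(policy, "classifier_policy")) policy
              else fit_policy(flat_ts, spec, seed = seed)
  }
  structure(list(policy = policy, training_set = all_ts, astar = astar,
                 epoch_summary = dplyr::bind_rows(summaries),
                 spec = spec, cfg = cfg, seed = seed,
                 label_source = label_source, epochs = as.integer(epochs)),
            class = "gala_fit")
}

#' @export
print.gala_fit <- function(x, ...) {
  cat(sprintf("<gala_fit> %d epoch(s), %d training example(s), labels vs %s\n",
              x$epochs, length(x$training_set$labels), x$label_source))
  print(x$epoch_summary)
  invisible(x)
}

#' Train a merge policy by the LASH protocol
#'
#' Runs `epochs` follow-to-completion epochs; each epoch's policy is fitted
#' on that epoch's data only (the protocol keeps only the last epoch's
#' training set).  Epoch 1 is guided by a flat-learning bootstrap policy.
#'
#' @inheritParams gala_train
#' @return an object of class `"gala_fit"` whose training set is the final
#'   epoch's.
#' @export
lash_train <- function(superpixels, cues, gold, epochs = 5L,
                       spec = classifier_spec(), cfg = feature_config(),
                       seed = 0L, boundary_mode = "thick", clamp = FALSE) {
  fresh_rag <- function() build_rag(superpixels, cues, bins = cfg$bins,
                                    boundary_mode = boundary_mode, clamp = clamp,
                                    midlevel = cfg$use_midlevel_2d)
  rag0 <- fresh_rag()
  astar <- best_agglomeration(superpixels, gold)
  flat_ts <- flat_learning(rag0, astar, cfg)
  policy <- fit_policy(flat_ts, spec, seed = seed)
  ts_e <- flat_ts
  summaries <- list()
  for (e in seq_len(epochs)) {
    rag <- fresh_rag()
    ts_e <- lash_epoch(rag, gold, policy, cfg, epoch = e, seed = seed + e)
    policy <- fit_policy(ts_e, spec, seed = seed)
    summaries[[e]] <- tibble::tibble(
      epoch = e, source = "lash", n_examples = length(ts_e$labels),
      n_merge = sum(ts_e$labels == 1L), n_boundary = sum(ts_e$labels == -1L))
  }
  structure(list(policy = policy, training_set = ts_e, astar = astar,
                 epoch_summary = dplyr::bind_rows(summaries),
                 spec = spec, cfg = cfg, seed = seed,
                 label_source = "gold", epochs = as.integer(epochs)),
            class = "gala_fit")
}
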