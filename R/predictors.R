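# The two scoring engines: the weighted-network inclined potential and
# the hybrid-property nearest-neighbour scorer, the 24-order ranking
# operator, and the overall dispatch rule.

new_potential_profile <- function(scores, ranking, method = NA_character_) {
  structure(
    list(scores = scores, ranking = ranking,
         unpredictable = all(scores == 0), method = method),
    class = "potential_profile"
  )
}

#' @export
print.potential_profile <- function(x, ...) {
  cat("<potential_profile>",
      if (!is.na(x$method)) paste0(" [", x$method, "]"),
      if (x$unpredictable) " (unpredictable: all-zero scores)", "\n",
      sep = "")
  top <- utils::head(x$ranking, 5L)
  cat("  top orders: ",
      paste(sprintf("%d:%s(%.4g)", seq_along(top), top, x$scores[top]),
            collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' Inclined potential of a network node towards each category
#'
#' The guilt-by-association score: for each functional category, the sum
#' of interaction confidence weights from the query to its annotated
#' neighbours carrying that category. Neighbours missing from the
#' annotation set contribute nothing; the query's own annotation is
#' never consulted (there is no self-interaction). A node whose
#' neighbours carry no annotations gets an all-zero profile, flagged
#' unpredictable.
#'
#' @param query Node identifier (must be in the network).
#' @param net A [weighted_network()].
#' @param ann An [annotation_set()] for the network's proteins.
#' @param tie,seed Passed to [rank_functions()].
#' @return A `potential_profile`: 24 nonnegative scores plus their
#'   descending ranking.
#' @export
inclined_potential <- function(query, net, ann, tie = c("index", "random"),
                               seed = NULL) {
  stopifnot(inherits(net, "weighted_network"), inherits(ann, "annotation_set"))
  nb <- net_neighbors(net, query)
  n_cat <- attr(ann, "n_categories")
  scores <- numeric(n_cat)
  for (i in seq_len(nrow(nb))) {
    fns <- ann[[nb$id[i]]]
    if (!is.null(fns)) {
      scores[fns] <- scores[fns] + nb$weight[i]
    }
  }
  prof <- rank_functions(scores, tie = tie, seed = seed)
  prof$method <- "network"
  prof
}

#' Arrange category scores into the 24-order ranking
#'
#' Applies the descending-order operator to a score vector: the
#' first-order prediction is the highest-scoring category, the
#' second-order the next, and so on through all 24. Tied scores break to
#' the ascending category index by default; `tie = "random"` instead
#' shuffles within each tie group under the given seed, mirroring the
#' random assignment used in the original protocol.
#'
#' @param scores Numeric vector of per-category scores (length 24 for
#'   the standard catalogue).
#' @param tie `"index"` (deterministic, default) or `"random"`.
#' @param seed Integer seed for `tie = "random"`.
#' @return A `potential_profile`.
#' @export
rank_functions <- function(scores, tie = c("index", "random"), seed = NULL) {
  tie <- match.arg(tie)
  stopifnot(is.numeric(scores), length(scores) >= 1L)
  if (tie == "index") {
    ranking <- order(scores, seq_along(scores), decreasing = c(TRUE, FALSE),
                     method = "radix")
  } else {
    shuffled <- if (is.null(seed)) {
      sample(seq_along(scores))
    } else {
      withr::with_seed(seed, sample(seq_along(scores)))
    }
    ranking <- shuffled[order(scores[shuffled], decreasing = TRUE)]
  }
  new_potential_profile(scores, ranking)
}

#' Cosine similarity between two feature vectors
#'
#' The inner product of the two vectors divided by the product of their
#' Euclidean norms. For nonnegative descriptors (all CTD/AAC features
#' are percentages) the value lies in `[0, 1]`.
#'
#' @param u,v Equal-length numeric vectors; if both are named, the names
#'   must agree in order.
#' @return Cosine similarity.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) {
    stop("cosine_similarity: vectors have different lengths", call. = FALSE)
  }
  if (!is.null(names(u)) && !is.null(names(v)) && !identical(names(u), names(v))) {
    stop("cosine_similarity: feature names disagree", call. = FALSE)
  }
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("cosine_similarity: zero-norm vector", call. = FALSE)
  }
  sum(u * v) / (nu * nv)
}

#' Hybrid-property nearest-neighbour potential
#'
#' Scores each functional category from cosine similarities between the
#' query's feature vector and the training proteins: by default the
#' score of category mu is the similarity of the most similar training
#' protein carrying mu (a pure nearest-neighbour generalisation to the
#' multi-label, 24-order setting); `agg = "sum"` instead sums the
#' similarities over all carriers. Categories carried by no training
#' protein score zero.
#'
#' @param query Numeric feature vector.
#' @param train_mat Training feature matrix (rownames are protein ids)
#'   with the same columns as `query`.
#' @param ann An [annotation_set()] covering the training rows.
#' @param agg `"max"` (default) or `"sum"` aggregation over carriers.
#' @param tie,seed Passed to [rank_functions()].
#' @return A `potential_profile`.
#' @export
hybrid_potential <- function(query, train_mat, ann, agg = c("max", "sum"),
                             tie = c("index", "random"), seed = NULL) {
  agg <- match.arg(agg)
  stopifnot(is.matrix(train_mat), nrow(train_mat) >= 1L,
            inherits(ann, "annotation_set"))
  sims <- similarity_to_set(query, train_mat)
  n_cat <- attr(ann, "n_categories")
  scores <- numeric(n_cat)
  ids <- rownames(train_mat)
  for (i in seq_along(ids)) {
    fns <- ann[[ids[i]]]
    if (is.null(fns) || is.na(sims[i])) next
    if (agg == "max") {
      scores[fns] <- pmax(scores[fns], sims[i])
    } else {
      scores[fns] <- scores[fns] + sims[i]
    }
  }
  prof <- rank_functions(scores, tie = tie, seed = seed)
  prof$method <- "hybrid"
  prof
}

# Cosine similarity of one query against every row of a matrix.
# Zero-norm rows give NA (excluded by callers); zero-norm query errors.
similarity_to_set <- function(query, mat) {
  nq <- sqrt(sum(query^2))
  if (nq == 0) {
    stop("cosine_similarity: zero-norm vector", call. = FALSE)
  }
  norms <- sqrt(rowSums(mat^2))
  sims <- as.numeric(mat %*% query) / (norms * nq)
  sims[norms == 0] <- NA_real_
  sims
}

#' Overall prediction with automatic method dispatch
#'
#' Applies the combined protocol: a query with usable interaction
#' information (a network node with at least one annotated neighbour) is
#' predicted by the network method; otherwise the sequence-based
#' hybrid-property method is used, provided a feature vector is
#' available. The returned profile is tagged with the method used.
#'
#' @param query Protein id.
#' @param net A [weighted_network()] or `NULL`.
#' @param ann An [annotation_set()] of known annotations (the query's
#'   own entry, if any, is never consulted).
#' @param query_features Numeric feature vector for the query, or `NULL`.
#' @param train_mat,train_ann Training matrix and annotations for the
#'   hybrid method (required when the network route is unavailable).
#' @param agg,tie,seed Scoring options, as in the two engines.
#' @return A `potential_profile` with `method` set to `"network"` or
#'   `"hybrid"`.
#' @export
predict_overall <- function(query, net = NULL, ann = NULL,
                            query_features = NULL, train_mat = NULL,
                            train_ann = NULL, agg = c("max", "sum"),
                            tie = c("index", "random"), seed = NULL) {
  use_network <- FALSE
  if (!is.null(net) && query %in% net$nodes && !is.null(ann)) {
    nb <- net_neighbors(net, query)
    annotated <- setdiff(intersect(nb$id, names(ann)), query)
    use_network <- length(annotated) > 0L
  }
  if (use_network) {
    ann_wo_query <- ann
    if (query %in% names(ann)) {
      sets <- unclass(ann)
      sets[[query]] <- NULL
      ann_wo_query <- annotation_set(sets,
                                     n_categories = attr(ann, "n_categories"))
    }
    return(inclined_potential(query, net, ann_wo_query, tie = tie,
                              seed = seed))
  }
  if (!is.null(query_features) && !is.null(train_mat) && !is.null(train_ann)) {
    keep <- setdiff(rownames(train_mat), query)
    if (length(keep) == 0L) {
      stop("query '", query, "': no training proteins for the hybrid method",
           call. = FALSE)
    }
    return(hybrid_potential(query_features,
                            train_mat[keep, , drop = FALSE],
                            train_ann, agg = agg, tie = tie, seed = seed))
  }
  stop("query '", query, "' is unpredictable: no annotated network ",
       "neighbours and no feature vector/training set supplied",
       call. = FALSE)
}
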