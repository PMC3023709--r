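# Mutual information, mRMR ranking and incremental feature selection
# (IFS) over the hybrid-property matrix.

#' Discretize a continuous feature matrix into state codes
#'
#' Mutual information is estimated from empirical cell frequencies, so
#' continuous features are first coded into a small number of states by
#' equal-frequency binning (default 3 bins). Bin edges are the
#' within-feature tertile quantiles; a value equal to an edge falls in
#' the upper bin. Features with fewer distinct quantile edges (constant
#' or near-constant features) collapse to fewer occupied states.
#'
#' @param mat Numeric feature matrix (proteins x features).
#' @param n_bins Number of states per feature (default 3).
#' @return List with `states` (integer matrix of codes starting at 0),
#'   and `edges` (list of numeric bin-edge vectors per feature).
#' @export
discretize_features <- function(mat, n_bins = 3L) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2L, n_bins >= 2L)
  probs <- seq_len(n_bins - 1L) / n_bins
  edges <- lapply(seq_len(ncol(mat)), function(j) {
    e <- unique(stats::quantile(mat[, j], probs, names = FALSE, type = 7))
    e[e > min(mat[, j])]  # an edge at the minimum would leave bin 0 empty
  })
  states <- vapply(seq_len(ncol(mat)), function(j) {
    findInterval(mat[, j], edges[[j]])
  }, integer(nrow(mat)))
  dimnames(states) <- dimnames(mat)
  list(states = states, edges = edges)
}

#' Binary label indicator matrix from an annotation set
#'
#' @param ann An [annotation_set()].
#' @param ids Row order; defaults to the annotation set's proteins.
#' @return Integer 0/1 matrix (proteins x categories).
#' @export
label_matrix <- function(ann, ids = names(ann)) {
  stopifnot(inherits(ann, "annotation_set"))
  n_cat <- attr(ann, "n_categories")
  m <- matrix(0L, nrow = length(ids), ncol = n_cat,
              dimnames = list(ids, paste0("cat", seq_len(n_cat))))
  for (i in seq_along(ids)) {
    m[i, ann[[ids[i]]]] <- 1L
  }
  m
}

#' Mutual information between two discrete vectors
#'
#' Plug-in estimate in nats: I(x; y) = sum over occupied cells of
#' p(x, y) log(p(x, y) / (p(x) p(y))), with empirical frequencies.
#' Always nonnegative and symmetric; zero when either vector is
#' constant.
#'
#' @param x,y Equal-length vectors of discrete state codes.
#' @return Nonnegative mutual information in nats.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) {
    stop("mutual_information: vectors have different lengths", call. = FALSE)
  }
  n <- length(x)
  stopifnot(n >= 1L)
  joint <- table(x, y) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  ratio <- joint / outer(px, py)
  occ <- joint > 0
  max(0, sum(joint[occ] * log(ratio[occ])))
}

# MI between every column of `a` and every column of `b` (matrices of
# state codes); returns a ncol(a) x ncol(b) matrix.
mi_cross <- function(a, b) {
  out <- matrix(0, ncol(a), ncol(b))
  for (i in seq_len(ncol(a))) {
    for (j in seq_len(ncol(b))) {
      out[i, j] <- mutual_information(a[, i], b[, j])
    }
  }
  out
}

#' Rank features by minimum-redundancy maximum-relevance (mRMR)
#'
#' Greedy forward selection: at each round the unselected feature
#' maximizing relevance minus redundancy is appended. Relevance of a
#' feature is its mean mutual information with the per-category binary
#' label indicators (reducing to plain single-target relevance when
#' there is one label column; `relevance = "max"` takes the maximum over
#' categories instead). Redundancy is the mean mutual information with
#' the already-selected features, zero in the first round. Score ties
#' break to the smallest feature index so the ranking is deterministic.
#'
#' @param states Integer matrix of discretized feature states
#'   (proteins x features), e.g. from [discretize_features()].
#' @param labels Integer 0/1 label matrix (proteins x categories), e.g.
#'   from [label_matrix()].
#' @param relevance Aggregation of per-category MI: `"mean"` (default)
#'   or `"max"`.
#' @return Data frame of class `ranked_features` with one row per
#'   selection round: `rank`, `feature` (column index), `name`,
#'   `relevance`, `redundancy`, `score` (relevance - redundancy).
#' @export
mrmr_rank <- function(states, labels, relevance = c("mean", "max")) {
  relevance <- match.arg(relevance)
  stopifnot(is.matrix(states), is.matrix(labels),
            nrow(states) == nrow(labels), ncol(states) >= 1L)
  M <- ncol(states)
  rel_by_cat <- mi_cross(states, labels)
  D <- if (relevance == "mean") rowMeans(rel_by_cat) else
    apply(rel_by_cat, 1L, max)
  # pairwise feature MI filled lazily: only rows for selected features
  pair_mi <- matrix(NA_real_, M, M)
  selected <- integer(0)
  rows <- vector("list", M)
  remaining <- seq_len(M)
  for (round in seq_len(M)) {
    if (length(selected)) {
      R <- colMeans(pair_mi[selected, remaining, drop = FALSE])
    } else {
      R <- numeric(length(remaining))
    }
    score <- D[remaining] - R
    pick_pos <- which.max(score)  # which.max returns the first (smallest index) maximum
    f <- remaining[pick_pos]
    rows[[round]] <- data.frame(
      rank = round, feature = f,
      name = if (!is.null(colnames(states))) colnames(states)[f] else
        paste0("f", f),
      relevance = D[f], redundancy = R[pick_pos],
      score = score[pick_pos], stringsAsFactors = FALSE)
    selected <- c(selected, f)
    remaining <- remaining[-pick_pos]
    if (length(remaining)) {
      for (g in remaining) {
        pair_mi[f, g] <- mutual_information(states[, f], states[, g])
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ranked_features", class(out))
  out
}

#' Write a ranked-feature table
#'
#' @param ranked A `ranked_features` data frame from [mrmr_rank()].
#' @param path Output path (tab-separated, with header).
#' @return `path`, invisibly.
#' @export
write_ranked_features <- function(ranked, path) {
  utils::write.table(ranked, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Incremental feature selection (IFS) over an mRMR ranking
#'
#' Evaluates the nested feature subsets S_1 subset S_2 subset ... formed
#' by prefixes of the mRMR selection order: for each prefix size the
#' proteins are recoded to that subset and the leave-one-out
#' nearest-neighbour jackknife is run, recording the first-order
#' accuracy. The resulting accuracy-versus-size curve is the IFS curve;
#' the optimal subset is the smallest prefix attaining the curve's
#' maximum (its apogee).
#'
#' @param mat Feature matrix (proteins x features, rownames are ids).
#' @param ann An [annotation_set()] covering every row.
#' @param ranked A `ranked_features` data frame from [mrmr_rank()]
#'   covering all columns of `mat`.
#' @param max_size Largest prefix size to evaluate (default: all).
#' @param agg,tie Passed to the nearest-neighbour jackknife
#'   ([jackknife_hybrid()]).
#' @return List of class `ifs_curve` with `curve` (data frame
#'   `size`, `lambda1`), `optimum` (smallest best prefix size) and
#'   `features` (column indices of the optimal subset, in rank order).
#' @export
ifs_select <- function(mat, ann, ranked, max_size = nrow(ranked),
                       agg = c("max", "sum"), tie = c("index", "random")) {
  agg <- match.arg(agg)
  tie <- match.arg(tie)
  stopifnot(is.matrix(mat), inherits(ann, "annotation_set"))
  order_idx <- ranked$feature
  stopifnot(length(order_idx) <= ncol(mat))
  max_size <- min(max_size, length(order_idx))
  lambda1 <- numeric(max_size)
  for (i in seq_len(max_size)) {
    sub <- mat[, order_idx[seq_len(i)], drop = FALSE]
    rep_i <- jackknife_hybrid(sub, ann, agg = agg, tie = tie)
    lambda1[i] <- rep_i$lambda[1]
  }
  optimum <- which.max(lambda1)  # first (smallest) maximizing prefix
  structure(
    list(curve = data.frame(size = seq_len(max_size), lambda1 = lambda1),
         optimum = optimum,
         features = order_idx[seq_len(optimum)]),
    class = "ifs_curve"
  )
}

#' @export
print.ifs_curve <- function(x, ...) {
  cat("<ifs_curve> ", nrow(x$curve), " prefix sizes; apogee at ",
      x$optimum, " features (first-order accuracy ",
      format(x$curve$lambda1[x$optimum], digits = 4), "%)\n", sep = "")
  invisible(x)
}

#' Write an IFS curve table
#'
#' @param ifs An `ifs_curve` from [ifs_select()].
#' @param path Output path (tab-separated: size, lambda1).
#' @return `path`, invisibly.
#' @export
write_ifs_curve <- function(ifs, path) {
  utils::write.table(ifs$curve, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
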