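# Jackknife harnesses for both predictors and the multi-order
# evaluation statistics: per-order accuracy Lambda_j, mean function
# count, and top-k coverage.

#' j-th order prediction accuracy
#'
#' The percent of proteins whose j-th ranked predicted category belongs
#' to their true function set.
#'
#' @param rankings Named list of ranking permutations (one per protein),
#'   or an integer matrix with one row per protein (rownames are ids).
#' @param truth An [annotation_set()] covering every ranked protein.
#' @param j Prediction order (1..24 for the standard catalogue).
#' @return Percent accuracy in `[0, 100]`.
#' @export
order_accuracy <- function(rankings, truth, j) {
  rankings <- as_ranking_matrix(rankings)
  n_cat <- attr(truth, "n_categories")
  if (length(j) != 1L || is.na(j) || j < 1L || j > n_cat) {
    stop("order j must be a single integer in 1..", n_cat, call. = FALSE)
  }
  ids <- rownames(rankings)
  hits <- vapply(seq_along(ids), function(i) {
    rankings[i, j] %in% truth[[ids[i]]]
  }, logical(1))
  100 * mean(hits)
}

as_ranking_matrix <- function(rankings) {
  if (is.matrix(rankings)) {
    stopifnot(!is.null(rownames(rankings)))
    return(rankings)
  }
  stopifnot(is.list(rankings), !is.null(names(rankings)))
  do.call(rbind, rankings)
}

#' Mean number of functions per protein
#'
#' The arithmetic mean of the true function-set sizes; its ceiling is
#' the order k at which top-k coverage is conventionally reported.
#'
#' @param truth An [annotation_set()].
#' @return The mean set size (a real in `[1, number of categories]`).
#' @export
mean_function_count <- function(truth) {
  stopifnot(inherits(truth, "annotation_set"), length(truth) >= 1L)
  mean(lengths(truth))
}

#' Top-k coverage probability
#'
#' The percent of proteins whose entire true function set is contained
#' in their top-k ranked categories. Non-decreasing in k and equal to
#' 100 at k = 24 whenever every protein has a full ranking.
#'
#' @inheritParams order_accuracy
#' @param k Number of leading orders to take.
#' @return Percent coverage in `[0, 100]`.
#' @export
coverage_probability <- function(rankings, truth, k) {
  rankings <- as_ranking_matrix(rankings)
  n_cat <- attr(truth, "n_categories")
  stopifnot(length(k) == 1L, k >= 1L, k <= n_cat)
  ids <- rownames(rankings)
  covered <- vapply(seq_along(ids), function(i) {
    all(truth[[ids[i]]] %in% rankings[i, seq_len(k)])
  }, logical(1))
  100 * mean(covered)
}

#' Expected first-order accuracy of a random guess
#'
#' With L categories and a mean of m true functions per protein, a
#' uniformly random first-order guess lands in the true set with
#' probability m / L; reported as a percent for comparison against
#' observed first-order accuracies.
#'
#' @param truth An [annotation_set()].
#' @return Percent chance rate.
#' @export
random_guess_rate <- function(truth) {
  100 * mean_function_count(truth) / attr(truth, "n_categories")
}

# Build an evaluation_report from per-protein rankings, truth and
# unpredictability flags. Unpredictable proteins stay in the
# denominator and count as misses at every order.
build_report <- function(rankings, truth, unpredictable) {
  ids <- rownames(rankings)
  n <- length(ids)
  n_cat <- attr(truth, "n_categories")
  stopifnot(length(unpredictable) == n)
  hit_mat <- matrix(FALSE, n, n_cat)
  for (i in seq_len(n)) {
    if (!unpredictable[i]) {
      hit_mat[i, ] <- rankings[i, ] %in% truth[[ids[i]]]
    }
  }
  n_correct <- colSums(hit_mat)
  lambda <- 100 * n_correct / n
  m_bar <- mean(lengths(unclass(truth)[ids]))
  k <- ceiling(m_bar)
  covered <- vapply(seq_len(n), function(i) {
    !unpredictable[i] && all(truth[[ids[i]]] %in% rankings[i, seq_len(k)])
  }, logical(1))
  detail <- data.frame(
    id = ids,
    n_true = lengths(unclass(truth)[ids]),
    first_order = rankings[, 1L],
    first_order_hit = hit_mat[, 1L],
    covered_at_k = covered,
    unpredictable = unpredictable,
    stringsAsFactors = FALSE
  )
  structure(
    list(lambda = lambda, n_total = n, n_correct = n_correct,
         mean_functions = m_bar, k = k, coverage = 100 * mean(covered),
         detail = detail,
         unpredictable_ids = ids[unpredictable]),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> N = ", x$n_total, "\n", sep = "")
  cat("  Lambda_1 = ", sprintf("%.2f%%", x$lambda[1]),
      ", Lambda_2 = ", sprintf("%.2f%%", x$lambda[2]),
      ", Lambda_3 = ", sprintf("%.2f%%", x$lambda[3]), "\n", sep = "")
  cat("  mean functions/protein = ", sprintf("%.2f", x$mean_functions),
      " => k = ", x$k, "; coverage Phi(k) = ",
      sprintf("%.1f%%", x$coverage), "\n", sep = "")
  if (length(x$unpredictable_ids)) {
    cat("  unpredictable (all-zero profile): ",
        length(x$unpredictable_ids), " protein(s)\n", sep = "")
  }
  invisible(x)
}

#' Write an evaluation report as tab-separated tables
#'
#' Writes the 24-row order/accuracy table followed by a '#'-commented
#' summary block, and optionally the per-protein detail table.
#'
#' @param report An `evaluation_report`.
#' @param path Output path for the order table.
#' @param detail_path Optional output path for the per-protein detail.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, detail_path = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  con <- file(path, "w")
  writeLines(c(
    paste0("# N\t", report$n_total),
    paste0("# mean_functions\t", format(report$mean_functions, digits = 10)),
    paste0("# k\t", report$k),
    paste0("# coverage_at_k\t", format(report$coverage, digits = 10)),
    paste0("# unpredictable\t", length(report$unpredictable_ids)),
    "order\tlambda"), con)
  writeLines(paste(seq_along(report$lambda),
                   format(report$lambda, digits = 10), sep = "\t"), con)
  close(con)
  if (!is.null(detail_path)) {
    utils::write.table(report$detail, detail_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Leave-one-out jackknife of the network method
#'
#' Each annotated network node is in turn held out: its own annotations
#' are hidden (its edges remain, since prediction only reads neighbour
#' labels), its inclined-potential profile is computed from the
#' remaining annotations and ranked, and the prediction is scored
#' against the hidden truth. Nodes whose profile is all-zero are flagged
#' unpredictable and count as misses at every order while staying in
#' the denominator.
#'
#' @param net A [weighted_network()].
#' @param ann An [annotation_set()]; only proteins that are network
#'   nodes with at least one edge are evaluated.
#' @param tie,seed Passed to [rank_functions()].
#' @return An `evaluation_report`.
#' @export
jackknife_network <- function(net, ann, tie = c("index", "random"),
                              seed = NULL) {
  tie <- match.arg(tie)
  stopifnot(inherits(net, "weighted_network"), inherits(ann, "annotation_set"))
  adj <- adjacency_list(net)
  degree <- vapply(adj, function(a) length(a$id), integer(1))
  eval_ids <- intersect(names(ann), names(degree)[degree > 0L])
  if (length(eval_ids) == 0L) {
    stop("no annotated nodes with edges to evaluate", call. = FALSE)
  }
  n_cat <- attr(ann, "n_categories")
  rankings <- matrix(0L, length(eval_ids), n_cat,
                     dimnames = list(eval_ids, NULL))
  unpredictable <- logical(length(eval_ids))
  for (i in seq_along(eval_ids)) {
    id <- eval_ids[i]
    nb <- adj[[id]]
    scores <- numeric(n_cat)
    for (j in seq_along(nb$id)) {
      if (nb$id[j] == id) next
      fns <- ann[[nb$id[j]]]
      if (!is.null(fns)) scores[fns] <- scores[fns] + nb$weight[j]
    }
    prof <- rank_functions(scores, tie = tie,
                           seed = if (!is.null(seed)) seed + i)
    rankings[i, ] <- prof$ranking
    unpredictable[i] <- prof$unpredictable
  }
  truth <- annotation_set(unclass(ann)[eval_ids], n_categories = n_cat)
  build_report(rankings, truth, unpredictable)
}

#' Leave-one-out jackknife of the hybrid-property method
#'
#' Each protein is in turn singled out and predicted by the
#' nearest-neighbour scorer from the remaining proteins, optionally
#' restricted to a feature subset (as during incremental feature
#' selection). Queries with a zero-norm vector under the chosen subset
#' are flagged unpredictable and count as misses.
#'
#' @param mat Feature matrix (proteins x features, rownames are ids).
#' @param ann An [annotation_set()] covering every row.
#' @param features Optional column subset (indices or names).
#' @param agg,tie,seed Passed to [hybrid_potential()].
#' @return An `evaluation_report`.
#' @export
jackknife_hybrid <- function(mat, ann, features = NULL,
                             agg = c("max", "sum"),
                             tie = c("index", "random"), seed = NULL) {
  agg <- match.arg(agg)
  tie <- match.arg(tie)
  stopifnot(is.matrix(mat), !is.null(rownames(mat)),
            inherits(ann, "annotation_set"))
  if (!is.null(features)) {
    mat <- mat[, features, drop = FALSE]
  }
  ids <- rownames(mat)
  missing <- setdiff(ids, names(ann))
  if (length(missing)) {
    stop("proteins without annotations: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(ids) < 2L) {
    stop("jackknife needs at least 2 proteins", call. = FALSE)
  }
  n_cat <- attr(ann, "n_categories")
  # precompute the full cosine similarity matrix once
  norms <- sqrt(rowSums(mat^2))
  sim <- tcrossprod(mat) / outer(norms, norms)
  sim[!is.finite(sim)] <- NA_real_
  label_mat <- label_matrix(ann, ids)
  rankings <- matrix(0L, length(ids), n_cat, dimnames = list(ids, NULL))
  unpredictable <- logical(length(ids))
  for (i in seq_along(ids)) {
    if (norms[i] == 0) {
      unpredictable[i] <- TRUE
      rankings[i, ] <- seq_len(n_cat)
      next
    }
    sims <- sim[i, -i]
    others <- ids[-i]
    scores <- numeric(n_cat)
    ok <- !is.na(sims)
    if (any(ok)) {
      lm_o <- label_mat[others[ok], , drop = FALSE]
      s_o <- sims[ok]
      for (mu in seq_len(n_cat)) {
        carriers <- lm_o[, mu] == 1L
        if (any(carriers)) {
          scores[mu] <- if (agg == "max") max(s_o[carriers]) else
            sum(s_o[carriers])
        }
      }
    }
    prof <- rank_functions(scores, tie = tie,
                           seed = if (!is.null(seed)) seed + i)
    rankings[i, ] <- prof$ranking
    unpredictable[i] <- prof$unpredictable
  }
  truth <- annotation_set(unclass(ann)[ids], n_categories = n_cat)
  build_report(rankings, truth, unpredictable)
}
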