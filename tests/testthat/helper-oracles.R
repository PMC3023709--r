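# Independent brute-force oracles used to cross-check the package's
# vectorized implementations, plus shared fixtures built in code.

# The printed 50-residue example sequence and its hydrophobicity
# translation, used as the exact-fidelity reference.
WORKED_SEQ <- "MSDKPDMAEIEKFSKETIEQEKQAGESTQEKNPLPMLLPATDKSKLKKTE"
WORKED_TRANSLATION <- "HNPPNPHNPHPPHNPPNHPPPPPNNPNNPPPPNHNHHHNNNPPNPHPPNP"

# Single-pass per-position oracle for the C/T/D statistics of a group
# string: plain loops, no shared code with the package internals.
oracle_ctd <- function(group_seq, groups) {
  chars <- strsplit(group_seq, "")[[1]]
  L <- length(chars)
  C <- sapply(groups, function(g) {
    n <- 0
    for (ch in chars) if (ch == g) n <- n + 1
    100 * n / L
  })
  pairs <- list()
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (i < j) pairs[[length(pairs) + 1]] <- c(groups[i], groups[j])
    }
  }
  K <- 0
  counts <- numeric(length(pairs))
  if (L > 1) {
    for (p in 1:(L - 1)) {
      a <- chars[p]; b <- chars[p + 1]
      if (a != b) {
        K <- K + 1
        for (q in seq_along(pairs)) {
          if ((a == pairs[[q]][1] && b == pairs[[q]][2]) ||
              (a == pairs[[q]][2] && b == pairs[[q]][1])) {
            counts[q] <- counts[q] + 1
          }
        }
      }
    }
  }
  Tv <- if (K == 0) counts else 100 * counts / K
  names(Tv) <- sapply(pairs, paste, collapse = "")
  D <- numeric(0)
  for (g in groups) {
    pos <- integer(0)
    for (p in seq_len(L)) if (chars[p] == g) pos <- c(pos, p)
    n <- length(pos)
    d <- if (n == 0) rep(0, 5) else {
      100 * c(pos[1], pos[ceiling(0.25 * n)], pos[ceiling(0.5 * n)],
              pos[ceiling(0.75 * n)], pos[n]) / L
    }
    names(d) <- paste0(g, ".", c(1, 25, 50, 75, 100))
    D <- c(D, d)
  }
  list(C = C, T = Tv, D = D, K = K)
}

# Brute-force inclined potential: per-neighbour, per-category double
# loop reading weights straight off the edge table.
oracle_inclined <- function(query, net, ann, n_cat = 24) {
  scores <- numeric(n_cat)
  e <- net$edges
  for (r in seq_len(nrow(e))) {
    other <- if (e$a[r] == query) e$b[r] else if (e$b[r] == query) e$a[r]
             else next
    fns <- ann[[other]]
    if (is.null(fns)) next
    for (mu in seq_len(n_cat)) {
      if (mu %in% fns) scores[mu] <- scores[mu] + e$weight[r]
    }
  }
  scores
}

# Direct-summation mutual information over explicit outcome pairs.
oracle_mi <- function(x, y) {
  n <- length(x)
  acc <- 0
  for (vx in unique(x)) {
    for (vy in unique(y)) {
      pxy <- sum(x == vx & y == vy) / n
      if (pxy > 0) {
        acc <- acc + pxy * log(pxy / ((sum(x == vx) / n) * (sum(y == vy) / n)))
      }
    }
  }
  acc
}

# Per-round exhaustive mRMR oracle: at every round scores every
# remaining feature from scratch with oracle_mi.
oracle_mrmr <- function(states, labels) {
  M <- ncol(states)
  D <- sapply(seq_len(M), function(f) {
    mean(sapply(seq_len(ncol(labels)),
                function(l) oracle_mi(states[, f], labels[, l])))
  })
  selected <- integer(0)
  remaining <- seq_len(M)
  for (round in seq_len(M)) {
    best <- NA; best_score <- -Inf
    for (f in remaining) {
      R <- if (length(selected) == 0) 0 else {
        mean(sapply(selected, function(s) oracle_mi(states[, f], states[, s])))
      }
      sc <- D[f] - R
      if (sc > best_score + 1e-12) {
        best <- f; best_score <- sc
      }
    }
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  selected
}

# Random annotated records carrying explicit per-residue annotation
# strings (so annotation-backed featurization needs no heuristic).
random_annotated_record <- function(id, len) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  s <- paste(sample(aa, len, replace = TRUE), collapse = "")
  protein_record(id, s, residue_annotations = list(
    secondary_structure = paste(sample(c("H", "E", "C"), len, replace = TRUE),
                                collapse = ""),
    solvent_accessibility = paste(sample(c("B", "X"), len, replace = TRUE),
                                  collapse = "")))
}

# Small deterministic annotation set whose mean set size is exactly m,
# built from sizes only (categories are arbitrary but valid).
annotation_set_with_mean <- function(sizes, n_categories = 24) {
  sets <- lapply(seq_along(sizes), function(i) seq_len(sizes[i]))
  names(sets) <- sprintf("m%03d", seq_along(sizes))
  annotation_set(sets, n_categories = n_categories)
}
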