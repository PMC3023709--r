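# The 132-feature hybrid-property descriptor: composition (C), transition
# (T) and distribution (D) statistics over six property-group alphabets,
# plus the 20 amino-acid composition (AAC) percentages. All values are
# percentages in [0, 100].

canonical_mask <- function(sequence) {
  strsplit(sequence, "", fixed = TRUE)[[1]] %in% CANONICAL_AA
}

#' Translate a protein sequence into a property-group string
#'
#' Each canonical residue is replaced by its property-group letter.
#' Noncanonical residues (X, B, Z, U, O, J) are excluded from the output
#' and from position numbering, so the translated string can be shorter
#' than the input sequence. For the annotation-backed properties
#' (secondary structure, solvent accessibility) the group letters are
#' taken from the record's residue annotations; if absent and
#' `fallback = TRUE`, the deterministic heuristic
#' [fallback_residue_annotation()] is used instead (and flagged).
#'
#' @param record A [protein_record()].
#' @param alphabet One element of [ctd_alphabets()].
#' @param fallback Allow the heuristic fallback for annotation-backed
#'   alphabets when no annotation is present (default `FALSE`).
#' @return A group-letter string over the alphabet's groups.
#' @export
translate_sequence <- function(record, alphabet, fallback = FALSE) {
  stopifnot(inherits(record, "protein_record"),
            inherits(alphabet, "property_alphabet"))
  chars <- strsplit(record$sequence, "", fixed = TRUE)[[1]]
  keep <- chars %in% CANONICAL_AA
  if (alphabet$source == "sequence") {
    out <- alphabet$mapping[chars[keep]]
  } else {
    lab <- record$residue_annotations[[alphabet$name]]
    if (is.null(lab)) {
      if (!fallback) {
        stop("record '", record$id, "': no '", alphabet$name,
             "' residue annotation and fallback disabled", call. = FALSE)
      }
      lab <- fallback_residue_annotation(record, alphabet$name)
    }
    lab_chars <- strsplit(toupper(lab), "", fixed = TRUE)[[1]]
    if (length(lab_chars) != length(chars)) {
      stop("record '", record$id, "': '", alphabet$name,
           "' annotation length mismatch", call. = FALSE)
    }
    out <- lab_chars[keep]
    bad <- setdiff(unique(out), alphabet$groups)
    if (length(bad)) {
      stop("record '", record$id, "': '", alphabet$name,
           "' annotation uses label(s) outside ",
           paste(alphabet$groups, collapse = "/"), ": ",
           paste(bad, collapse = ","), call. = FALSE)
    }
  }
  paste(out, collapse = "")
}

#' Composition features (C)
#'
#' Global percent composition of each property group in a translated
#' group-letter string. Values sum to 100.
#'
#' @param group_seq Group-letter string (from [translate_sequence()]).
#' @param alphabet The matching alphabet.
#' @return Named numeric vector, one percentage per group.
#' @export
composition_features <- function(group_seq, alphabet) {
  chars <- strsplit(group_seq, "", fixed = TRUE)[[1]]
  if (length(chars) == 0L) {
    stop("empty translated sequence: no canonical residues to describe",
         call. = FALSE)
  }
  counts <- vapply(alphabet$groups, function(g) sum(chars == g), numeric(1))
  100 * counts / length(chars)
}

group_pairs <- function(groups) {
  n <- length(groups)
  pairs <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      pairs[[length(pairs) + 1L]] <- c(groups[i], groups[j])
    }
  }
  pairs
}

#' Transition features (T)
#'
#' Percent frequency with which the group letter changes between
#' adjacent positions, per unordered group pair. The denominator is the
#' number of adjacent positions whose letters differ (not sequence
#' length minus one), so the nonzero case sums to 100; a string with no
#' letter changes yields all zeros.
#'
#' @inheritParams composition_features
#' @return Named numeric vector, one percentage per unordered group pair.
#' @export
transition_features <- function(group_seq, alphabet) {
  chars <- strsplit(group_seq, "", fixed = TRUE)[[1]]
  if (length(chars) == 0L) {
    stop("empty translated sequence: no canonical residues to describe",
         call. = FALSE)
  }
  pairs <- group_pairs(alphabet$groups)
  nm <- vapply(pairs, paste0, character(1), collapse = "")
  if (length(chars) == 1L) {
    return(stats::setNames(numeric(length(pairs)), nm))
  }
  a <- chars[-length(chars)]
  b <- chars[-1L]
  diff <- a != b
  K <- sum(diff)
  counts <- vapply(pairs, function(p) {
    sum((a == p[1] & b == p[2]) | (a == p[2] & b == p[1]))
  }, numeric(1))
  vals <- if (K == 0L) numeric(length(pairs)) else 100 * counts / K
  stats::setNames(vals, nm)
}

#' Distribution features (D)
#'
#' For each group, the percent of the translated sequence length within
#' which the first, 25%, 50%, 75% and 100% of that group's residues are
#' located. With n occurrences at 1-based positions q_1 < ... < q_n in a
#' string of length L, the landmarks are q_1 and q_ceil(0.25 n),
#' q_ceil(0.5 n), q_ceil(0.75 n), q_n, each reported as 100 q / L. A
#' group with no occurrences yields (0, 0, 0, 0, 0).
#'
#' @inheritParams composition_features
#' @return Named numeric vector of length 5 x number of groups; each
#'   group's 5-tuple is non-decreasing.
#' @export
distribution_features <- function(group_seq, alphabet) {
  chars <- strsplit(group_seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  if (L == 0L) {
    stop("empty translated sequence: no canonical residues to describe",
         call. = FALSE)
  }
  qs <- c(1, 25, 50, 75, 100)
  out <- numeric(0)
  for (g in alphabet$groups) {
    pos <- which(chars == g)
    n <- length(pos)
    vals <- if (n == 0L) {
      numeric(5)
    } else {
      idx <- c(1L, ceiling(0.25 * n), ceiling(0.5 * n), ceiling(0.75 * n), n)
      100 * pos[idx] / L
    }
    names(vals) <- paste0(g, ".", qs)
    out <- c(out, vals)
  }
  out
}

#' Amino-acid composition features (AAC)
#'
#' Percentage of each of the 20 canonical amino acids among the
#' canonical residues of the sequence. Noncanonical residues are
#' excluded from both numerator and denominator.
#'
#' @param record A [protein_record()].
#' @return Named numeric vector of 20 percentages summing to 100.
#' @export
aac_features <- function(record) {
  stopifnot(inherits(record, "protein_record"))
  chars <- strsplit(record$sequence, "", fixed = TRUE)[[1]]
  chars <- chars[chars %in% CANONICAL_AA]
  if (length(chars) == 0L) {
    stop("record '", record$id, "': no canonical residues", call. = FALSE)
  }
  counts <- vapply(CANONICAL_AA, function(a) sum(chars == a), numeric(1))
  100 * counts / length(chars)
}

property_block <- function(record, alphabet, fallback) {
  gs <- translate_sequence(record, alphabet, fallback = fallback)
  C <- composition_features(gs, alphabet)
  Tr <- transition_features(gs, alphabet)
  D <- distribution_features(gs, alphabet)
  if (length(alphabet$groups) == 2L) {
    # Two-group properties are reported with the dimensionality of the
    # published 132-feature layout: one composition value (the second
    # group's percentage is its complement), the single transition pair,
    # and the first group's distribution 5-tuple.
    C <- C[1L]
    D <- D[1:5]
  }
  vals <- c(C, Tr, D)
  names(vals) <- paste0(alphabet$name, ".",
                        c(paste0("C.", names(C)),
                          paste0("T.", names(Tr)),
                          paste0("D.", names(D))))
  vals
}

#' Compute the full 132-feature hybrid-property descriptor
#'
#' Concatenates, in fixed order, the C/T/D blocks for hydrophobicity,
#' secondary structure, solvent accessibility, normalized van der Waals
#' volume, polarity and polarizability (block sizes 21, 21, 7, 21, 21,
#' 21), followed by the 20 amino-acid composition features: 132 named
#' features in total, all percentages.
#'
#' @param record A [protein_record()].
#' @param alphabets Property alphabets, default [ctd_alphabets()].
#' @param fallback Allow heuristic per-residue annotation fallback for
#'   secondary structure and solvent accessibility (default `FALSE`).
#' @return Named numeric vector of length 132.
#' @export
featurize <- function(record, alphabets = ctd_alphabets(), fallback = FALSE) {
  blocks <- lapply(alphabets, function(a) property_block(record, a, fallback))
  aac <- aac_features(record)
  names(aac) <- paste0("aac.", names(aac))
  out <- c(unlist(unname(blocks)), aac)
  stopifnot(length(out) == 132L)
  out
}

#' Featurize a set of protein records into a matrix
#'
#' @param records Named list of [protein_record()] objects.
#' @inheritParams featurize
#' @return Numeric matrix, one row per protein (rownames are ids), 132
#'   named feature columns.
#' @export
featurize_records <- function(records, alphabets = ctd_alphabets(),
                              fallback = FALSE) {
  rows <- lapply(records, featurize, alphabets = alphabets,
                 fallback = fallback)
  mat <- do.call(rbind, rows)
  rownames(mat) <- vapply(records, `[[`, character(1), "id")
  mat
}

#' Heuristic per-residue annotation fallback
#'
#' Produces deterministic per-residue labels when no external
#' predictor output is available. Secondary structure assigns each
#' residue the state (helix H, sheet E, coil C) with the highest
#' Chou-Fasman conformational propensity, with ties going to coil.
#' Solvent accessibility marks a residue buried (B) when the mean
#' Kyte-Doolittle hydropathy over a 9-residue window (truncated at the
#' sequence ends) is positive, else exposed (X). These are crude
#' single-residue/window heuristics and are flagged as such; supplying
#' real predictor output via residue-annotation files is always
#' preferred. Noncanonical residues receive the default state (C or X);
#' they are excluded at translation anyway.
#'
#' @param record A [protein_record()].
#' @param property `"secondary_structure"` or `"solvent_accessibility"`.
#' @param quiet Suppress the heuristic-use message.
#' @return Per-residue label string, same length as the sequence.
#' @export
fallback_residue_annotation <- function(record, property, quiet = FALSE) {
  stopifnot(inherits(record, "protein_record"))
  property <- match.arg(property,
                        c("secondary_structure", "solvent_accessibility"))
  if (!quiet) {
    message("record '", record$id, "': using heuristic '", property,
            "' labels (no annotation supplied)")
  }
  chars <- strsplit(record$sequence, "", fixed = TRUE)[[1]]
  canon <- chars %in% CANONICAL_AA
  if (property == "secondary_structure") {
    lab <- rep("C", length(chars))
    cc <- chars[canon]
    prop <- CHOU_FASMAN[cc, , drop = FALSE]
    pick <- apply(prop, 1L, function(p) {
      m <- max(p)
      # tie (or turn/coil max) resolves to coil
      if (p[3] == m || sum(p == m) > 1L) "C" else c("H", "E")[which.max(p[1:2])]
    })
    lab[canon] <- pick
  } else {
    lab <- rep("X", length(chars))
    hp <- KYTE_DOOLITTLE[chars[canon]]
    n <- length(hp)
    win <- vapply(seq_len(n), function(i) {
      mean(hp[max(1L, i - 4L):min(n, i + 4L)])
    }, numeric(1))
    lab[canon] <- ifelse(win > 0, "B", "X")
  }
  paste(lab, collapse = "")
}

#' Filter duplicate feature vectors against their annotations
#'
#' Applies the two dataset-filtering rules used before training the
#' sequence-based predictor: (1) every member of a group of proteins
#' sharing an identical coding vector but differing function sets is
#' removed (their labels are contradictory at this feature resolution);
#' (2) of a group sharing both the coding vector and the function set,
#' only one representative (the lexicographically smallest id) is kept.
#'
#' @param mat Feature matrix with protein ids as rownames.
#' @param ann An [annotation_set()] covering every row.
#' @return List with `features` (filtered matrix), `annotations`
#'   (filtered annotation set) and `report` (data frame of removed ids
#'   with columns `id`, `reason`, `group`).
#' @export
dedupe_vectors <- function(mat, ann) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)),
            inherits(ann, "annotation_set"))
  ids <- rownames(mat)
  missing <- setdiff(ids, names(ann))
  if (length(missing)) {
    stop("proteins without annotations: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  key <- apply(mat, 1L, function(r) paste(format(r, digits = 15), collapse = "|"))
  removed <- data.frame(id = character(), reason = character(),
                        group = integer(), stringsAsFactors = FALSE)
  drop <- character(0)
  groups <- split(ids, key)
  gi <- 0L
  for (g in groups) {
    gi <- gi + 1L
    if (length(g) == 1L) next
    fsets <- lapply(g, function(id) ann[[id]])
    same <- all(vapply(fsets, identical, logical(1), fsets[[1]]))
    if (!same) {
      drop <- c(drop, g)
      removed <- rbind(removed, data.frame(
        id = g, reason = "identical_vector_conflicting_functions",
        group = gi, stringsAsFactors = FALSE))
    } else {
      keep <- sort(g)[1L]
      lose <- setdiff(g, keep)
      drop <- c(drop, lose)
      removed <- rbind(removed, data.frame(
        id = lose, reason = "identical_vector_same_functions",
        group = gi, stringsAsFactors = FALSE))
    }
  }
  keep_ids <- setdiff(ids, drop)
  sets <- unclass(ann)[keep_ids]
  list(
    features = mat[keep_ids, , drop = FALSE],
    annotations = annotation_set(sets,
                                 n_categories = attr(ann, "n_categories")),
    report = removed
  )
}
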