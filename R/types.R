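# Core domain containers: protein records, annotation sets, weighted networks.

CANONICAL_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
NONCANONICAL_AA <- c("X", "B", "Z", "U", "O", "J")

#' Create a protein record
#'
#' A protein record couples an identifier with an amino-acid sequence and,
#' optionally, per-residue annotation strings (e.g. secondary-structure
#' states from an external predictor, or buried/exposed solvent
#' accessibility calls). Sequences are uppercased; the 20 canonical
#' residues plus the noncanonical set X, B, Z, U, O, J are accepted, and
#' any noncanonical residues present are flagged on the record.
#'
#' @param id Protein identifier (non-empty string).
#' @param sequence Amino-acid sequence (non-empty).
#' @param residue_annotations Optional named list of per-residue label
#'   strings, each the same length as `sequence`. Recognised names are
#'   `"secondary_structure"` (labels over H/E/C) and
#'   `"solvent_accessibility"` (labels over B/X).
#' @return An object of class `protein_record` with elements `id`,
#'   `sequence`, `residue_annotations`, and `noncanonical` (character
#'   vector of flagged noncanonical letters, possibly empty).
#' @export
protein_record <- function(id, sequence, residue_annotations = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  if (!nzchar(sequence)) {
    stop("protein record '", id, "': empty sequence", call. = FALSE)
  }
  letters_seen <- unique(strsplit(sequence, "", fixed = TRUE)[[1]])
  bad <- setdiff(letters_seen, c(CANONICAL_AA, NONCANONICAL_AA))
  if (length(bad)) {
    stop("protein record '", id, "': invalid residue letter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  noncanon <- intersect(letters_seen, NONCANONICAL_AA)
  if (length(residue_annotations)) {
    stopifnot(is.list(residue_annotations), !is.null(names(residue_annotations)))
    for (nm in names(residue_annotations)) {
      lab <- residue_annotations[[nm]]
      if (nchar(lab) != nchar(sequence)) {
        stop("protein record '", id, "': residue annotation '", nm,
             "' length ", nchar(lab), " != sequence length ",
             nchar(sequence), call. = FALSE)
      }
    }
  }
  structure(
    list(id = id, sequence = sequence,
         residue_annotations = residue_annotations,
         noncanonical = noncanon),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$id, " (", nchar(x$sequence), " aa",
      if (length(x$noncanonical))
        paste0("; noncanonical: ", paste(x$noncanonical, collapse = ",")),
      if (length(x$residue_annotations))
        paste0("; annotations: ",
               paste(names(x$residue_annotations), collapse = ",")),
      ")\n", sep = "")
  invisible(x)
}

#' Create an annotation set
#'
#' Maps protein identifiers to non-empty sets of functional-category
#' indices drawn from the 24-category catalogue ([funcat_catalog()]).
#'
#' @param x Named list of integer vectors (one per protein), each a
#'   non-empty set of category indices.
#' @param n_categories Number of categories in the label space (default 24).
#' @return An object of class `annotation_set`: a named list of sorted
#'   unique integer vectors, with attribute `n_categories`.
#' @export
annotation_set <- function(x, n_categories = 24L) {
  stopifnot(is.list(x), !is.null(names(x)), all(nzchar(names(x))))
  if (anyDuplicated(names(x))) {
    stop("duplicate protein ids in annotation set: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(names(x), function(id) {
    v <- x[[id]]
    if (length(v) == 0L) {
      stop("protein '", id, "': empty category list", call. = FALSE)
    }
    v <- as.integer(v)
    if (anyNA(v) || any(v < 1L) || any(v > n_categories)) {
      stop("protein '", id, "': category index outside 1..", n_categories,
           call. = FALSE)
    }
    sort(unique(v))
  })
  names(out) <- names(x)
  structure(out, class = "annotation_set", n_categories = as.integer(n_categories))
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set> ", length(x), " proteins, ",
      attr(x, "n_categories"), " categories, mean set size ",
      format(mean(lengths(x)), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Create a weighted undirected interaction network
#'
#' Stores an undirected protein-protein interaction network with strictly
#' positive edge confidence weights (e.g. STRING combined scores). Edge
#' weights are kept on whatever positive scale they arrive on: every
#' downstream ranking is invariant to uniform positive rescaling, so no
#' normalisation is imposed. Self-loops are not representable: the
#' interaction of a protein with itself is defined to be absent (weight 0).
#'
#' @param edges Data frame with columns `a`, `b` (protein ids) and
#'   `weight` (positive numeric). Pairs are unordered; duplicate rows for
#'   the same pair must carry equal weights (use [read_edge_list()] for
#'   the tolerant max-collapse behaviour).
#' @param nodes Optional character vector of node ids; the union of the
#'   edge endpoints is always included, so this only adds isolated nodes.
#' @return An object of class `weighted_network` with elements `nodes`
#'   (character) and `edges` (data frame `a`, `b`, `weight` with
#'   `a < b` lexicographically).
#' @export
weighted_network <- function(edges, nodes = NULL) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(a = character(), b = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("a", "b", "weight") %in% names(edges)))
  edges$a <- as.character(edges$a)
  edges$b <- as.character(edges$b)
  edges$weight <- as.numeric(edges$weight)
  if (anyNA(edges$weight) || any(edges$weight <= 0)) {
    stop("edge weights must be strictly positive numbers", call. = FALSE)
  }
  if (any(edges$a == edges$b)) {
    stop("self-loop edges are not allowed", call. = FALSE)
  }
  lo <- pmin(edges$a, edges$b)
  hi <- pmax(edges$a, edges$b)
  edges$a <- lo
  edges$b <- hi
  key <- paste(edges$a, edges$b, sep = "\r")
  if (anyDuplicated(key)) {
    w_by_key <- split(edges$weight, key)
    if (any(vapply(w_by_key, function(w) length(unique(w)) > 1L, logical(1)))) {
      stop("conflicting duplicate edges; use read_edge_list() to collapse",
           call. = FALSE)
    }
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(as.character(nodes), edges$a, edges$b)))
  structure(list(nodes = nodes, edges = edges), class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat("<weighted_network> ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Neighbours of a node with interaction weights
#'
#' @param net A [weighted_network()].
#' @param id Node identifier.
#' @return Data frame with columns `id` (neighbour) and `weight`; zero
#'   rows for an isolated node.
#' @export
net_neighbors <- function(net, id) {
  stopifnot(inherits(net, "weighted_network"))
  if (!id %in% net$nodes) {
    stop("node '", id, "' is not in the network", call. = FALSE)
  }
  e <- net$edges
  sel_a <- e$a == id
  sel_b <- e$b == id
  data.frame(
    id = c(e$b[sel_a], e$a[sel_b]),
    weight = c(e$weight[sel_a], e$weight[sel_b]),
    stringsAsFactors = FALSE
  )
}

# Fast adjacency list for repeated neighbour lookups (jackknife loops).
adjacency_list <- function(net) {
  e <- net$edges
  adj <- vector("list", length(net$nodes))
  names(adj) <- net$nodes
  both_from <- c(e$a, e$b)
  both_to <- c(e$b, e$a)
  both_w <- c(e$weight, e$weight)
  idx <- split(seq_along(both_from), both_from)
  for (nm in names(idx)) {
    i <- idx[[nm]]
    adj[[nm]] <- list(id = both_to[i], weight = both_w[i])
  }
  for (nm in setdiff(net$nodes, names(idx))) {
    adj[[nm]] <- list(id = character(), weight = numeric())
  }
  adj
}
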