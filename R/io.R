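# Readers and writers for the external formats the toolkit touches:
# FASTA sequences, FASTA-like residue-annotation files, edge lists,
# annotation tables and id maps. All table readers accept tab- or
# whitespace-delimited rows, '#' comment lines, blank lines and CRLF
# line endings.

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and internal whitespace is stripped.
#' Noncanonical residues (X, B, Z, U, O, J) are retained and flagged on
#' the returned records; how they are treated downstream is decided at
#' featurization (they are excluded from translated property strings and
#' from the amino-acid composition).
#'
#' @param path Path to a FASTA file.
#' @return Named list of [protein_record()] objects (names are the ids).
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA file '", path, "' contains no records", call. = FALSE)
  }
  ids <- sub("[[:space:]].*$", "", names(set))
  if (any(!nzchar(ids))) {
    stop("FASTA file '", path, "' has a record with an empty header",
         call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("FASTA file '", path, "' has duplicate ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- unname(as.character(set))
  empty <- !nzchar(gsub("[[:space:]]", "", seqs))
  if (any(empty)) {
    stop("FASTA file '", path, "' has record(s) with empty sequence: ",
         paste(ids[empty], collapse = ", "), call. = FALSE)
  }
  recs <- lapply(seq_along(ids), function(i) protein_record(ids[i], seqs[i]))
  names(recs) <- ids
  for (r in recs) {
    if (length(r$noncanonical)) {
      message("record '", r$id, "': noncanonical residue(s) ",
              paste(r$noncanonical, collapse = ","), " flagged")
    }
  }
  recs
}

#' Write protein records to a FASTA file
#'
#' @param records Named list of [protein_record()] objects.
#' @param path Output path.
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(paste0(">", r$id), con)
    s <- r$sequence
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# Shared tolerant table reader: whitespace/tab delimited, '#' comments,
# blank lines and CRLF all accepted.
read_plain_table <- function(path, n_cols, what) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[!grepl("^[[:space:]]*(#|$)", lines)]
  if (length(lines) == 0L) {
    stop(what, " file '", path, "' contains no data rows", call. = FALSE)
  }
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- which(lengths(parts) != n_cols)
  if (length(bad)) {
    stop(what, " file '", path, "': row ", bad[1], " has ",
         lengths(parts)[bad[1]], " fields (expected ", n_cols, ")",
         call. = FALSE)
  }
  as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
}

#' Read a protein-to-function annotation table
#'
#' Expects two columns: protein id and a comma-separated list of
#' functional-category indices (1..24). Duplicate rows for the same
#' protein are unioned with a warning.
#'
#' @param path Path to the annotation table.
#' @param catalog Category catalogue; defaults to [funcat_catalog()].
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path, catalog = funcat_catalog()) {
  tab <- read_plain_table(path, 2L, "annotation")
  n_cat <- nrow(catalog)
  ids <- tab[[1]]
  sets <- lapply(seq_len(nrow(tab)), function(i) {
    raw <- strsplit(tab[[2]][i], ",", fixed = TRUE)[[1]]
    raw <- raw[nzchar(trimws(raw))]
    if (length(raw) == 0L) {
      stop("protein '", ids[i], "': empty category list", call. = FALSE)
    }
    v <- suppressWarnings(as.integer(trimws(raw)))
    if (anyNA(v)) {
      stop("protein '", ids[i], "': non-integer category entry", call. = FALSE)
    }
    if (any(v < 1L | v > n_cat)) {
      stop("protein '", ids[i], "': category index outside 1..", n_cat,
           call. = FALSE)
    }
    v
  })
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    warning("duplicate annotation rows unioned for: ",
            paste(dups, collapse = ", "), call. = FALSE)
    sets <- lapply(split(sets, ids), function(s) unique(unlist(s)))
    return(annotation_set(sets[unique(ids)], n_categories = n_cat))
  }
  names(sets) <- ids
  annotation_set(sets, n_categories = n_cat)
}

#' Write an annotation set to a two-column table
#'
#' @param ann An [annotation_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  lines <- vapply(names(ann), function(id) {
    paste0(id, "\t", paste(ann[[id]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a weighted edge list into a network
#'
#' Expects three columns: two protein ids and a strictly positive
#' confidence weight (STRING-style combined scores or any positive
#' scale). The network is undirected: rows `a b w` and `b a w` describe
#' the same edge. Duplicate pairs collapse to the maximum weight with a
#' warning; self-pairs are dropped with a warning.
#'
#' @param path Path to the edge-list file.
#' @return A [weighted_network()].
#' @export
read_edge_list <- function(path) {
  tab <- read_plain_table(path, 3L, "edge list")
  w <- suppressWarnings(as.numeric(tab[[3]]))
  if (anyNA(w) || any(w <= 0)) {
    bad <- which(is.na(w) | w <= 0)[1]
    stop("edge list '", path, "': non-positive or non-numeric weight ",
         "in row ", bad, " ('", tab[[3]][bad], "')", call. = FALSE)
  }
  a <- tab[[1]]
  b <- tab[[2]]
  self <- a == b
  if (any(self)) {
    warning("dropped ", sum(self), " self-pair row(s): ",
            paste(unique(a[self]), collapse = ", "), call. = FALSE)
    a <- a[!self]; b <- b[!self]; w <- w[!self]
  }
  if (length(a) == 0L) {
    return(weighted_network(NULL))
  }
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  if (anyDuplicated(key)) {
    keep_w <- tapply(w, key, max)
    dup_keys <- names(which(table(key) > 1L))
    warning("collapsed ", length(dup_keys),
            " duplicate pair(s) to their maximum weight", call. = FALSE)
    first <- !duplicated(key)
    edges <- data.frame(a = lo[first], b = hi[first],
                        weight = as.numeric(keep_w[key[first]]),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(a = lo, b = hi, weight = w, stringsAsFactors = FALSE)
  }
  weighted_network(edges)
}

#' Write a network as a three-column edge list
#'
#' @param net A [weighted_network()].
#' @param path Output path.
#' @param header Optional character vector written as '#' comment lines.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path, header = NULL) {
  stopifnot(inherits(net, "weighted_network"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(paste0("# ", header), con)
  }
  e <- net$edges
  writeLines(paste(e$a, e$b, format(e$weight, trim = TRUE, digits = 15),
                   sep = "\t"), con)
  invisible(path)
}

#' Read per-residue annotation files
#'
#' Reads FASTA-like files whose body lines are per-residue label strings
#' (secondary-structure states H/E/C or solvent-accessibility states
#' B/X), one record per protein, mirroring the output format of external
#' per-residue predictors.
#'
#' @param path Path to the annotation file.
#' @return Named character vector of label strings.
#' @export
read_residue_annotations <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("[[:space:]].*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("residue-annotation file '", path, "' has duplicate ids",
         call. = FALSE)
  }
  labs <- toupper(gsub("[[:space:]]", "", as.character(set)))
  names(labs) <- ids
  labs
}

#' Write per-residue annotations
#'
#' @param labels Named character vector of per-residue label strings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_residue_annotations <- function(labels, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(labels)) {
    writeLines(c(paste0(">", id), labels[[id]]), con)
  }
  invisible(path)
}

#' Translate identifiers via a two-column mapping table
#'
#' Applies an old-id to new-id mapping (e.g. database accession to
#' Ensembl id) to a network, an annotation set or a list of protein
#' records. Unmapped ids are retained unchanged and reported via the
#' `"unmapped"` attribute (and a message). An old id mapping to more
#' than one distinct new id is an error: the toolkit refuses to guess.
#'
#' @param x A [weighted_network()], [annotation_set()], or named list of
#'   [protein_record()] objects.
#' @param map_path Path to a two-column table (old id, new id).
#' @return Object of the same type with ids translated; attribute
#'   `"unmapped"` lists ids left unchanged.
#' @export
apply_id_map <- function(x, map_path) {
  tab <- read_plain_table(map_path, 2L, "id map")
  old <- tab[[1]]
  new <- tab[[2]]
  tab <- unique(data.frame(old = old, new = new, stringsAsFactors = FALSE))
  multi <- unique(tab$old[duplicated(tab$old)])
  if (length(multi)) {
    stop("ambiguous id map: old id(s) with multiple targets: ",
         paste(multi, collapse = ", "), call. = FALSE)
  }
  map <- stats::setNames(tab$new, tab$old)
  translate <- function(ids) {
    hit <- ids %in% names(map)
    ids[hit] <- unname(map[ids[hit]])
    ids
  }
  if (inherits(x, "weighted_network")) {
    unmapped <- setdiff(x$nodes, names(map))
    e <- x$edges
    e$a <- translate(e$a)
    e$b <- translate(e$b)
    out <- weighted_network(e, nodes = translate(x$nodes))
  } else if (inherits(x, "annotation_set")) {
    unmapped <- setdiff(names(x), names(map))
    sets <- unclass(x)
    names(sets) <- translate(names(sets))
    out <- annotation_set(sets, n_categories = attr(x, "n_categories"))
  } else if (is.list(x) && all(vapply(x, inherits, logical(1), "protein_record"))) {
    unmapped <- setdiff(vapply(x, `[[`, character(1), "id"), names(map))
    out <- lapply(x, function(r) {
      r$id <- translate(r$id)
      r
    })
    names(out) <- vapply(out, `[[`, character(1), "id")
  } else {
    stop("apply_id_map: unsupported input type", call. = FALSE)
  }
  if (length(unmapped)) {
    message(length(unmapped), " id(s) had no mapping and were retained: ",
            paste(utils::head(unmapped, 5), collapse = ", "),
            if (length(unmapped) > 5) ", ...")
  }
  attr(out, "unmapped") <- unmapped
  out
}
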