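# Domain types shared by every pipeline stage: taxon universe, orthogroup
# alignment, score track, orthogroup set, partition scheme, supermatrix.
# Alignments are stored as character matrices (rows = taxa, columns = sites);
# this makes site masking, identity computation and concatenation direct
# column operations.

#' Alphabet definitions
#'
#' The pipeline handles two residue alphabets: `amino20` (the 20 canonical
#' IUPAC amino-acid letters plus ambiguity letters B, Z, J, X, U, O, the
#' alignment gap `-`, the missing symbol `?` and the stop `*`) and `dayhoff6`
#' (digit states `0`..`5` from Dayhoff-class recoding, plus `-` and `?`).
#'
#' @format `AA20` is the character vector of the 20 canonical amino-acid
#'   letters in alphabetical order.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_AMBIG <- c("B", "Z", "J", "X", "U", "O")

.alphabet_chars <- function(alphabet) {
  switch(alphabet,
    amino20 = c(AA20, AA_AMBIG, "-", "?", "*"),
    dayhoff6 = c(as.character(0:5), "-", "?"),
    stop("unknown alphabet: ", alphabet, call. = FALSE)
  )
}

# residues carrying no character information (used by occupancy and
# missing-data statistics; ambiguity letters are NOT missing for occupancy)
.missing_chars <- c("-", "?")

.canonical_states <- function(alphabet) {
  switch(alphabet, amino20 = AA20, dayhoff6 = as.character(0:5))
}

#' Construct a taxon universe
#'
#' The ordered set of taxon labels over which all orthogroups and the
#' supermatrix are defined.  Order determines row order in every emitted
#' matrix; the default is lexicographic so that output files are reproducible
#' regardless of input file order.
#'
#' @param labels character vector of unique, non-empty taxon identifiers
#'   without leading/trailing whitespace.
#' @param sort if `TRUE` (default), labels are sorted lexicographically
#'   (C locale); if `FALSE` the supplied order is kept verbatim.
#' @return a `taxon_universe` object (a classed character vector).
#' @examples
#' taxon_universe(c("Mya", "Chama", "Lucina"))
#' @export
taxon_universe <- function(labels, sort = TRUE) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("taxon universe must be non-empty", call. = FALSE)
  bad <- labels == "" | is.na(labels) | labels != trimws(labels)
  if (any(bad)) {
    stop("invalid taxon labels (empty or padded with whitespace): ",
         paste(sQuote(labels[bad]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("duplicated taxon labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  if (sort) {
    old <- Sys.getlocale("LC_COLLATE")
    on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
    Sys.setlocale("LC_COLLATE", "C")
    labels <- sort(labels)
  }
  structure(labels, class = "taxon_universe")
}

#' @export
print.taxon_universe <- function(x, ...) {
  cat("Taxon universe:", length(x), "taxa\n")
  utils::str(unclass(x))
  invisible(x)
}

# convert a named character vector of sequence strings into a residue matrix
seqs_to_matrix <- function(seqs) {
  if (length(seqs) == 0L) {
    return(matrix(character(0), nrow = 0, ncol = 0))
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    stop("ragged sequence lengths: ",
         paste(names(seqs), lens, sep = "=", collapse = ", "), call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  mat
}

# inverse of seqs_to_matrix
matrix_to_seqs <- function(mat) {
  if (nrow(mat) == 0L) return(stats::setNames(character(0), character(0)))
  stats::setNames(apply(mat, 1L, paste, collapse = ""), rownames(mat))
}

#' Construct an orthogroup alignment
#'
#' One aligned locus: an equal-length set of residue rows, at most one per
#' taxon (OMA-style orthogroups are one sequence per taxon).
#'
#' @param id orthogroup identifier (single non-empty string).
#' @param rows either a named character vector of aligned sequence strings or
#'   a character matrix of single residues with taxon rownames.
#' @param alphabet `"amino20"` or `"dayhoff6"`.
#' @return an `og_alignment` object with elements `id`, `mat` (residue
#'   matrix), `alphabet`.
#' @examples
#' og_alignment("og1", c(A = "MK-R", B = "MKQR"))
#' @export
og_alignment <- function(id, rows, alphabet = c("amino20", "dayhoff6")) {
  alphabet <- match.arg(alphabet)
  if (length(id) != 1L || is.na(id) || id == "") {
    stop("orthogroup id must be a single non-empty string", call. = FALSE)
  }
  mat <- if (is.matrix(rows)) rows else seqs_to_matrix(rows)
  if (nrow(mat) > 0L) {
    if (is.null(rownames(mat)) || any(rownames(mat) == "")) {
      stop("alignment rows must be named by taxon", call. = FALSE)
    }
    if (anyDuplicated(rownames(mat))) {
      stop("orthogroup ", id, ": more than one row for taxon ",
           paste(unique(rownames(mat)[duplicated(rownames(mat))]),
                 collapse = ", "), call. = FALSE)
    }
    legal <- .alphabet_chars(alphabet)
    illegal <- !(mat %in% legal)
    dim(illegal) <- dim(mat)
    if (any(illegal)) {
      w <- which(illegal, arr.ind = TRUE)[1L, ]
      stop("orthogroup ", id, ": illegal ", alphabet, " residue ",
           sQuote(mat[w[1L], w[2L]]), " (taxon ", rownames(mat)[w[1L]],
           ", column ", w[2L], ")", call. = FALSE)
    }
  }
  structure(list(id = id, mat = mat, alphabet = alphabet),
            class = "og_alignment")
}

#' @export
print.og_alignment <- function(x, ...) {
  cat(sprintf("Orthogroup alignment '%s': %d taxa x %d columns [%s]\n",
              x$id, nrow(x$mat), ncol(x$mat), x$alphabet))
  invisible(x)
}

#' Number of alignment columns
#' @param og an [og_alignment].
#' @return integer column count.
#' @export
og_length <- function(og) ncol(og$mat)

#' Taxa present in an alignment
#' @param og an [og_alignment].
#' @return character vector of row labels.
#' @export
og_taxa <- function(og) rownames(og$mat) %||% character(0)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Alignment rows as sequence strings
#' @param og an [og_alignment].
#' @return named character vector, one string per taxon.
#' @export
og_sequences <- function(og) matrix_to_seqs(og$mat)

#' Construct a per-column confidence score track
#'
#' Holds one non-negative confidence value per alignment column, in column
#' order — the content of a ZORRO output file.  Length agreement with the
#' alignment it annotates is checked where the two meet ([mask_sites()]).
#'
#' @param og_id orthogroup identifier the track belongs to.
#' @param scores numeric vector of non-negative scores.
#' @return a `score_track` object.
#' @export
score_track <- function(og_id, scores) {
  scores <- as.numeric(scores)
  if (anyNA(scores) || any(scores < 0)) {
    stop("scores must be non-negative real numbers", call. = FALSE)
  }
  structure(list(og_id = og_id, scores = scores), class = "score_track")
}

#' Construct an orthogroup set
#'
#' A collection of orthogroup alignments over a shared taxon universe.  Loci
#' are stored sorted lexicographically by orthogroup id so that concatenation
#' order is reproducible.
#'
#' @param loci list of [og_alignment] objects with unique ids.
#' @param universe a [taxon_universe]; if `NULL`, built from the union of
#'   taxa observed across loci (sorted).
#' @return an `og_set` object with elements `universe` and `loci` (named by
#'   orthogroup id).
#' @export
og_set <- function(loci, universe = NULL) {
  ids <- vapply(loci, function(og) og$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicated orthogroup ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (is.null(universe)) {
    all_taxa <- unique(unlist(lapply(loci, og_taxa)))
    if (length(all_taxa) == 0L) stop("cannot infer a taxon universe from loci without rows",
                                     call. = FALSE)
    universe <- taxon_universe(all_taxa)
  }
  if (!inherits(universe, "taxon_universe")) universe <- taxon_universe(universe)
  for (og in loci) {
    extra <- setdiff(og_taxa(og), universe)
    if (length(extra) > 0L) {
      stop("orthogroup ", og$id, ": taxa not in universe: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  o <- order(ids, method = "radix")
  loci <- loci[o]
  names(loci) <- ids[o]
  structure(list(universe = universe, loci = loci), class = "og_set")
}

#' @export
print.og_set <- function(x, ...) {
  cat(sprintf("Orthogroup set: %d loci over %d taxa\n",
              length(x$loci), length(x$universe)))
  invisible(x)
}

#' Number of loci in an orthogroup set
#' @param s an [og_set].
#' @return integer.
#' @export
n_loci <- function(s) length(s$loci)

#' Construct a partition scheme
#'
#' Maps supermatrix column ranges back to their source orthogroups.
#' Coordinates are 1-based inclusive (the RAxML/NEXUS convention); entries
#' must tile `1..L` contiguously without overlap.
#'
#' @param locus character vector of orthogroup ids.
#' @param start,end integer vectors of 1-based inclusive column ranges.
#' @return a `partition_scheme`: a data.frame with columns `locus`, `start`,
#'   `end`.
#' @export
partition_scheme <- function(locus, start, end) {
  df <- data.frame(locus = as.character(locus),
                   start = as.integer(start),
                   end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0L) {
    if (df$start[1L] != 1L) stop("first partition must start at 1", call. = FALSE)
    if (any(df$end < df$start)) stop("partition with end < start", call. = FALSE)
    if (nrow(df) > 1L && any(df$start[-1L] != df$end[-nrow(df)] + 1L)) {
      stop("partitions must be contiguous", call. = FALSE)
    }
    if (anyDuplicated(df$locus)) stop("duplicated locus in partition scheme",
                                      call. = FALSE)
  }
  class(df) <- c("partition_scheme", "data.frame")
  df
}

#' Construct a supermatrix
#'
#' Usually produced by [concatenate()]; the constructor checks the invariants
#' tying rows, universe and partition scheme together: one row per universe
#' taxon, all rows of length `L`, and `L` equal to the partition total.
#'
#' @param universe a [taxon_universe].
#' @param rows named character vector of concatenated sequence strings (or a
#'   residue matrix) covering every universe taxon.
#' @param scheme a [partition_scheme].
#' @param alphabet `"amino20"` or `"dayhoff6"`.
#' @return a `supermatrix` object with elements `universe`, `mat`, `scheme`,
#'   `alphabet`.
#' @export
supermatrix <- function(universe, rows, scheme,
                        alphabet = c("amino20", "dayhoff6")) {
  alphabet <- match.arg(alphabet)
  if (!inherits(universe, "taxon_universe")) universe <- taxon_universe(universe)
  mat <- if (is.matrix(rows)) rows else seqs_to_matrix(rows)
  if (!setequal(rownames(mat), universe) || nrow(mat) != length(universe)) {
    stop("supermatrix rows must cover the taxon universe exactly", call. = FALSE)
  }
  mat <- mat[as.character(universe), , drop = FALSE]
  L <- if (nrow(scheme) > 0L) scheme$end[nrow(scheme)] else 0L
  if (ncol(mat) != L) {
    stop("matrix length ", ncol(mat), " does not match partition total ", L,
         call. = FALSE)
  }
  structure(list(universe = universe, mat = mat, scheme = scheme,
                 alphabet = alphabet),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("Supermatrix: %d taxa x %d columns, %d partitions [%s]\n",
              nrow(x$mat), ncol(x$mat), nrow(x$scheme), x$alphabet))
  cat(sprintf("  missing data: %.2f%%\n", missingness(x)))
  invisible(x)
}

#' Validate an orthogroup set
#'
#' Structural audit of an [og_set] against the domain invariants: unique
#' locus ids, rectangular rows, at most one row per taxon, legal residues for
#' the declared alphabet, and taxon membership in the universe.  Unlike the
#' constructors (which refuse invalid input) this is a reporting operation:
#' it inspects an already-built object and enumerates every violation.
#'
#' @param s an [og_set] (possibly hand-assembled or corrupted).
#' @return character vector of human-readable violations; empty if the set
#'   is valid.
#' @export
validate_og_set <- function(s) {
  v <- character(0)
  ids <- vapply(s$loci, function(og) og$id %||% NA_character_, character(1))
  if (anyDuplicated(ids)) {
    v <- c(v, paste0("duplicated orthogroup ids: ",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  u <- as.character(s$universe)
  if (anyDuplicated(u)) v <- c(v, "duplicated taxon labels in universe")
  if (any(u == "" | u != trimws(u))) v <- c(v, "empty or padded taxon labels in universe")
  for (og in s$loci) {
    mat <- og$mat
    if (!is.matrix(mat)) {
      # tolerate raw rows that never went through the constructor
      lens <- nchar(unlist(og$rows %||% list()))
      if (length(unique(lens)) > 1L) {
        v <- c(v, paste0("orthogroup ", og$id, ": rows of unequal length"))
      }
      next
    }
    taxa <- rownames(mat) %||% character(0)
    if (nrow(mat) > 0L && anyDuplicated(taxa)) {
      v <- c(v, paste0("orthogroup ", og$id, ": multiple rows for taxon ",
                       paste(unique(taxa[duplicated(taxa)]), collapse = ", ")))
    }
    extra <- setdiff(taxa, u)
    if (length(extra) > 0L) {
      v <- c(v, paste0("orthogroup ", og$id, ": taxa not in universe: ",
                       paste(extra, collapse = ", ")))
    }
    legal <- .alphabet_chars(og$alphabet %||% "amino20")
    bad <- setdiff(unique(as.vector(mat)), legal)
    if (length(bad) > 0L) {
      v <- c(v, paste0("orthogroup ", og$id, ": illegal residues: ",
                       paste(sQuote(bad), collapse = ", ")))
    }
  }
  v
}
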