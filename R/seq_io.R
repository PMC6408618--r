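# Readers and writers for the formats the pipeline touches: FASTA alignments,
# ZORRO score tracks (one score per line), relaxed PHYLIP, RAxML/NEXUS
# partition files, and TSV occupancy reports.

#' Read a FASTA alignment as an orthogroup
#'
#' Headers are taken up to the first whitespace and used as taxon labels; the
#' orthogroup id is the file stem.  Residues are upper-cased and `.`
#' normalised to `-`.  Ragged record lengths, duplicate headers and residues
#' outside the declared alphabet are errors.
#'
#' @param path FASTA file (any line wrapping).
#' @param alphabet `"amino20"` (default) or `"dayhoff6"`.
#' @return an [og_alignment].
#' @export
read_fasta_alignment <- function(path, alphabet = c("amino20", "dayhoff6")) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  names(seqs) <- sub("\\s.*$", "", names(set))
  og_alignment(tools::file_path_sans_ext(basename(path)), seqs, alphabet)
}

#' Write an orthogroup alignment as FASTA
#'
#' @param og an [og_alignment].
#' @param path output file; sequence lines wrapped at 80 columns.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(og, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(og_sequences(og)),
                              path, width = 80L)
  invisible(path)
}

#' Write a supermatrix as FASTA
#' @param sm a [supermatrix].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta_supermatrix <- function(sm, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(matrix_to_seqs(sm$mat)),
                              path, width = 80L)
  invisible(path)
}

#' Write a supermatrix in relaxed PHYLIP format
#'
#' Relaxed dialect: header line `ntax nchar`, then one `label<space>sequence`
#' line per taxon in universe order.  Labels are not truncated to 10
#' characters (strict PHYLIP truncation creates label collisions; every
#' modern inference tool accepts the relaxed form).
#'
#' @param sm a [supermatrix].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(sm, path) {
  seqs <- matrix_to_seqs(sm$mat)
  lines <- c(paste(nrow(sm$mat), ncol(sm$mat)),
             paste(names(seqs), seqs))
  writeLines(lines, path)
  invisible(path)
}

#' Read a relaxed PHYLIP alignment
#'
#' Inverse of [write_phylip()] for sequential, one-line-per-taxon files.
#'
#' @param path PHYLIP file.
#' @return named character vector of sequence strings.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  hdr <- scan(text = lines[1L], what = integer(), n = 2L, quiet = TRUE)
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) != hdr[1L]) {
    stop("PHYLIP header declares ", hdr[1L], " taxa but file has ",
         length(body), " rows", call. = FALSE)
  }
  m <- regmatches(body, regexec("^(\\S+)\\s+(\\S+)$", body))
  labs <- vapply(m, `[`, character(1), 2L)
  seqs <- vapply(m, `[`, character(1), 3L)
  if (any(nchar(seqs) != hdr[2L])) {
    stop("sequence length disagrees with PHYLIP header", call. = FALSE)
  }
  stats::setNames(seqs, labs)
}

#' Read a ZORRO-style confidence score track
#'
#' ZORRO writes one real-valued column confidence per line.  Empty lines are
#' ignored; any non-numeric line is a parse error reported with its line
#' number.  The track id is the file stem, which must match the stem of the
#' alignment it annotates.
#'
#' @param path score file.
#' @return a [score_track].
#' @export
read_score_track <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  if (anyNA(vals)) {
    bad <- which(keep)[which(is.na(vals))[1L]]
    stop("cannot parse score at ", basename(path), " line ", bad, ": ",
         sQuote(lines[bad]), call. = FALSE)
  }
  score_track(tools::file_path_sans_ext(basename(path)), vals)
}

#' Write a score track in ZORRO format
#' @param track a [score_track].
#' @param path output file (one score per line).
#' @return `path`, invisibly.
#' @export
write_score_track <- function(track, path) {
  writeLines(format(track$scores, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}

#' Write a partition file
#'
#' Emits per-locus coordinate ranges, 1-based inclusive, in either the
#' RAxML-style flat format (`<model>, <locus> = <start>-<end>`) or a NEXUS
#' `sets` block with one `charset` per locus.
#'
#' @param scheme a [partition_scheme].
#' @param path output file.
#' @param dialect `"raxml"` or `"nexus"`.
#' @param model model token prepended to each RAxML line (the per-partition
#'   substitution model is chosen downstream, e.g. by ModelFinder; the token
#'   is a placeholder the inference tool interprets).
#' @return `path`, invisibly.
#' @export
write_partitions <- function(scheme, path, dialect = c("raxml", "nexus"),
                             model = "LG4X") {
  dialect <- match.arg(dialect)
  if (nrow(scheme) == 0L) {
    warning("writing empty partition scheme to ", path)
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- switch(dialect,
    raxml = sprintf("%s, %s = %d-%d", model, scheme$locus, scheme$start,
                    scheme$end),
    nexus = c("#NEXUS", "begin sets;",
              sprintf("    charset %s = %d-%d;", scheme$locus, scheme$start,
                      scheme$end),
              "end;")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a RAxML-style partition file
#'
#' Inverse of [write_partitions()] for the `raxml` dialect.
#'
#' @param path partition file with lines `<model>, <locus> = <start>-<end>`.
#' @return a [partition_scheme].
#' @export
read_partitions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(partition_scheme(character(0), integer(0), integer(0)))
  m <- regmatches(lines,
                  regexec("^\\s*\\S+,\\s*(\\S+)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$",
                          lines))
  ok <- lengths(m) == 4L
  if (!all(ok)) {
    stop("cannot parse partition line: ", sQuote(lines[!ok][1L]), call. = FALSE)
  }
  partition_scheme(vapply(m, `[`, character(1), 2L),
                   as.integer(vapply(m, `[`, character(1), 3L)),
                   as.integer(vapply(m, `[`, character(1), 4L)))
}

#' Write an occupancy report as TSV
#'
#' Three tab-separated sections, each introduced by a `#` header line:
#' per-taxon locus counts and fractions, per-locus occupancy, and the overall
#' missing-data percentages.
#'
#' @param report an `occupancy_report` from [occupancy_report()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_occupancy_table <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# per-taxon gene representation", con)
  writeLines("taxon\tn_loci\tfraction", con)
  pt <- report$per_taxon
  writeLines(sprintf("%s\t%d\t%.6f", pt$taxon, pt$n_loci, pt$fraction), con)
  writeLines("# per-locus occupancy", con)
  writeLines("locus\tn_taxa", con)
  pl <- report$per_locus
  writeLines(sprintf("%s\t%d", pl$locus, pl$occupancy), con)
  writeLines("# overall", con)
  writeLines(sprintf("missing_pct\t%.6f", report$missing_pct), con)
  writeLines(sprintf("absent_fill_pct\t%.6f", report$absent_fill_pct), con)
  invisible(path)
}

#' Read a directory of orthogroup FASTA alignments
#'
#' Loads every `*.fa`, `*.fasta` or `*.fst` file in a directory into an
#' [og_set]; ids are the file stems, loci are ordered lexicographically by
#' id.
#'
#' @param dir directory of per-orthogroup FASTA files.
#' @param alphabet residue alphabet of all files.
#' @param universe optional [taxon_universe]; inferred from the files when
#'   `NULL`.
#' @return an [og_set].
#' @export
read_og_directory <- function(dir, alphabet = "amino20", universe = NULL) {
  files <- list.files(dir, pattern = "\\.(fa|fasta|fst)$", full.names = TRUE)
  if (length(files) == 0L) stop("no FASTA files in ", dir, call. = FALSE)
  loci <- lapply(files, read_fasta_alignment, alphabet = alphabet)
  og_set(loci, universe = universe)
}

#' Read a directory of ZORRO score tracks
#'
#' @param dir directory of `*.zorro` or `*.scores` files, stems matching the
#'   alignments they annotate.
#' @return named list of [score_track] objects (names = orthogroup ids).
#' @export
read_score_directory <- function(dir) {
  files <- list.files(dir, pattern = "\\.(zorro|scores)$", full.names = TRUE)
  tracks <- lapply(files, read_score_track)
  stats::setNames(tracks, vapply(tracks, function(t) t$og_id, character(1)))
}
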