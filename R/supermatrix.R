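# Concatenation of selected orthogroups into a partitioned supermatrix,
# with occupancy and missing-data statistics.

#' Concatenate an orthogroup set into a supermatrix
#'
#' Joins the loci column-wise in set order (lexicographic by orthogroup id).
#' Every universe taxon gets a row; where a taxon is absent from a locus its
#' cells are filled with the missing symbol `?` — not `-`, so that no-data
#' cells remain distinguishable from alignment gaps (both count as missing
#' in the statistics).  The partition scheme records each locus's 1-based
#' inclusive column range.
#'
#' @param s an [og_set] with at least one locus.
#' @return a [supermatrix].
#' @export
concatenate <- function(s) {
  if (n_loci(s) == 0L) {
    stop(errorCondition("cannot concatenate an empty orthogroup set",
                        class = c("supermat_empty_matrix", "error",
                                  "condition")))
  }
  taxa <- as.character(s$universe)
  lens <- vapply(s$loci, og_length, integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  alphabet <- s$loci[[1L]]$alphabet
  mat <- matrix("?", nrow = length(taxa), ncol = sum(lens),
                dimnames = list(taxa, NULL))
  for (i in seq_along(s$loci)) {
    og <- s$loci[[i]]
    if (nrow(og$mat) > 0L) {
      mat[og_taxa(og), starts[i]:ends[i]] <- og$mat
    }
  }
  supermatrix(s$universe, mat,
              partition_scheme(names(s$loci), starts, ends),
              alphabet = alphabet)
}

#' Missing-data percentage of a supermatrix
#'
#' `100 * (cells that are '?' or '-') / (ntax * L)`: the fraction of matrix
#' cells carrying no character information, counting both absent-taxon fill
#' and alignment gaps.  The absent-fill-only variant (`?` cells alone) is
#' available via `what = "absent_fill"`; published missing-data figures do
#' not always say which convention they use, so both are reported by
#' [occupancy_report()].
#'
#' @param sm a [supermatrix] with at least one column.
#' @param what `"all"` (gaps and `?`, default) or `"absent_fill"` (`?`
#'   only).
#' @return percentage in `[0, 100]`.
#' @export
missingness <- function(sm, what = c("all", "absent_fill")) {
  what <- match.arg(what)
  if (ncol(sm$mat) == 0L || nrow(sm$mat) == 0L) {
    stop("missingness undefined for an empty matrix", call. = FALSE)
  }
  miss <- switch(what, all = .missing_chars, absent_fill = "?")
  100 * sum(sm$mat %in% miss) / length(sm$mat)
}

#' Occupancy and missing-data report
#'
#' Summarises a supermatrix together with the orthogroup set it was built
#' from: per-taxon locus counts (gene representation) and fractions,
#' per-locus occupancy, and overall missing-data percentages under both
#' conventions (gaps counted as missing, and absent-taxon fill only).
#'
#' @param s the [og_set] the matrix was concatenated from.
#' @param sm the [supermatrix] built from `s`.
#' @return an `occupancy_report`: list with `per_taxon` (data.frame `taxon`,
#'   `n_loci`, `fraction`), `per_locus` (data.frame `locus`, `occupancy`),
#'   `missing_pct`, `absent_fill_pct`.
#' @export
occupancy_report <- function(s, sm) {
  if (!identical(as.character(s$universe), as.character(sm$universe)) ||
      !identical(names(s$loci), sm$scheme$locus)) {
    stop("supermatrix was not built from this orthogroup set", call. = FALSE)
  }
  taxa <- as.character(s$universe)
  present <- vapply(s$loci, function(og) {
    taxa %in% og_taxa(og)[.nonempty_rows(og)]
  }, logical(length(taxa)))
  if (is.null(dim(present))) present <- matrix(present, nrow = length(taxa))
  per_taxon <- data.frame(
    taxon = taxa,
    n_loci = as.integer(rowSums(present)),
    fraction = rowSums(present) / max(1L, n_loci(s)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  per_locus <- data.frame(
    locus = names(s$loci),
    occupancy = as.integer(colSums(present)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(per_taxon = per_taxon,
                 per_locus = per_locus,
                 missing_pct = missingness(sm, "all"),
                 absent_fill_pct = missingness(sm, "absent_fill")),
            class = "occupancy_report")
}

#' @export
print.occupancy_report <- function(x, ...) {
  cat(sprintf("Occupancy report: %d taxa, %d loci\n",
              nrow(x$per_taxon), nrow(x$per_locus)))
  cat(sprintf("  missing data (gaps + absent): %.2f%%\n", x$missing_pct))
  cat(sprintf("  absent-taxon fill only:       %.2f%%\n", x$absent_fill_pct))
  invisible(x)
}
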