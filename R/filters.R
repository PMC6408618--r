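# The three bespoke filtering stages: confidence-score site masking,
# occupancy-threshold orthogroup selection, and rate-based orthogroup
# trimming with mean percent pairwise identity as the rate proxy.

#' Mask low-confidence alignment columns
#'
#' Drops every column whose per-column confidence score falls below the
#' threshold, keeping the surviving columns in their original order.  With
#' ZORRO scores (0-10 scale) the conventional cutoff is 5: columns scoring
#' below 5 are considered divergently aligned and discarded.
#'
#' @param og an [og_alignment].
#' @param track a [score_track] with exactly one score per column of `og`.
#' @param threshold minimum score a column must reach to be retained
#'   (default 5).
#' @return an [og_alignment] containing the columns with
#'   `score >= threshold`; the row set is unchanged.
#' @export
mask_sites <- function(og, track, threshold = 5) {
  if (length(track$scores) != og_length(og)) {
    stop("score track for ", og$id, " has ", length(track$scores),
         " scores but alignment has ", og_length(og), " columns",
         call. = FALSE)
  }
  keep <- track$scores >= threshold
  if (!any(keep) && og_length(og) > 0L) {
    warning("all ", og_length(og), " columns of ", og$id,
            " fall below the confidence threshold ", threshold)
  }
  out <- og
  out$mat <- og$mat[, keep, drop = FALSE]
  out
}

# rows carrying at least one informative residue
.nonempty_rows <- function(og) {
  if (nrow(og$mat) == 0L) return(logical(0))
  if (ncol(og$mat) == 0L) return(rep(FALSE, nrow(og$mat)))
  apply(og$mat, 1L, function(r) any(!(r %in% .missing_chars)))
}

#' Gene occupancy of an orthogroup
#'
#' The number of distinct taxa with at least one informative residue in the
#' locus.  Rows consisting entirely of gaps (`-`) and missing symbols (`?`)
#' do not count: a taxon whose row was emptied by site masking contributes
#' no data.
#'
#' @param og an [og_alignment].
#' @return integer in `[0, nrow]`.
#' @export
occupancy <- function(og) sum(.nonempty_rows(og))

#' Select orthogroups by minimum occupancy
#'
#' Retains the loci whose [occupancy()] is at least `min_taxa`; the taxon
#' universe is unchanged.  This is the matrix-construction step of
#' occupancy-threshold supermatrix design: e.g. requiring presence in 55 of
#' 108 taxa targets 50% gene occupancy.
#'
#' @param s an [og_set].
#' @param min_taxa non-negative integer occupancy threshold.
#' @return an [og_set] with the retained loci, original order.
#' @export
select_by_occupancy <- function(s, min_taxa) {
  stopifnot(min_taxa >= 0)
  keep <- vapply(s$loci, function(og) occupancy(og) >= min_taxa, logical(1))
  out <- s
  out$loci <- s$loci[keep]
  out
}

#' Occupancy count implied by a target fraction
#'
#' Converts a target gene-occupancy fraction into the minimum-taxon count
#' used by [select_by_occupancy()].  Published matrices state fractions
#' ("minimum gene occupancy of 50%") whose printed counts do not always
#' follow one rounding rule, so the conversion is explicit about policy:
#'
#' * `ceil` — `ceiling(fraction * n_taxa)`, the smallest count whose
#'   fraction is at least the target (default);
#' * `floor_plus_one` — `floor(fraction * n_taxa) + 1`, strictly more than
#'   the target when it lands on an integer (50% of 108 gives 55);
#' * `explicit` — pass a published count through unchanged; its implied
#'   fraction is reported via `message()` for the log.
#'
#' @param n_taxa size of the taxon universe.
#' @param fraction target occupancy fraction in `(0, 1]`.
#' @param rounding conversion policy (see above).
#' @param count the explicit count (only with `rounding = "explicit"`).
#' @return integer occupancy threshold.
#' @examples
#' min_taxa_for_fraction(108, 0.5)                     # 54
#' min_taxa_for_fraction(108, 0.5, "floor_plus_one")   # 55
#' @export
min_taxa_for_fraction <- function(n_taxa, fraction,
                                  rounding = c("ceil", "floor_plus_one",
                                               "explicit"),
                                  count = NULL) {
  rounding <- match.arg(rounding)
  if (rounding == "explicit") {
    if (is.null(count)) stop("rounding = 'explicit' requires a count",
                             call. = FALSE)
    count <- as.integer(count)
    message(sprintf("explicit occupancy threshold %d of %d taxa (%.1f%%)",
                    count, n_taxa, 100 * count / n_taxa))
    return(count)
  }
  if (fraction <= 0 || fraction > 1) {
    stop("occupancy fraction must lie in (0, 1]", call. = FALSE)
  }
  switch(rounding,
         ceil = as.integer(ceiling(fraction * n_taxa)),
         floor_plus_one = as.integer(floor(fraction * n_taxa)) + 1L)
}

#' Percent pairwise identity between two aligned rows
#'
#' Fraction of comparable positions at which the two rows carry the same
#' canonical residue.  Only the canonical states of the alphabet are
#' compared; gaps, `?`, stops and ambiguity letters are uninformative.
#' Under `exclude_pairs_with_gap` (default) a position where either row is
#' uninformative is dropped from the denominator; under `count_as_mismatch`
#' the denominator is the full alignment length and such positions count as
#' mismatches.  Gap-rich rows would otherwise conflate missingness with
#' divergence, hence the default.
#'
#' @param a,b character vectors of residues, equal length.
#' @param gap_policy `"exclude_pairs_with_gap"` or `"count_as_mismatch"`.
#' @param alphabet alphabet of the rows.
#' @return identity in `[0, 1]`, or `NA` when no position is comparable.
#' @export
pairwise_identity <- function(a, b,
                              gap_policy = c("exclude_pairs_with_gap",
                                             "count_as_mismatch"),
                              alphabet = "amino20") {
  gap_policy <- match.arg(gap_policy)
  if (length(a) != length(b)) stop("rows have different lengths", call. = FALSE)
  canon <- .canonical_states(alphabet)
  comparable <- (a %in% canon) & (b %in% canon)
  matches <- sum(a[comparable] == b[comparable])
  denom <- switch(gap_policy,
                  exclude_pairs_with_gap = sum(comparable),
                  count_as_mismatch = length(a))
  if (denom == 0L) return(NA_real_)
  matches / denom
}

#' Locus conservation score
#'
#' Mean percent pairwise identity over all unordered pairs of non-empty rows
#' — the accumulated-conservation value of a locus, normalised to `[0, 1]`.
#' High values mean a conserved (slow-evolving) locus; `1 - conservation`
#' serves as the evolutionary-rate proxy used for rate-tail trimming.  The
#' raw accumulated sum over pairs is available as `statistic = "sum"`.
#'
#' @param og an [og_alignment] with at least two non-empty rows.
#' @param gap_policy passed to [pairwise_identity()].
#' @param statistic `"mean"` (normalised, default) or `"sum"` (raw
#'   accumulated identity over pairs).
#' @return conservation score; pairs with no comparable positions are
#'   excluded from the mean.
#' @export
locus_conservation <- function(og,
                               gap_policy = c("exclude_pairs_with_gap",
                                              "count_as_mismatch"),
                               statistic = c("mean", "sum")) {
  gap_policy <- match.arg(gap_policy)
  statistic <- match.arg(statistic)
  mat <- og$mat[.nonempty_rows(og), , drop = FALSE]
  n <- nrow(mat)
  if (n < 2L) {
    stop("conservation undefined for ", og$id, ": fewer than 2 non-empty rows",
         call. = FALSE)
  }
  pairs <- utils::combn(n, 2L)
  ids <- apply(pairs, 2L, function(p) {
    pairwise_identity(mat[p[1L], ], mat[p[2L], ], gap_policy, og$alphabet)
  })
  ids <- ids[!is.na(ids)]
  if (length(ids) == 0L) {
    stop("conservation undefined for ", og$id, ": no comparable residue pairs",
         call. = FALSE)
  }
  switch(statistic, mean = mean(ids), sum = sum(ids))
}

#' Rank loci by conservation
#'
#' Computes [locus_conservation()] for every locus and ranks them from most
#' conserved (slowest evolving) to least conserved (fastest evolving), ties
#' broken by orthogroup id for determinism.  Loci with fewer than two
#' non-empty rows have no defined score and are flagged.
#'
#' @param s an [og_set].
#' @inheritParams locus_conservation
#' @return data.frame with columns `locus`, `conservation` (`NA` where
#'   undefined) and `rank` (1 = slowest; `NA` for undefined loci), one row
#'   per locus in set order.
#' @export
rate_table <- function(s, gap_policy = c("exclude_pairs_with_gap",
                                         "count_as_mismatch")) {
  gap_policy <- match.arg(gap_policy)
  cons <- vapply(s$loci, function(og) {
    if (sum(.nonempty_rows(og)) < 2L) return(NA_real_)
    tryCatch(locus_conservation(og, gap_policy), error = function(e) NA_real_)
  }, numeric(1))
  df <- data.frame(locus = names(s$loci), conservation = cons,
                   rank = NA_integer_, stringsAsFactors = FALSE,
                   row.names = NULL)
  ok <- !is.na(df$conservation)
  # most conserved first; ties by locus id
  o <- order(-df$conservation[ok], df$locus[ok], method = "radix")
  df$rank[ok][o] <- seq_len(sum(ok))
  df
}

#' Trim rate tails from an orthogroup set
#'
#' Discards the orthogroups at the extremes of the evolutionary-rate
#' spectrum before concatenation: `q_low` is the fraction discarded at the
#' low-rate end (the most conserved, slowest-evolving loci) and `q_high` the
#' fraction discarded at the high-rate end (the least conserved,
#' fastest-evolving).  Rate is proxied by `1 - locus_conservation`; each tail
#' removes `floor(q * N)` loci, where `N` counts the loci with a defined
#' conservation score.  The surviving middle is returned in original input
#' order.  Loci whose conservation is undefined (fewer than two non-empty
#' rows) are dropped with a warning.
#'
#' @param s an [og_set].
#' @param q_low,q_high tail fractions in `[0, 1)` with `q_low + q_high < 1`
#'   (defaults 0.2 and 0.2, the conventional 20/20 trim).
#' @inheritParams locus_conservation
#' @return an [og_set] with the retained loci.
#' @export
trim_rate_tails <- function(s, q_low = 0.2, q_high = 0.2,
                            gap_policy = c("exclude_pairs_with_gap",
                                           "count_as_mismatch")) {
  gap_policy <- match.arg(gap_policy)
  if (q_low < 0 || q_high < 0 || q_low + q_high >= 1) {
    stop("tail fractions must be non-negative with q_low + q_high < 1",
         call. = FALSE)
  }
  rt <- rate_table(s, gap_policy)
  undef <- rt$locus[is.na(rt$rank)]
  if (length(undef) > 0L) {
    warning("dropping ", length(undef),
            " locus/loci with undefined conservation: ",
            paste(undef, collapse = ", "))
  }
  ranked <- rt[!is.na(rt$rank), , drop = FALSE]
  ranked <- ranked[order(ranked$rank), , drop = FALSE]
  n <- nrow(ranked)
  drop_slow <- floor(q_low * n)    # top of the ranking: most conserved
  drop_fast <- floor(q_high * n)   # bottom: least conserved
  keep_ids <- if (n == 0L) character(0) else {
    ranked$locus[seq_len(n) > drop_slow & seq_len(n) <= n - drop_fast]
  }
  out <- s
  out$loci <- s$loci[names(s$loci) %in% keep_ids]
  out
}
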