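# Fixture builders and deliberately naive reference implementations used to
# cross-check the package's vectorised operations.  The oracles work on
# plain named character vectors of sequence strings and use explicit loops.

make_aln <- function(id, seqs, alphabet = "amino20") {
  og_alignment(id, unlist(seqs), alphabet)
}

# random amino-acid locus over a taxon set, with optional all-missing rows
random_locus <- function(id, taxa, len, p_present = 0.8, p_gap = 0.05) {
  present <- taxa[stats::runif(length(taxa)) < p_present]
  if (length(present) == 0L) present <- taxa[1L]
  seqs <- vapply(present, function(t) {
    res <- sample(supermat::AA20, len, replace = TRUE)
    res[stats::runif(len) < p_gap] <- "-"
    paste(res, collapse = "")
  }, character(1))
  og_alignment(id, seqs)
}

rows_as_strings <- function(mat) apply(mat, 1L, paste, collapse = "")

# --- oracles (string-based, loop-based, independent of package internals) ---

oracle_mask <- function(seqs, scores, threshold) {
  out <- stats::setNames(rep("", length(seqs)), names(seqs))
  for (j in seq_along(scores)) {
    if (scores[j] >= threshold) {
      for (t in names(seqs)) {
        out[t] <- paste0(out[t], substr(seqs[t], j, j))
      }
    }
  }
  out
}

oracle_occupancy <- function(seqs) {
  n <- 0L
  for (s in seqs) {
    chars <- strsplit(s, "")[[1L]]
    informative <- FALSE
    for (c in chars) if (c != "-" && c != "?") informative <- TRUE
    if (informative && nchar(s) > 0L) n <- n + 1L
  }
  n
}

oracle_missingness <- function(seqs) {
  miss <- 0L; total <- 0L
  for (s in seqs) {
    for (c in strsplit(s, "")[[1L]]) {
      total <- total + 1L
      if (c == "-" || c == "?") miss <- miss + 1L
    }
  }
  100 * miss / total
}

# concatenate a list of named sequence-string vectors over a taxon vector
oracle_concat <- function(loci_seqs, taxa) {
  rows <- stats::setNames(rep("", length(taxa)), taxa)
  for (seqs in loci_seqs) {
    len <- nchar(seqs[[1L]])
    for (t in taxa) {
      rows[t] <- paste0(rows[t],
                        if (t %in% names(seqs)) seqs[[t]]
                        else strrep("?", len))
    }
  }
  rows
}

oracle_identity <- function(a, b, policy = "exclude_pairs_with_gap") {
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  canon <- supermat::AA20
  match_n <- 0L; comp_n <- 0L
  for (j in seq_along(av)) {
    if (av[j] %in% canon && bv[j] %in% canon) {
      comp_n <- comp_n + 1L
      if (av[j] == bv[j]) match_n <- match_n + 1L
    }
  }
  denom <- if (policy == "count_as_mismatch") length(av) else comp_n
  if (denom == 0L) return(NA_real_)
  match_n / denom
}

# alignment holding each of the 20 canonical amino acids at least once
all20_alignment <- function() {
  og_alignment("all20", c(tA = "ACDEFGHIKL", tB = "MNPQRSTVWY",
                          tC = "AC-EFGHIKL"))
}
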