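test_that("site masking keeps exactly the columns at or above threshold", {
  og <- make_aln("og1", c(tA = "MKQR", tB = "MRQW"))
  tr <- score_track("og1", c(7, 4, 5, 2))
  m <- mask_sites(og, tr, threshold = 5)
  expect_equal(og_length(m), 2L)
  expect_identical(og_sequences(m), c(tA = "MQ", tB = "MQ"))  # columns 1, 3

  # all columns pass -> identity; none pass -> empty with a warning
  expect_identical(mask_sites(og, score_track("og1", rep(9, 4)))$mat, og$mat)
  expect_warning(empty <- mask_sites(og, score_track("og1", rep(1, 4))),
                 "below the confidence threshold")
  expect_equal(og_length(empty), 0L)
  expect_error(mask_sites(og, score_track("og1", c(1, 2))), "4 columns")
})

test_that("masking agrees with the column-filter oracle and commutes with row subsetting", {
  set.seed(42)
  for (i in 1:20) {
    og <- random_locus(paste0("og", i), paste0("t", 1:6), len = 40)
    scores <- round(stats::runif(40, 0, 10), 2)
    tr <- score_track(og$id, scores)
    masked <- suppressWarnings(mask_sites(og, tr))
    expect_equal(og_length(masked), sum(scores >= 5))
    expect_identical(og_sequences(masked),
                     oracle_mask(og_sequences(og), scores, 5))
    # commutes with row subsetting
    keep <- og_taxa(og)[seq_len(max(1, nrow(og$mat) - 2))]
    sub_then_mask <- suppressWarnings(mask_sites(
      og_alignment(og$id, og$mat[keep, , drop = FALSE]), tr))
    mask_then_sub <- masked$mat[keep, , drop = FALSE]
    expect_identical(sub_then_mask$mat, mask_then_sub)
  }
})

test_that("occupancy counts taxa with informative residues only", {
  og <- make_aln("og1", c(tA = "MK", tB = "MR", tC = "QQ", tD = "??"))
  expect_equal(occupancy(og), 3L)
  expect_equal(occupancy(make_aln("og1", c(tA = "--", tB = "-?"))), 0L)
  # zero-column alignment (fully masked) has occupancy 0
  masked <- suppressWarnings(
    mask_sites(og, score_track("og1", c(0, 0))))
  expect_equal(occupancy(masked), 0L)
  set.seed(7)
  for (i in 1:15) {
    r <- random_locus("x", paste0("t", 1:8), 30)
    expect_equal(occupancy(r), oracle_occupancy(og_sequences(r)))
  }
})

test_that("occupancy selection keeps loci at or above the threshold, idempotently and monotonically", {
  taxa <- paste0("t", 1:5)
  mk <- function(id, n) {
    og_alignment(id, stats::setNames(rep("MKQR", n), taxa[seq_len(n)]))
  }
  s <- og_set(list(mk("a", 3), mk("b", 5), mk("c", 2)),
              universe = taxon_universe(taxa))
  expect_identical(names(select_by_occupancy(s, 3)$loci), c("a", "b"))
  expect_identical(select_by_occupancy(s, 0), s)              # identity
  expect_equal(n_loci(select_by_occupancy(s, 6)), 0L)         # > universe
  # idempotent and monotone in min_taxa
  s3 <- select_by_occupancy(s, 3)
  expect_identical(select_by_occupancy(s3, 3), s3)
  counts <- vapply(0:6, function(k) n_loci(select_by_occupancy(s, k)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("fraction-to-count conversion follows the declared rounding policy", {
  expect_identical(min_taxa_for_fraction(108, 0.5), 54L)
  expect_identical(min_taxa_for_fraction(108, 0.5, "floor_plus_one"), 55L)
  expect_identical(min_taxa_for_fraction(10, 1.0), 10L)
  expect_message(k <- min_taxa_for_fraction(108, 0.5, "explicit", count = 55),
                 "50.9%")
  expect_identical(k, 55L)
  expect_error(min_taxa_for_fraction(108, 0), "fraction")
  expect_error(min_taxa_for_fraction(108, 1.2), "fraction")
  expect_error(min_taxa_for_fraction(108, 0.5, "explicit"), "count")
})

test_that("pairwise identity handles gaps under both policies", {
  A <- strsplit("AAAA", "")[[1]]
  expect_equal(pairwise_identity(A, strsplit("AAAT", "")[[1]]), 0.75)
  expect_equal(pairwise_identity(A, A), 1.0)
  a <- strsplit("A-AA", "")[[1]]; b <- strsplit("AAAA", "")[[1]]
  expect_equal(pairwise_identity(a, b, "exclude_pairs_with_gap"), 1.0)
  expect_equal(pairwise_identity(a, b, "count_as_mismatch"), 0.75)
  expect_true(is.na(pairwise_identity(strsplit("--", "")[[1]],
                                      strsplit("AA", "")[[1]])))
  expect_error(pairwise_identity(A, A[1:2]), "lengths")
})

test_that("pairwise identity is symmetric and column-permutation invariant", {
  set.seed(11)
  for (i in 1:20) {
    a <- sample(c(AA20, "-", "?"), 30, replace = TRUE)
    b <- sample(c(AA20, "-", "?"), 30, replace = TRUE)
    for (pol in c("exclude_pairs_with_gap", "count_as_mismatch")) {
      expect_equal(pairwise_identity(a, b, pol), pairwise_identity(b, a, pol))
      expect_equal(pairwise_identity(a, b, pol),
                   oracle_identity(paste(a, collapse = ""),
                                   paste(b, collapse = ""), pol))
      perm <- sample(30)
      expect_equal(pairwise_identity(a[perm], b[perm], pol),
                   pairwise_identity(a, b, pol))
    }
  }
})

test_that("locus conservation is the mean pairwise identity over non-empty rows", {
  expect_equal(locus_conservation(make_aln("x", c(a = "MKQR", b = "MKQR"))), 1)
  expect_equal(locus_conservation(make_aln("x", c(a = "AAAA", b = "AAAT"))),
               0.75)
  # pair identities {1.0, 0.5, 0.5} -> mean 2/3
  og3 <- make_aln("x", c(a = "AAAA", b = "AAAA", c = "AATT"))
  expect_equal(locus_conservation(og3), 2 / 3)
  expect_equal(locus_conservation(og3, statistic = "sum"), 2.0)
  # all-missing rows are excluded; < 2 informative rows is an error
  og_pad <- make_aln("x", c(a = "AAAA", b = "AAAT", c = "????"))
  expect_equal(locus_conservation(og_pad), 0.75)
  expect_error(locus_conservation(make_aln("x", c(a = "AAAA", b = "????"))),
               "fewer than 2")
  # invariant under row order
  set.seed(3)
  og <- random_locus("x", paste0("t", 1:6), 25, p_present = 1)
  og_rev <- og_alignment("x", og$mat[rev(seq_len(nrow(og$mat))), ])
  expect_equal(locus_conservation(og), locus_conservation(og_rev))
})

test_that("rate table ranks most-conserved first with id tie-breaks", {
  s <- og_set(list(make_aln("ogB", c(a = "AAAA", b = "AAAT")),   # 0.75
                   make_aln("ogA", c(a = "AAAA", b = "AAAT")),   # 0.75 tie
                   make_aln("ogC", c(a = "AAAA", b = "AAAA")),   # 1.00
                   make_aln("ogD", c(a = "AAAA", b = "????"))))  # undefined
  rt <- rate_table(s)
  expect_identical(rt$locus, c("ogA", "ogB", "ogC", "ogD"))
  expect_identical(rt$rank, c(2L, 3L, 1L, NA_integer_))
})

test_that("rate-tail trimming drops floor(q*N) loci from each extreme", {
  taxa <- c("a", "b")
  # conservation gradient: locus i has i mismatches out of 20
  loci <- lapply(1:10, function(i) {
    og_alignment(sprintf("og%02d", i),
                 c(a = strrep("A", 20),
                   b = paste0(strrep("T", i), strrep("A", 20 - i))))
  })
  s <- og_set(loci)
  kept <- trim_rate_tails(s, 0.2, 0.2)
  expect_equal(n_loci(kept), 6L)
  # most conserved (og01, og02) and least conserved (og09, og10) are gone
  expect_identical(names(kept$loci), sprintf("og%02d", 3:8))
  expect_identical(trim_rate_tails(s, 0, 0), s)
  expect_error(trim_rate_tails(s, 0.5, 0.5), "q_low \\+ q_high")
  # retention arithmetic on assorted sizes and fractions
  for (n in c(3, 7, 10)) {
    ss <- og_set(loci[seq_len(n)])
    for (q in list(c(0.2, 0.2), c(0.1, 0.3), c(0, 0.25))) {
      expect_equal(n_loci(trim_rate_tails(ss, q[1], q[2])),
                   n - floor(q[1] * n) - floor(q[2] * n))
    }
  }
})

test_that("loci with undefined conservation are dropped from trimming with a warning", {
  s <- og_set(list(make_aln("og1", c(a = "AAAA", b = "AAAT")),
                   make_aln("og2", c(a = "AAAA", b = "AATT")),
                   make_aln("og3", c(a = "AAAA", b = "????"))))
  expect_warning(kept <- trim_rate_tails(s, 0, 0), "undefined conservation")
  expect_identical(names(kept$loci), c("og1", "og2"))
})
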