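test_that("concatenation joins loci with '?' fill and cumulative partitions", {
  s <- og_set(list(make_aln("og1", c(tA = "MKQRW", tB = "MKQRW")),
                   make_aln("og2", c(tA = "CCCCCCC"))),
              universe = taxon_universe(c("tA", "tB")))
  sm <- concatenate(s)
  expect_equal(ncol(sm$mat), 12L)
  expect_identical(sm$scheme$start, c(1L, 6L))
  expect_identical(sm$scheme$end, c(5L, 12L))
  seqs <- rows_as_strings(sm$mat)
  expect_identical(unname(seqs["tB"]), paste0("MKQRW", strrep("?", 7)))
  # single locus: row content equals locus rows
  s1 <- og_set(list(make_aln("og1", c(tA = "MKQR", tB = "MKQW"))))
  expect_identical(rows_as_strings(concatenate(s1)$mat),
                   og_sequences(s1$loci$og1))
  # empty set is a typed error
  s0 <- s; s0$loci <- list()
  expect_error(concatenate(s0), class = "supermat_empty_matrix")
})

test_that("every partition range maps back to its source locus bit-exactly", {
  set.seed(21)
  loci <- lapply(1:8, function(i) {
    random_locus(sprintf("og%02d", i), paste0("t", 1:6),
                 len = sample(10:40, 1))
  })
  s <- og_set(loci)
  sm <- concatenate(s)
  for (k in seq_len(nrow(sm$scheme))) {
    og <- s$loci[[sm$scheme$locus[k]]]
    block <- sm$mat[og_taxa(og), sm$scheme$start[k]:sm$scheme$end[k],
                    drop = FALSE]
    expect_identical(unname(block), unname(og$mat))
  }
})

test_that("concatenation is associative under locus-list splitting", {
  set.seed(8)
  loci <- lapply(1:6, function(i) {
    random_locus(sprintf("og%d", i), paste0("t", 1:5), len = 15)
  })
  u <- taxon_universe(paste0("t", 1:5))
  whole <- concatenate(og_set(loci, u))
  left <- concatenate(og_set(loci[1:3], u))
  right <- concatenate(og_set(loci[4:6], u))
  expect_identical(whole$mat, cbind(left$mat, right$mat))
})

test_that("missingness counts '?' and '-' cells against the matrix size", {
  u <- taxon_universe(c("tA", "tB"))
  s <- og_set(list(make_aln("og1", c(tA = strrep("M", 10), tB = strrep("K", 10))),
                   make_aln("og2", c(tA = strrep("W", 10)))), universe = u)
  sm <- concatenate(s)
  expect_equal(missingness(sm), 25.0)          # 10 of 40 cells
  expect_equal(missingness(sm, "absent_fill"), 25.0)
  full <- concatenate(og_set(list(make_aln("og1", c(tA = "MK", tB = "MK")))))
  expect_equal(missingness(full), 0.0)
  # gaps count under "all" but not under "absent_fill"
  g <- concatenate(og_set(list(make_aln("og1", c(tA = "M-", tB = "MK")))))
  expect_equal(missingness(g), 25.0)
  expect_equal(missingness(g, "absent_fill"), 0.0)
  empty_sm <- supermatrix(u, c(tA = "", tB = ""),
                          partition_scheme(character(0), integer(0),
                                           integer(0)))
  expect_error(missingness(empty_sm), "undefined")
})

test_that("missingness matches the brute-force cell scan and ignores ordering", {
  set.seed(13)
  for (i in 1:10) {
    loci <- lapply(1:5, function(j) {
      random_locus(sprintf("og%d", j), paste0("t", 1:6), len = 20,
                   p_present = 0.7, p_gap = 0.1)
    })
    s <- og_set(loci, universe = taxon_universe(paste0("t", 1:6)))
    sm <- concatenate(s)
    expect_equal(missingness(sm),
                 oracle_missingness(apply(sm$mat, 1, paste, collapse = "")))
    # invariant under taxon and column permutation
    perm <- sm
    perm$mat <- sm$mat[sample(nrow(sm$mat)), sample(ncol(sm$mat))]
    expect_equal(missingness(perm), missingness(sm))
  }
})

test_that("occupancy reports reconcile with per-locus occupancy and missingness", {
  set.seed(17)
  loci <- lapply(1:6, function(j) {
    random_locus(sprintf("og%d", j), paste0("t", 1:7), len = 12,
                 p_present = 0.6)
  })
  s <- og_set(loci, universe = taxon_universe(paste0("t", 1:7)))
  sm <- concatenate(s)
  rep <- occupancy_report(s, sm)
  expect_identical(rep$per_locus$occupancy,
                   vapply(s$loci, occupancy, integer(1), USE.NAMES = FALSE))
  expect_equal(rep$missing_pct, missingness(sm))
  expect_equal(rep$per_taxon$fraction, rep$per_taxon$n_loci / n_loci(s))
  # taxon present in every locus has count == n_loci
  full <- og_set(list(make_aln("a", c(tA = "MK", tB = "MK")),
                      make_aln("b", c(tA = "QQ"))))
  fr <- occupancy_report(full, concatenate(full))
  expect_equal(fr$per_taxon$n_loci[fr$per_taxon$taxon == "tA"], 2L)
  # mismatched inputs are rejected
  other <- og_set(list(make_aln("zzz", c(tA = "MK"))))
  expect_error(occupancy_report(other, sm), "not built from")
})
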