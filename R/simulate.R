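# Synthetic orthogroup-dataset generator.  Emulates the statistical
# structure of OMA-style orthogroup output that the pipeline assumes:
# heterogeneous taxon occupancy (per-taxon capture probabilities),
# per-locus evolutionary-rate multipliers (conservation gradient), and a
# minority of unreliable columns carrying low confidence scores.  Ground
# truth is returned for parameter-recovery tests.

#' Simulation parameters
#'
#' Defaults describe a desk-scale transcriptomic orthogroup study: 20 taxa,
#' 100 loci of 100-350 aligned amino acids (mean ~225, matching typical
#' published orthogroup lengths), exponential branch lengths of mean 0.05
#' substitutions/site (giving a mean pairwise tree depth of roughly 0.5
#' substitutions/site on a 20-taxon random tree), lognormal rate multipliers
#' with `sdlog = 0.5`, Beta(6, 2) per-taxon capture probabilities (mean
#' 0.75, i.e. ~25% absent-taxon cells before other filtering), and 10%
#' unreliable columns whose confidence scores are drawn from U[0, 3]
#' against U[6, 10] for reliable columns — well separated around the
#' conventional masking threshold of 5.
#'
#' @param n_taxa number of taxa (>= 3).
#' @param n_loci number of orthogroups (>= 1).
#' @param len_range integer range `[Lmin, Lmax]` of locus lengths (columns).
#' @param branch_mean mean of the exponential branch-length distribution
#'   (substitutions/site at rate multiplier 1).
#' @param rate_meanlog,rate_sdlog lognormal parameters of the per-locus rate
#'   multiplier.
#' @param capture_shape1,capture_shape2 Beta parameters of the per-taxon
#'   capture probability (probability that a taxon's sequence is recovered
#'   in any given locus).
#' @param noisy_fraction fraction of columns per locus replaced by random
#'   residues and flagged with low confidence scores.
#' @param score_low,score_high `c(min, max)` of the uniform confidence-score
#'   distributions for noisy and clean columns.
#' @param seed integer seed driving every random draw.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_taxa = 20, n_loci = 100, len_range = c(100L, 350L),
                       branch_mean = 0.05,
                       rate_meanlog = 0, rate_sdlog = 0.5,
                       capture_shape1 = 6, capture_shape2 = 2,
                       noisy_fraction = 0.1,
                       score_low = c(0, 3), score_high = c(6, 10),
                       seed = 1L) {
  p <- list(n_taxa = as.integer(n_taxa), n_loci = as.integer(n_loci),
            len_range = as.integer(len_range), branch_mean = branch_mean,
            rate_meanlog = rate_meanlog, rate_sdlog = rate_sdlog,
            capture_shape1 = capture_shape1, capture_shape2 = capture_shape2,
            noisy_fraction = noisy_fraction,
            score_low = score_low, score_high = score_high,
            seed = as.integer(seed))
  stopifnot(p$n_taxa >= 3L, p$n_loci >= 1L,
            length(p$len_range) == 2L, p$len_range[1L] <= p$len_range[2L],
            p$len_range[1L] >= 1L,
            p$branch_mean > 0, p$rate_sdlog >= 0,
            p$capture_shape1 > 0, p$capture_shape2 > 0,
            p$noisy_fraction >= 0, p$noisy_fraction <= 1)
  structure(p, class = "sim_params")
}

#' Simulate a random rooted tree
#'
#' Random topology by sequential random joins with i.i.d. exponential branch
#' lengths; deterministic given the seed.  A rooted binary tree on `n` tips
#' has `n - 1` internal nodes and `2n - 2` branches.
#'
#' @param n_taxa number of tips (>= 3).
#' @param branch_mean mean branch length.
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (as inside [simulate_dataset()]).
#' @param labels tip labels; default `taxon01`, `taxon02`, ...
#' @return an [ape::rtree()]-style `phylo` object, rooted.
#' @export
simulate_tree <- function(n_taxa, branch_mean = 0.05, seed = NULL,
                          labels = NULL) {
  stopifnot(n_taxa >= 3L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(labels)) labels <- sprintf("taxon%02d", seq_len(n_taxa))
  tree <- ape::rtree(n_taxa, rooted = TRUE,
                     br = function(n) stats::rexp(n, rate = 1 / branch_mean))
  # rtree labels tips t1..tn in a random order; reassign ours preserving
  # the (random) attachment order
  tree$tip.label <- labels[as.integer(sub("^t", "", tree$tip.label))]
  tree
}

# evolve one sequence of length L along one branch under the 20-state
# equal-exchangeability model; expected substitutions = rate * t, with
# P(same) = 1/20 + (19/20) exp(-(20/19) rate t)
.evolve_branch <- function(idx, rate, t) {
  L <- length(idx)
  p_same <- 1 / 20 + (19 / 20) * exp(-(20 / 19) * rate * t)
  change <- stats::runif(L) >= p_same
  n <- sum(change)
  if (n > 0L) {
    # uniform over the 19 other states: shift by 1..19 modulo 20
    idx[change] <- ((idx[change] - 1L +
                       sample.int(19L, n, replace = TRUE)) %% 20L) + 1L
  }
  idx
}

# simulate one locus alignment (all taxa present) along a rooted tree
.simulate_locus_matrix <- function(tree, rate, L) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  seqs <- vector("list", n_node)
  root <- n_tip + 1L
  seqs[[root]] <- sample.int(20L, L, replace = TRUE)
  # preorder: parents before children
  tree <- ape::reorder.phylo(tree, "cladewise")
  edges <- tree$edge
  el <- tree$edge.length
  for (i in seq_len(nrow(edges))) {
    seqs[[edges[i, 2L]]] <- .evolve_branch(seqs[[edges[i, 1L]]], rate, el[i])
  }
  mat <- do.call(rbind, lapply(seq_len(n_tip), function(i) AA20[seqs[[i]]]))
  rownames(mat) <- tree$tip.label
  mat[order(rownames(mat)), , drop = FALSE]
}

#' Simulate an orthogroup dataset with ground truth
#'
#' For each locus: length drawn uniformly from `len_range`; a root sequence
#' i.i.d. uniform over the 20 amino acids evolved along a shared random tree
#' under the 20-state equal-exchangeability Markov model, the expected number
#' of substitutions on a branch of length `t` being `r * t` with `r` the
#' locus's lognormal rate multiplier.  After simulation each taxon's row is
#' deleted with probability `1 - c_i`, where `c_i` is the taxon's Beta-drawn
#' capture probability (whole-row dropout, matching orthogroup semantics).
#' Finally a fraction `noisy_fraction` of columns is overwritten with i.i.d.
#' uniform residues and assigned confidence scores from the low
#' distribution; all other columns score from the high distribution.
#'
#' @param params a [sim_params()] object.
#' @return list with elements
#'   * `og_set` — the simulated [og_set] (absent taxa simply have no row),
#'   * `tracks` — named list of [score_track] objects, one per locus,
#'   * `truth` — list with `rates` (named per-locus multipliers), `capture`
#'     (named per-taxon capture probabilities), `noisy_cols` (named list of
#'     1-based noisy column indices), `tree` (Newick string).
#' @export
simulate_dataset <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  taxa <- sprintf("taxon%02d", seq_len(params$n_taxa))
  tree <- simulate_tree(params$n_taxa, params$branch_mean, seed = NULL,
                        labels = taxa)
  capture <- stats::setNames(
    stats::rbeta(params$n_taxa, params$capture_shape1, params$capture_shape2),
    taxa)
  rates <- stats::setNames(
    stats::rlnorm(params$n_loci, params$rate_meanlog, params$rate_sdlog),
    sprintf("og%04d", seq_len(params$n_loci)))
  loci <- vector("list", params$n_loci)
  tracks <- vector("list", params$n_loci)
  noisy_cols <- vector("list", params$n_loci)
  for (g in seq_len(params$n_loci)) {
    id <- names(rates)[g]
    L <- sample(seq(params$len_range[1L], params$len_range[2L]), 1L)
    mat <- .simulate_locus_matrix(tree, rates[[g]], L)
    present <- stats::runif(params$n_taxa) < capture[rownames(mat)]
    mat <- mat[present, , drop = FALSE]
    n_noisy <- round(params$noisy_fraction * L)
    noisy <- sort(sample.int(L, n_noisy))
    if (n_noisy > 0L && nrow(mat) > 0L) {
      mat[, noisy] <- AA20[sample.int(20L, nrow(mat) * n_noisy,
                                      replace = TRUE)]
    }
    scores <- stats::runif(L, params$score_high[1L], params$score_high[2L])
    if (n_noisy > 0L) {
      scores[noisy] <- stats::runif(n_noisy, params$score_low[1L],
                                    params$score_low[2L])
    }
    loci[[g]] <- og_alignment(id, mat, "amino20")
    tracks[[g]] <- score_track(id, scores)
    noisy_cols[[g]] <- noisy
  }
  names(tracks) <- names(rates)
  names(noisy_cols) <- names(rates)
  list(og_set = og_set(loci, universe = taxon_universe(taxa)),
       tracks = tracks,
       truth = list(rates = rates, capture = capture,
                    noisy_cols = noisy_cols,
                    tree = ape::write.tree(tree)))
}

#' Write a simulated dataset to disk
#'
#' Emits one FASTA file and one ZORRO-format score file per locus, the
#' generating tree in Newick, and the ground truth as JSON — the layout
#' [read_og_directory()] and [read_score_directory()] consume.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (og in sim$og_set$loci) {
    write_fasta_alignment(og, file.path(dir, paste0(og$id, ".fasta")))
  }
  for (tr in sim$tracks) {
    write_score_track(tr, file.path(dir, paste0(tr$og_id, ".zorro")))
  }
  writeLines(sim$truth$tree, file.path(dir, "tree.nwk"))
  jsonlite::write_json(
    list(rates = as.list(sim$truth$rates),
         capture = as.list(sim$truth$capture),
         noisy_cols = sim$truth$noisy_cols),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
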