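# Composite pipeline: mask -> occupancy-select -> [rate-trim] -> [recode]
# -> concatenate, with a machine-readable manifest.  Masking runs before
# occupancy selection because culling columns can empty rows and therefore
# change occupancy.

#' Run the supermatrix-construction pipeline
#'
#' Executes the fixed stage order
#' `mask -> occupancy-select -> [rate-trim] -> [recode] -> concatenate`
#' on a directory of orthogroup alignments (or a simulated dataset) and
#' writes the supermatrix (FASTA + relaxed PHYLIP), partition files (RAxML +
#' NEXUS), an occupancy/missingness report, and a JSON manifest recording
#' parameters, seed, input hashes and per-stage locus counts.  The manifest
#' contains nothing volatile, so identical configuration and seed give
#' byte-identical output trees.
#'
#' @param config named list (or path to a YAML file) with keys:
#'   * `input` — directory of per-orthogroup FASTA files, or
#'   * `simulate` — named list of [sim_params()] arguments (used when
#'     `input` is absent);
#'   * `scores` — optional directory of ZORRO score tracks (stems matching
#'     the alignments); required for the masking stage, which is skipped
#'     with a message when absent;
#'   * `mask_threshold` — confidence cutoff (default 5);
#'   * `taxa` — optional character vector (or file of one label per line)
#'     restricting the universe to a clade subset before any filtering;
#'     occupancy fractions are then resolved against the subset size;
#'   * `occupancy` — list with either `min_taxa` (explicit count) or
#'     `fraction` + optional `rounding` (see [min_taxa_for_fraction()]);
#'     default `fraction = 0.5, rounding = "ceil"`;
#'   * `trim` — optional list with `q_low`, `q_high` for
#'     [trim_rate_tails()]; omit to skip trimming;
#'   * `gap_policy` — identity gap policy (default
#'     `"exclude_pairs_with_gap"`);
#'   * `recode` — logical, Dayhoff-recode the selected loci (default
#'     `FALSE`);
#'   * `model` — partition-file model token (default `"LG4X"`);
#'   * `out` — output directory (required);
#'   * `seed` — integer seed for the simulate block (default 1).
#' @return the manifest list, invisibly; side effect: files under
#'   `config$out`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- config
  if (is.null(cfg$out)) {
    stop(errorCondition("config key 'out' (output directory) is required",
                        class = c("supermat_usage_error", "error",
                                  "condition")))
  }
  known <- c("input", "simulate", "scores", "mask_threshold", "taxa",
             "occupancy", "trim", "gap_policy", "recode", "model", "out",
             "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    stop(errorCondition(paste0("unknown config keys: ",
                               paste(unknown, collapse = ", ")),
                        class = c("supermat_usage_error", "error",
                                  "condition")))
  }
  gap_policy <- cfg$gap_policy %||% "exclude_pairs_with_gap"
  threshold <- cfg$mask_threshold %||% 5
  seed <- as.integer(cfg$seed %||% 1L)

  manifest <- list(
    tool = "supermat",
    version = as.character(utils::packageVersion("supermat")),
    seed = seed,
    parameters = list(mask_threshold = threshold, gap_policy = gap_policy,
                      occupancy = cfg$occupancy %||%
                        list(fraction = 0.5, rounding = "ceil"),
                      trim = cfg$trim, recode = isTRUE(cfg$recode),
                      model = cfg$model %||% "LG4X"),
    stages = list()
  )

  # ---- load or simulate -------------------------------------------------
  tracks <- NULL
  if (!is.null(cfg$input)) {
    s <- read_og_directory(cfg$input)
    files <- list.files(cfg$input, pattern = "\\.(fa|fasta|fst)$",
                        full.names = TRUE)
    manifest$input <- list(dir = cfg$input,
                           md5 = as.list(tools::md5sum(files)))
    if (!is.null(cfg$scores)) tracks <- read_score_directory(cfg$scores)
  } else if (!is.null(cfg$simulate)) {
    params <- do.call(sim_params, c(cfg$simulate, list(seed = seed)))
    sim <- simulate_dataset(params)
    s <- sim$og_set
    tracks <- sim$tracks
    manifest$input <- list(simulate = unclass(params))
  } else {
    stop(errorCondition("config needs either 'input' or 'simulate'",
                        class = c("supermat_usage_error", "error",
                                  "condition")))
  }
  manifest$stages$loaded <- n_loci(s)

  # ---- optional taxon subset (clade-enriched runs) ----------------------
  if (!is.null(cfg$taxa)) {
    subset <- cfg$taxa
    if (length(subset) == 1L && file.exists(subset)) {
      subset <- readLines(subset)
      subset <- trimws(subset[nzchar(trimws(subset))])
    }
    missing_taxa <- setdiff(subset, s$universe)
    if (length(missing_taxa) > 0L) {
      stop(errorCondition(paste0("taxa not in dataset: ",
                                 paste(missing_taxa, collapse = ", ")),
                          class = c("supermat_usage_error", "error",
                                    "condition")))
    }
    s$universe <- taxon_universe(subset)
    s$loci <- lapply(s$loci, function(og) {
      og$mat <- og$mat[rownames(og$mat) %in% subset, , drop = FALSE]
      og
    })
    manifest$stages$taxon_subset <- length(subset)
  }

  # ---- mask -------------------------------------------------------------
  if (!is.null(tracks)) {
    s$loci <- lapply(s$loci, function(og) {
      tr <- tracks[[og$id]]
      if (is.null(tr)) {
        stop("no score track for orthogroup ", og$id, call. = FALSE)
      }
      suppressWarnings(mask_sites(og, tr, threshold))
    })
    manifest$stages$masked <- n_loci(s)
  } else {
    message("no score tracks supplied; masking stage skipped")
  }

  # ---- occupancy selection ---------------------------------------------
  occ <- cfg$occupancy %||% list(fraction = 0.5, rounding = "ceil")
  min_taxa <- if (!is.null(occ$min_taxa)) {
    suppressMessages(min_taxa_for_fraction(length(s$universe), 1,
                                           rounding = "explicit",
                                           count = occ$min_taxa))
  } else {
    min_taxa_for_fraction(length(s$universe), occ$fraction,
                          rounding = occ$rounding %||% "ceil")
  }
  manifest$parameters$min_taxa <- min_taxa
  s <- select_by_occupancy(s, min_taxa)
  manifest$stages$occupancy_selected <- n_loci(s)

  # ---- rate trim --------------------------------------------------------
  if (!is.null(cfg$trim)) {
    s <- trim_rate_tails(s, q_low = cfg$trim$q_low %||% 0.2,
                         q_high = cfg$trim$q_high %||% 0.2,
                         gap_policy = gap_policy)
    manifest$stages$rate_trimmed <- n_loci(s)
  }

  if (n_loci(s) == 0L) {
    stop(errorCondition("no orthogroups survive the configured filters",
                        class = c("supermat_empty_matrix", "error",
                                  "condition")))
  }

  # ---- recode -----------------------------------------------------------
  if (isTRUE(cfg$recode)) {
    s$loci <- lapply(s$loci, recode_alignment)
    manifest$stages$recoded <- n_loci(s)
  }

  # ---- concatenate and write -------------------------------------------
  sm <- concatenate(s)
  rep <- occupancy_report(s, sm)
  out <- cfg$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_fasta_supermatrix(sm, file.path(out, "supermatrix.fasta"))
  write_phylip(sm, file.path(out, "supermatrix.phy"))
  write_partitions(sm$scheme, file.path(out, "partitions.raxml"),
                   dialect = "raxml", model = cfg$model %||% "LG4X")
  write_partitions(sm$scheme, file.path(out, "partitions.nex"),
                   dialect = "nexus")
  write_occupancy_table(rep, file.path(out, "occupancy.tsv"))
  manifest$matrix <- list(n_taxa = nrow(sm$mat), n_columns = ncol(sm$mat),
                          n_partitions = nrow(sm$scheme),
                          alphabet = sm$alphabet,
                          missing_pct = rep$missing_pct,
                          absent_fill_pct = rep$absent_fill_pct)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
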