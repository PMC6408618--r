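# Dayhoff-category recoding: collapse the 20 amino acids into six
# exchange-prone classes to reduce compositional heterogeneity and
# saturation in downstream inference.

#' Dayhoff six-state recoding scheme
#'
#' The classic partition of the 20 amino acids into six Dayhoff categories,
#' written with digit state symbols so recoded matrices are directly
#' consumable by multistate inference programs:
#' `0 = AGPST`, `1 = FWY`, `2 = C`, `3 = HKR`, `4 = ILMV`, `5 = EDNQ`.
#'
#' @param name scheme label.
#' @param classes named list mapping each state symbol to its amino-acid
#'   letters; classes must be disjoint.
#' @return a `recoding_scheme` object.
#' @export
recoding_scheme <- function(name = "dayhoff6",
                            classes = list(`0` = c("A", "G", "P", "S", "T"),
                                           `1` = c("F", "W", "Y"),
                                           `2` = "C",
                                           `3` = c("H", "K", "R"),
                                           `4` = c("I", "L", "M", "V"),
                                           `5` = c("E", "D", "N", "Q"))) {
  letters20 <- unlist(classes, use.names = FALSE)
  if (anyDuplicated(letters20)) {
    stop("recoding classes must be disjoint", call. = FALSE)
  }
  structure(list(name = name, classes = classes), class = "recoding_scheme")
}

# flat lookup: amino letter -> state symbol
.scheme_map <- function(scheme) {
  sizes <- lengths(scheme$classes)
  stats::setNames(rep(names(scheme$classes), sizes),
                  unlist(scheme$classes, use.names = FALSE))
}

#' Recode a single residue
#'
#' Canonical amino-acid letters map to their class symbol; the gap `-`
#' passes through; ambiguity letters (B, Z, J, X, U, O), `?` and `*` all
#' become `?`.  Ambiguity letters are not resolved to a class even when all
#' their expansions fall in one (B is D or N, both class 5): collapsing them
#' silently would hide the ambiguity, so they are treated as missing.
#'
#' @param r single residue character from the amino20 alphabet.
#' @param scheme a [recoding_scheme()].
#' @return single recoded character.
#' @examples
#' recode_residue("W")   # "1"
#' recode_residue("-")   # "-"
#' @export
recode_residue <- function(r, scheme = recoding_scheme()) {
  if (length(r) != 1L || !(r %in% .alphabet_chars("amino20"))) {
    stop("not an amino20 residue: ", sQuote(r), call. = FALSE)
  }
  if (r == "-") return("-")
  map <- .scheme_map(scheme)
  if (r %in% names(map)) unname(map[r]) else "?"
}

#' Recode an orthogroup alignment into Dayhoff classes
#'
#' Applies [recode_residue()] to every cell: same dimensions, same taxa,
#' same gap positions; the alphabet becomes `dayhoff6` with at most six
#' distinct informative states.
#'
#' @param og an [og_alignment] with `alphabet == "amino20"`.
#' @param scheme a [recoding_scheme()].
#' @return an [og_alignment] with `alphabet == "dayhoff6"`.
#' @export
recode_alignment <- function(og, scheme = recoding_scheme()) {
  if (og$alphabet != "amino20") {
    stop("orthogroup ", og$id, " is not an amino20 alignment", call. = FALSE)
  }
  out <- og
  out$mat <- .recode_matrix(og$mat, scheme)
  out$alphabet <- "dayhoff6"
  out
}

.recode_matrix <- function(mat, scheme) {
  map <- .scheme_map(scheme)
  full <- c(map, stats::setNames("-", "-"),
            stats::setNames(rep("?", length(AA_AMBIG) + 2L),
                            c(AA_AMBIG, "?", "*")))
  bad <- setdiff(unique(as.vector(mat)), names(full))
  if (length(bad) > 0L) {
    stop("cannot recode non-amino20 residues: ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  res <- matrix(full[mat], nrow = nrow(mat), dimnames = dimnames(mat))
  res
}

#' Recode a supermatrix into Dayhoff classes
#'
#' @param sm an amino-acid [supermatrix].
#' @param scheme a [recoding_scheme()].
#' @return the recoded [supermatrix] (`dayhoff6` alphabet); the partition
#'   scheme is unchanged since recoding preserves coordinates.
#' @export
recode_supermatrix <- function(sm, scheme = recoding_scheme()) {
  if (sm$alphabet != "amino20") stop("supermatrix is not amino20", call. = FALSE)
  out <- sm
  out$mat <- .recode_matrix(sm$mat, scheme)
  out$alphabet <- "dayhoff6"
  out
}
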