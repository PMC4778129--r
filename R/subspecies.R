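#' Pairwise p-distance matrix
#'
#' Proportion of mismatching sites between every pair of equal-length,
#' gap-free sequences.
#'
#' @inheritParams polymorphic_sites
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(aln) {
  aln <- toupper(unlist(aln, use.names = TRUE))
  L <- unique(nchar(aln))
  if (length(L) != 1L) stop("ragged alignment: sequences differ in length")
  .pair_diff_matrix(aln) / L
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (Saitou-Nei), unrooted, with negative branch
#' lengths clamped to zero; returned as a newick string.
#'
#' @param d symmetric distance matrix with labelled rows/columns, n >= 3.
#' @return Newick string.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-12)) stop("distance matrix not symmetric")
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  ape::write.tree(tr)
}

#' Classify an isolate against a panel of subspecies type strains
#'
#' For each locus the isolate is assigned to the subspecies whose type strain
#' is nearest by p-distance (an exact tie gives an unresolved vote); the
#' final call is the strict plurality winner of the per-locus votes. Isolates
#' whose loci vote for more than one subspecies are flagged as mosaic; a tied
#' plurality yields an unresolved final call, never a random one.
#'
#' @param record named character vector/list, locus -> sequence (all scheme
#'   loci present).
#' @param panel named list subspecies-name -> (named list locus -> sequence):
#'   the type-strain reference panel.
#' @param loci locus definition table.
#' @return List with `per_locus_calls` (named character vector; `NA` for tied
#'   loci), `votes` (table), `final_call` (subspecies or `"unresolved"`) and
#'   `mosaic_flag`.
#' @export
classify_isolate <- function(record, panel, loci = default_loci()) {
  loci <- .check_loci(loci)
  miss <- setdiff(loci$name, names(record))
  if (length(miss)) stop("record missing locus: ", paste(miss, collapse = ", "))
  for (sp in names(panel)) {
    miss <- setdiff(loci$name, names(panel[[sp]]))
    if (length(miss))
      stop("panel reference '", sp, "' missing locus: ",
           paste(miss, collapse = ", "))
  }
  sps <- names(panel)
  calls <- stats::setNames(rep(NA_character_, nrow(loci)), loci$name)
  for (lc in loci$name) {
    q <- toupper(as.character(record[[lc]]))
    dd <- vapply(sps, function(sp) {
      r <- toupper(as.character(panel[[sp]][[lc]]))
      if (nchar(r) != nchar(q)) stop("ragged sequences at locus ", lc)
      mean(strsplit(q, "")[[1]] != strsplit(r, "")[[1]])
    }, numeric(1))
    best <- which(dd == min(dd))
    if (length(best) == 1L) calls[lc] <- sps[best]
  }
  votes <- table(factor(calls, levels = sps))
  top <- which(votes == max(votes))
  final <- if (max(votes) == 0L || length(top) > 1L) "unresolved" else sps[top]
  list(per_locus_calls = calls, votes = votes, final_call = final,
       mosaic_flag = sum(votes > 0L) >= 2L)
}
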