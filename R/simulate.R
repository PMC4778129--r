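#' Configuration for the clonal population simulator
#'
#' The generator emulates a clonal bacterial population typed at a
#' multi-locus scheme: K divergent ancestral lineages, clonal expansion by
#' sequential transmissions with per-site point mutation, and occasional
#' whole-locus replacement recombination from a co-existing isolate. Defaults
#' mirror a yogurt-culture MLST study design: the eight standard loci
#' (4261 bp), six ancestral lineages, 251 isolates, ancestor divergence 0.005
#' substitutions/site, mutation 2e-4 /site/transmission and locus-replacement
#' recombination at 0.02 /transmission.
#'
#' @param loci locus definition table.
#' @param n_lineages integer K >= 1, number of divergent ancestors.
#' @param ancestor_divergence per-site substitution probability separating
#'   each later ancestor from ancestor 1.
#' @param n_isolates number of isolates to emit.
#' @param generations transmissions separating a child from its parent.
#' @param mu per-site, per-transmission point-mutation probability.
#' @param rho per-transmission probability of replacing one whole locus with
#'   the homologous locus of a random co-existing isolate.
#' @param seed mandatory integer seed; the simulator never seeds from the
#'   clock.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(loci = default_loci(), n_lineages = 6L,
                              ancestor_divergence = 0.005, n_isolates = 251L,
                              generations = 1L, mu = 2e-4, rho = 0.02,
                              seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(n_lineages >= 1L, n_isolates >= 1L, generations >= 1L,
            mu >= 0, mu <= 1, rho >= 0, rho <= 1,
            ancestor_divergence >= 0, ancestor_divergence <= 1)
  structure(list(loci = .check_loci(loci), n_lineages = as.integer(n_lineages),
                 ancestor_divergence = ancestor_divergence,
                 n_isolates = as.integer(n_isolates),
                 generations = as.integer(generations),
                 mu = mu, rho = rho, seed = as.integer(seed)),
            class = "sim_config")
}

# random in-frame stop-free sequence of a locus
.random_locus_seq <- function(ldef) {
  L <- ldef$expected_length
  off <- ldef$frame_offset
  n_cod <- (L - off) %/% 3L
  sense <- setdiff(names(GENETIC_CODE), STOP_CODONS)
  body <- paste(sample(sense, n_cod, replace = TRUE), collapse = "")
  head <- if (off > 0L) paste(sample(.BASES, off, replace = TRUE),
                              collapse = "") else ""
  tailn <- L - off - 3L * n_cod
  tail <- if (tailn > 0L) paste(sample(.BASES, tailn, replace = TRUE),
                                collapse = "") else ""
  paste0(head, body, tail)
}

# substitute base at `site`, avoiding a stop codon in the declared frame;
# a non-stop alternative always exists (at most 2 of 3 changes reach a stop)
.mutate_site <- function(seq, site, ldef) {
  cur <- substr(seq, site, site)
  cand <- sample(setdiff(.BASES, cur))
  off <- ldef$frame_offset
  in_codon <- site > off && (site - off) <= 3L * ((nchar(seq) - off) %/% 3L)
  for (b in cand) {
    new <- seq
    substr(new, site, site) <- b
    if (!in_codon) return(new)
    cod_idx <- (site - off - 1L) %/% 3L
    start <- off + cod_idx * 3L + 1L
    if (!substr(new, start, start + 2L) %in% STOP_CODONS) return(new)
  }
  seq  # unreachable
}

#' Generate the K divergent ancestors
#'
#' Ancestor 1 is a random stop-codon-free in-frame sequence per locus;
#' ancestors 2..K are derived from it by independent per-site substitution at
#' the configured divergence, with stop codons avoided by resampling.
#'
#' @param config a `sim_config`.
#' @return Named list `A1`..`AK`, each a named list locus -> sequence.
#' @export
make_ancestors <- function(config) {
  set.seed(config$seed)
  loci <- config$loci
  a1 <- stats::setNames(lapply(seq_len(nrow(loci)), function(i)
    .random_locus_seq(loci[i, ])), loci$name)
  anc <- list(A1 = a1)
  if (config$n_lineages > 1L) for (k in 2:config$n_lineages) {
    ak <- a1
    for (i in seq_len(nrow(loci))) {
      lc <- loci$name[i]
      L <- loci$expected_length[i]
      hits <- which(stats::runif(L) < config$ancestor_divergence)
      for (s in hits) ak[[lc]] <- .mutate_site(ak[[lc]], s, loci[i, ])
    }
    anc[[paste0("A", k)]] <- ak
  }
  anc
}

#' Evolve a clonal population with known ground truth
#'
#' Isolates are born sequentially: each is assigned a lineage (every lineage
#' is seeded once, then lineages are drawn uniformly), descends from a
#' uniformly chosen earlier isolate of the same lineage (or the lineage
#' ancestor), and is separated from its parent by `generations`
#' transmissions. Each transmission applies independent per-site point
#' mutation at rate `mu` (stop codons avoided by resampling) and then, with
#' probability `rho`, replaces one uniformly chosen locus with the homologous
#' locus of a uniformly chosen co-existing isolate. Every event is recorded
#' so each emitted sequence can be reproduced by replaying the truth log
#' (see [replay_truth()]).
#'
#' @param config a `sim_config`.
#' @return List with `sequences` (named list locus -> named character vector
#'   over isolates), `ancestors`, `truth` (list: `lineage_of`, `parent_of`,
#'   `mutation_events`, `recombination_events`) and `config`.
#' @export
evolve_population <- function(config) {
  ancestors <- make_ancestors(config)   # consumes the seed deterministically
  loci <- config$loci
  n <- config$n_isolates
  K <- config$n_lineages
  ids <- sprintf("iso%03d", seq_len(n))
  lineage_of <- integer(n)
  parent_of <- character(n)
  seqs <- lapply(ids, function(i) NULL)
  names(seqs) <- ids
  mut <- list(); rec <- list()
  for (i in seq_len(n)) {
    lin <- if (i <= K) i else sample.int(K, 1L)
    lineage_of[i] <- lin
    prev <- which(lineage_of[seq_len(i - 1L)] == lin)
    if (length(prev)) {
      pick <- prev[sample.int(length(prev), 1L)]
      parent <- ids[pick]
      cur <- seqs[[parent]]
    } else {
      parent <- paste0("A", lin)
      cur <- ancestors[[parent]]
    }
    for (g in seq_len(config$generations)) {
      for (li in seq_len(nrow(loci))) {
        lc <- loci$name[li]
        hits <- which(stats::runif(loci$expected_length[li]) < config$mu)
        for (s in hits) {
          new <- .mutate_site(cur[[lc]], s, loci[li, ])
          mut[[length(mut) + 1L]] <- data.frame(
            isolate = ids[i], round = g, locus = lc, site = s,
            to = substr(new, s, s), stringsAsFactors = FALSE)
          cur[[lc]] <- new
        }
      }
      if (i > 1L && stats::runif(1) < config$rho) {
        donor <- ids[sample.int(i - 1L, 1L)]
        lc <- loci$name[sample.int(nrow(loci), 1L)]
        cur[[lc]] <- seqs[[donor]][[lc]]
        rec[[length(rec) + 1L]] <- data.frame(
          isolate = ids[i], round = g, locus = lc, donor = donor,
          stringsAsFactors = FALSE)
      }
    }
    seqs[[ids[i]]] <- cur
    parent_of[i] <- parent
  }
  empty_mut <- data.frame(isolate = character(), round = integer(),
                          locus = character(), site = integer(),
                          to = character(), stringsAsFactors = FALSE)
  empty_rec <- data.frame(isolate = character(), round = integer(),
                          locus = character(), donor = character(),
                          stringsAsFactors = FALSE)
  truth <- list(
    lineage_of = stats::setNames(lineage_of, ids),
    parent_of = stats::setNames(parent_of, ids),
    mutation_events = if (length(mut)) do.call(rbind, mut) else empty_mut,
    recombination_events = if (length(rec)) do.call(rbind, rec) else empty_rec)
  by_locus <- stats::setNames(lapply(loci$name, function(lc)
    vapply(ids, function(i) seqs[[i]][[lc]], character(1))), loci$name)
  list(sequences = by_locus, ancestors = ancestors, truth = truth,
       config = config)
}

#' Replay a simulation truth log
#'
#' Independently reconstructs every isolate's sequences from the ancestors
#' and the recorded mutation/recombination events, in birth order. Used as an
#' oracle: the replayed sequences must equal the emitted ones byte-exactly.
#'
#' @param truth the `truth` element of [evolve_population()] output.
#' @param ancestors the `ancestors` element.
#' @param loci locus definition table of the run.
#' @return Named list locus -> named character vector over isolates.
#' @export
replay_truth <- function(truth, ancestors, loci = default_loci()) {
  ids <- names(truth$parent_of)
  seqs <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    parent <- truth$parent_of[[id]]
    cur <- if (parent %in% names(ancestors)) ancestors[[parent]]
           else seqs[[parent]]
    me_mut <- truth$mutation_events[truth$mutation_events$isolate == id, ]
    me_rec <- truth$recombination_events[
      truth$recombination_events$isolate == id, ]
    rounds <- sort(unique(c(me_mut$round, me_rec$round)))
    for (g in rounds) {
      mm <- me_mut[me_mut$round == g, ]
      for (r in seq_len(nrow(mm)))
        substr(cur[[mm$locus[r]]], mm$site[r], mm$site[r]) <- mm$to[r]
      rr <- me_rec[me_rec$round == g, ]
      for (r in seq_len(nrow(rr)))
        cur[[rr$locus[r]]] <- seqs[[rr$donor[r]]][[rr$locus[r]]]
    }
    seqs[[id]] <- cur
  }
  stats::setNames(lapply(loci$name, function(lc)
    vapply(ids, function(i) seqs[[i]][[lc]], character(1))), loci$name)
}

#' Independently permute each alignment column across sequences
#'
#' Destroys all between-site linkage while preserving each column's base
#' composition; the null generator for recombination-test calibration.
#'
#' @inheritParams polymorphic_sites
#' @param seed optional integer seed.
#' @return Character vector of shuffled sequences (same names and length).
#' @export
shuffle_sites <- function(aln, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- if (is.matrix(aln)) aln else .aln_matrix(aln)
  for (j in seq_len(ncol(m))) m[, j] <- m[sample.int(nrow(m)), j]
  apply(m, 1L, paste, collapse = "")
}
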