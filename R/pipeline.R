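#' Run the full MLST population-genetics pipeline
#'
#' Orchestrates typing, diversity, clonal-complex clustering, recombination
#' testing and (optionally) subspecies classification, writing one TSV per
#' stage plus a snapshot graph and a run log into `out_dir`. Every numeric
#' cell is produced by the corresponding module function; stages are
#' deterministic given the inputs and the seed.
#'
#' @param seqs_by_locus named list locus -> named character vector of isolate
#'   sequences; may be `NULL` when `profiles` are supplied directly.
#' @param profiles optional integer matrix of per-isolate allele profiles
#'   (used instead of sequences; diversity and PHI stages are then skipped).
#' @param loci locus definition table.
#' @param subset optional isolate-id subset for diversity statistics.
#' @param membership optional named vector ST id -> lineage label; adds
#'   per-lineage I_A^S rows.
#' @param panel optional type-strain reference panel for classification.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for the stochastic stages (PHI permutations,
#'   I_A^S resampling).
#' @param permutations permutations/resamples for PHI and I_A^S.
#' @param phi_window PHI window on the informative-site subalignment.
#' @return Invisibly, a list with the stage results (`profiles`, `sts`,
#'   `diversity`, `eburst`, `recombination`, `classification`, `files`).
#' @export
run_pipeline <- function(seqs_by_locus = NULL, profiles = NULL,
                         loci = default_loci(), subset = NULL,
                         membership = NULL, panel = NULL,
                         out_dir, seed, permutations = 1000L,
                         phi_window = 100L) {
  if (missing(seed)) stop("a seed is required")
  if (is.null(seqs_by_locus) && is.null(profiles))
    stop("either sequences or profiles must be supplied")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  log <- c(sprintf("mlstpg %s", as.character(utils::packageVersion("mlstpg"))),
           sprintf("seed: %d", seed))

  # -- typing -----------------------------------------------------------
  db <- NULL
  if (!is.null(seqs_by_locus)) {
    typed <- type_isolates(seqs_by_locus, loci)
    profiles <- typed$profiles
    db <- typed$db
    log <- c(log, sprintf("typing: %d isolates, %d loci", nrow(profiles),
                          ncol(profiles)))
  }
  sts <- assign_sts(profiles)
  f <- file.path(out_dir, "profiles.tsv")
  write_profiles(sts$registry, f, loci)
  files <- c(files, f)
  iso_tab <- data.frame(isolate = names(sts$st_of), ST = unname(sts$st_of))
  f <- file.path(out_dir, "isolate_sts.tsv")
  utils::write.table(iso_tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  log <- c(log, sprintf("sts: %d isolates -> %d STs", nrow(profiles),
                        nrow(sts$registry)))

  # -- diversity --------------------------------------------------------
  div <- NULL
  if (!is.null(seqs_by_locus)) {
    div <- diversity_table(seqs_by_locus, loci, subset = subset)
    f <- file.path(out_dir, "diversity.tsv")
    utils::write.table(div, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    if (any(!is.finite(div$dnds)))
      log <- c(log, "warning: dN/dS undefined for some loci (dS = 0)")
  }

  # -- eburst -----------------------------------------------------------
  counts <- stats::setNames(as.integer(table(sts$st_of)),
                            as.character(seq_len(nrow(sts$registry))))
  g <- build_slv_graph(sts$registry, counts)
  eb <- cluster_groups(g)
  f <- file.path(out_dir, "groups.tsv")
  utils::write.table(eb$membership, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f)
  export_snapshot(g, file.path(out_dir, "snapshot.graphml"),
                  file.path(out_dir, "snapshot.dot"))
  files <- c(files, file.path(out_dir, c("snapshot.graphml", "snapshot.dot")))
  log <- c(log, sprintf("eburst: %d CCs, %d doubletons, %d singletons",
                        sum(eb$groups$group_type == "CC"),
                        sum(eb$groups$group_type == "doubleton"),
                        sum(eb$groups$group_type == "singleton")))

  # -- recombination ----------------------------------------------------
  rec_rows <- list()
  ia_all <- ia_standardized(sts$registry, resamples = permutations,
                            seed = seed)
  phi_all <- NULL
  if (!is.null(seqs_by_locus)) {
    iso <- rownames(profiles)
    concat <- vapply(iso, function(i) concatenate_record(
      lapply(seqs_by_locus, `[[`, i), loci), character(1))
    st_concat <- concat[!duplicated(sts$st_of)]
    if (length(st_concat) >= 4L)
      phi_all <- phi_test(st_concat, window = phi_window,
                          permutations = permutations, seed = seed)
  }
  rec_rows[["all"]] <- data.frame(
    population = sprintf("All (%dST)", nrow(sts$registry)),
    phi_p = if (is.null(phi_all)) NA_real_ else phi_all$p_value,
    ia_s = ia_all$ia_s, ia_p = ia_all$p_value,
    n_sts = nrow(sts$registry), stringsAsFactors = FALSE)
  if (!is.null(membership)) {
    for (lin in sort(unique(membership))) {
      sel <- names(membership)[membership == lin]
      sub <- sts$registry[rownames(sts$registry) %in% sel, , drop = FALSE]
      ia_l <- tryCatch(ia_standardized(sub, resamples = permutations,
                                       seed = seed),
                       error = function(e) NULL)
      rec_rows[[lin]] <- data.frame(
        population = sprintf("%s (%dST)", lin, nrow(sub)),
        phi_p = NA_real_,
        ia_s = if (is.null(ia_l)) NA_real_ else ia_l$ia_s,
        ia_p = if (is.null(ia_l)) NA_real_ else ia_l$p_value,
        n_sts = nrow(sub), stringsAsFactors = FALSE)
    }
  }
  rec <- do.call(rbind, rec_rows)
  f <- file.path(out_dir, "recombination.tsv")
  utils::write.table(rec, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  # -- classification ---------------------------------------------------
  cls <- NULL
  if (!is.null(panel) && !is.null(seqs_by_locus)) {
    iso <- rownames(profiles)
    cls <- do.call(rbind, lapply(iso, function(i) {
      r <- classify_isolate(lapply(seqs_by_locus, `[[`, i), panel, loci)
      data.frame(isolate = i, final_call = r$final_call,
                 mosaic = r$mosaic_flag,
                 votes = paste(sprintf("%s:%d", names(r$votes), r$votes),
                               collapse = ","), stringsAsFactors = FALSE)
    }))
    f <- file.path(out_dir, "classification.tsv")
    utils::write.table(cls, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }

  writeLines(log, file.path(out_dir, "run.log"))
  files <- c(files, file.path(out_dir, "run.log"))
  invisible(list(profiles = profiles, sts = sts, db = db, diversity = div,
                 eburst = eb, graph = g, recombination = rec,
                 ia = ia_all, phi = phi_all, classification = cls,
                 files = files))
}
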