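# Standard genetic code (translation table 1)
GENETIC_CODE <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

.BASES <- c("A", "C", "G", "T")

#' Polymorphic (segregating) sites of an alignment
#'
#' @param aln character vector of equal-length, gap-free nucleotide strings
#'   (or a character matrix, sequences x sites).
#' @return Integer vector of 1-based site positions at which at least two
#'   distinct bases are observed; its length is the polymorphic-site count.
#' @export
polymorphic_sites <- function(aln) {
  m <- if (is.matrix(aln)) aln else .aln_matrix(aln)
  which(apply(m, 2L, function(col) length(unique(col)) > 1L))
}

#' G+C content of an alignment
#'
#' @inheritParams polymorphic_sites
#' @return Percent G+C over all bases of all sequences.
#' @export
gc_content <- function(aln) {
  m <- if (is.matrix(aln)) aln else .aln_matrix(aln)
  100 * sum(m %in% c("G", "C")) / length(m)
}

# pairwise difference counts between unique sequences (integer matrix)
.pair_diff_matrix <- function(seqs) {
  m <- .aln_matrix(seqs)
  if (nrow(m) == 1L) return(matrix(0L, 1L, 1L))
  db <- ape::as.DNAbin(tolower(m))
  as.matrix(ape::dist.dna(db, model = "N", pairwise.deletion = FALSE))
}

#' Nucleotide diversity (pi)
#'
#' The average number of nucleotide differences per site between two randomly
#' selected sequences: `sum over pairs of d_ij / C(n,2) / L`, with no
#' multiple-hit correction.
#'
#' @inheritParams polymorphic_sites
#' @return Numeric scalar in `[0, 1]`.
#' @export
nucleotide_diversity <- function(aln) {
  aln <- toupper(unlist(aln, use.names = TRUE))
  n <- length(aln)
  if (n < 2L) stop("nucleotide diversity needs at least 2 sequences")
  L <- nchar(aln[[1L]])
  uniq <- unique(aln)
  w <- as.numeric(table(factor(aln, levels = uniq)))
  d <- .pair_diff_matrix(uniq)
  tot <- 0
  for (i in seq_along(uniq))
    for (j in seq_len(i - 1L))
      tot <- tot + w[i] * w[j] * d[i, j]
  tot / choose(n, 2) / L
}

#' Classify polymorphic sites as synonymous or nonsynonymous
#'
#' Each polymorphic site inside a complete codon (given the reading frame) is
#' classified by examining every pair of observed codons that differ at that
#' site: substituting one codon's base at the site into the other tests
#' whether the amino acid changes because of that site. A site with any
#' amino-acid-changing pair is nonsynonymous; otherwise synonymous. Sites in
#' incomplete leading/trailing codons are left unclassified.
#'
#' @inheritParams polymorphic_sites
#' @param frame_offset integer in 0:2, offset of the first complete codon.
#' @return List with `n_nsnp`, `n_ssnp`, and `sites` (data.frame of position
#'   and class among `"nonsynonymous"`, `"synonymous"`, `NA` for sites
#'   outside complete codons).
#' @export
classify_snp_sites <- function(aln, frame_offset = 0L) {
  m <- if (is.matrix(aln)) aln else .aln_matrix(aln)
  L <- ncol(m)
  pos <- polymorphic_sites(m)
  cls <- rep(NA_character_, length(pos))
  if (length(pos)) {
    for (k in seq_along(pos)) {
      p <- pos[k]
      off <- p - frame_offset          # 1-based within coding part
      if (off < 1L) next
      cod_idx <- (off - 1L) %/% 3L
      start <- frame_offset + cod_idx * 3L + 1L
      if (start + 2L > L) next
      cods <- unique(apply(m[, start:(start + 2L), drop = FALSE], 1L,
                           paste, collapse = ""))
      if (any(GENETIC_CODE[cods] == "*"))
        stop("internal stop codon encountered at codon starting ", start)
      within <- p - start + 1L
      nonsyn <- FALSE
      for (i in seq_along(cods)) for (j in seq_along(cods)) {
        if (i == j) next
        a <- cods[i]; b <- cods[j]
        if (substr(a, within, within) == substr(b, within, within)) next
        hybrid <- a
        substr(hybrid, within, within) <- substr(b, within, within)
        if (GENETIC_CODE[[hybrid]] != GENETIC_CODE[[a]]) { nonsyn <- TRUE; break }
      }
      cls[k] <- if (nonsyn) "nonsynonymous" else "synonymous"
    }
  }
  list(n_nsnp = sum(cls == "nonsynonymous", na.rm = TRUE),
       n_ssnp = sum(cls == "synonymous", na.rm = TRUE),
       sites = data.frame(position = pos, class = cls,
                          stringsAsFactors = FALSE))
}

# fraction of synonymous changes per codon position, stop-target changes
# excluded from the denominator; returns total synonymous sites of the codon
.syn_sites_codon <- function(codon) {
  aa <- GENETIC_CODE[[codon]]
  s <- 0
  for (p in 1:3) {
    alt <- .BASES[.BASES != substr(codon, p, p)]
    syn <- 0L; tot <- 0L
    for (b in alt) {
      mut <- codon
      substr(mut, p, p) <- b
      if (GENETIC_CODE[[mut]] == "*") next
      tot <- tot + 1L
      if (GENETIC_CODE[[mut]] == aa) syn <- syn + 1L
    }
    if (tot > 0L) s <- s + syn / tot
  }
  s
}

# synonymous/nonsynonymous differences between two codons, averaged with
# equal weight over minimal mutational pathways that avoid stop codons
.codon_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(nd,
                  list(pos),
                  list(pos, rev(pos)),
                  { p <- pos
                    list(p[c(1,2,3)], p[c(1,3,2)], p[c(2,1,3)],
                         p[c(2,3,1)], p[c(3,1,2)], p[c(3,2,1)]) })
  walk <- function(order) {
    cur <- c1; sd <- 0L; nd <- 0L
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (GENETIC_CODE[[nxt]] == "*") return(NULL)
      if (GENETIC_CODE[[nxt]] == GENETIC_CODE[[cur]]) sd <- sd + 1L
      else nd <- nd + 1L
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(perms, walk))
  if (!length(res))  # no stop-free pathway; fall back to all pathways
    res <- lapply(perms, function(order) {
      cur <- c1; sd <- 0L; nd <- 0L
      for (p in order) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (GENETIC_CODE[[nxt]] != "*" &&
            GENETIC_CODE[[cur]] != "*" &&
            GENETIC_CODE[[nxt]] == GENETIC_CODE[[cur]]) sd <- sd + 1L
        else nd <- nd + 1L
        cur <- nxt
      }
      c(sd, nd)
    })
  avg <- Reduce(`+`, res) / length(res)
  c(sd = avg[1L], nd = avg[2L])
}

.jc_correct <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NaN)
}

#' Nei-Gojobori dN/dS for an alignment
#'
#' Counts synonymous and nonsynonymous sites per sequence (fractional,
#' stop-target changes excluded), averages them over each pair, counts
#' differences along minimal mutational pathways (equal weights over
#' stop-free pathways), applies the Jukes-Cantor correction to the per-site
#' proportions, and averages dN and dS over all sequence pairs before taking
#' the ratio. The ratio is 0 when dN = 0 and reported as `NaN` (with
#' `undefined = TRUE`) when dS = 0 with dN > 0.
#'
#' @inheritParams classify_snp_sites
#' @return List with `dn`, `ds`, `ratio` (Jukes-Cantor corrected), `pn`,
#'   `ps`, `ratio_raw` (uncorrected proportions), pair-averaged counts
#'   `syn_sites`, `nonsyn_sites`, `syn_diffs`, `nonsyn_diffs`, and flags
#'   `identical` and `undefined`.
#' @export
dn_ds <- function(aln, frame_offset = 0L) {
  aln <- toupper(unlist(aln, use.names = TRUE))
  n <- length(aln)
  if (n < 2L) stop("dn_ds needs at least 2 sequences")
  cods <- lapply(aln, codons_of, frame_offset = frame_offset)
  nc <- length(cods[[1L]])
  if (nc < 1L) stop("alignment shorter than one codon")
  if (any(vapply(cods, function(x) any(x %in% STOP_CODONS), logical(1))))
    stop("internal stop codon encountered")
  uniq <- unique(aln)
  w <- as.numeric(table(factor(aln, levels = uniq)))
  ucods <- cods[match(uniq, aln)]
  S_seq <- vapply(ucods, function(cs) sum(vapply(cs, .syn_sites_codon,
                                                 numeric(1))), numeric(1))
  tot_pairs <- choose(n, 2)
  sumS <- sumN <- sumSd <- sumNd <- sumDn <- sumDs <- sumPn <- sumPs <- 0
  # identical-sequence pairs contribute their sites and zero differences
  for (i in seq_along(uniq)) {
    wp <- choose(w[i], 2)
    if (wp > 0) { sumS <- sumS + wp * S_seq[i]
                  sumN <- sumN + wp * (3 * nc - S_seq[i]) }
  }
  u <- length(uniq)
  if (u > 1L) for (i in 1:(u - 1L)) for (j in (i + 1L):u) {
    wp <- w[i] * w[j]
    Sp <- (S_seq[i] + S_seq[j]) / 2
    Np <- 3 * nc - Sp
    dif <- which(ucods[[i]] != ucods[[j]])
    sd <- nd <- 0
    for (k in dif) {
      dd <- .codon_diffs(ucods[[i]][k], ucods[[j]][k])
      sd <- sd + dd[["sd"]]; nd <- nd + dd[["nd"]]
    }
    ps <- sd / Sp; pn <- nd / Np
    sumS <- sumS + wp * Sp;   sumN <- sumN + wp * Np
    sumSd <- sumSd + wp * sd; sumNd <- sumNd + wp * nd
    sumPs <- sumPs + wp * ps; sumPn <- sumPn + wp * pn
    sumDs <- sumDs + wp * .jc_correct(ps)
    sumDn <- sumDn + wp * .jc_correct(pn)
  }
  dn <- sumDn / tot_pairs; ds <- sumDs / tot_pairs
  pn <- sumPn / tot_pairs; ps <- sumPs / tot_pairs
  ratio_of <- function(a, b) {
    if (!is.nan(a) && a == 0) return(0)   # dN = 0: ratio 0 by convention
    if (is.nan(a) || is.nan(b) || b == 0) return(NaN)
    a / b
  }
  list(dn = dn, ds = ds, ratio = ratio_of(dn, ds),
       pn = pn, ps = ps, ratio_raw = ratio_of(pn, ps),
       syn_sites = sumS / tot_pairs, nonsyn_sites = sumN / tot_pairs,
       syn_diffs = sumSd / tot_pairs, nonsyn_diffs = sumNd / tot_pairs,
       identical = u == 1L,
       undefined = (!is.nan(ds) && ds == 0 && !is.nan(dn) && dn > 0) ||
                   is.nan(ds) || is.nan(dn))
}

#' Per-locus and concatenated diversity table
#'
#' One row per locus plus a `concatenated` row, mirroring the usual MLST
#' diversity summary: allele counts, polymorphic sites, nSNP/sSNP classes,
#' G+C percent, nucleotide diversity and Nei-Gojobori dN/dS. The
#' concatenated row counts distinct STs as its allele count and sums the
#' per-locus site counts; its dN/dS pools pair-averaged sites and differences
#' across loci before correction.
#'
#' @param seqs_by_locus named list locus -> named character vector of
#'   sequences (names = isolate ids).
#' @param loci locus definition table.
#' @param subset optional character vector of isolate ids to restrict to.
#' @return A `data.frame` with columns `locus`, `size_bp`, `n_alleles`,
#'   `n_polymorphic`, `n_nsnp`, `n_ssnp`, `gc_percent`, `pi`, `dn`, `ds`,
#'   `dnds`.
#' @export
diversity_table <- function(seqs_by_locus, loci = default_loci(),
                            subset = NULL) {
  loci <- .check_loci(loci)
  miss <- setdiff(loci$name, names(seqs_by_locus))
  if (length(miss)) stop("missing locus: ", paste(miss, collapse = ", "))
  isolates <- names(seqs_by_locus[[loci$name[1L]]])
  if (!is.null(subset)) {
    isolates <- intersect(isolates, subset)
    if (!length(isolates)) stop("empty subset")
  }
  rows <- list()
  pooled <- c(S = 0, N = 0, sd = 0, nd = 0)
  concat <- rep("", length(isolates))
  for (li in seq_len(nrow(loci))) {
    lc <- loci$name[li]
    seqs <- toupper(seqs_by_locus[[lc]][isolates])
    concat <- paste0(concat, seqs)
    n_all <- length(unique(seqs))
    poly <- length(polymorphic_sites(seqs))
    snp <- classify_snp_sites(seqs, loci$frame_offset[li])
    pi <- if (length(seqs) >= 2L) nucleotide_diversity(seqs) else NA_real_
    dd <- if (length(seqs) >= 2L) dn_ds(seqs, loci$frame_offset[li]) else NULL
    if (!is.null(dd))
      pooled <- pooled + c(dd$syn_sites, dd$nonsyn_sites,
                           dd$syn_diffs, dd$nonsyn_diffs)
    rows[[lc]] <- data.frame(
      locus = lc, size_bp = loci$expected_length[li], n_alleles = n_all,
      n_polymorphic = poly, n_nsnp = snp$n_nsnp, n_ssnp = snp$n_ssnp,
      gc_percent = gc_content(seqs), pi = pi,
      dn = if (is.null(dd)) NA_real_ else dd$dn,
      ds = if (is.null(dd)) NA_real_ else dd$ds,
      dnds = if (is.null(dd)) NA_real_ else dd$ratio,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  ps <- pooled[["sd"]] / pooled[["S"]]
  pn <- pooled[["nd"]] / pooled[["N"]]
  dsc <- .jc_correct(ps); dnc <- .jc_correct(pn)
  dnds_c <- if (length(isolates) < 2L) NA_real_
            else if (is.nan(dnc) || is.nan(dsc)) NaN
            else if (dnc == 0) 0 else if (dsc == 0) NaN else dnc / dsc
  crow <- data.frame(
    locus = "concatenated", size_bp = sum(loci$expected_length),
    n_alleles = length(unique(concat)),
    n_polymorphic = sum(tab$n_polymorphic),
    n_nsnp = sum(tab$n_nsnp), n_ssnp = sum(tab$n_ssnp),
    gc_percent = gc_content(concat),
    pi = if (length(isolates) >= 2L) nucleotide_diversity(concat) else NA_real_,
    dn = if (length(isolates) >= 2L) dnc else NA_real_,
    ds = if (length(isolates) >= 2L) dsc else NA_real_,
    dnds = dnds_c, stringsAsFactors = FALSE)
  out <- rbind(tab, crow)
  rownames(out) <- NULL
  out
}
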