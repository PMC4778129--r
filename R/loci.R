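#' Locus definitions for an MLST scheme
#'
#' A locus definition records the fragment name, its expected length in bp,
#' the reading-frame offset of the first complete codon (0, 1 or 2), and its
#' position in the canonical locus order used for profiles and concatenation.
#'
#' @param name character scalar, locus name.
#' @param expected_length integer, fragment length in bp (> 0).
#' @param frame_offset integer in 0:2; number of bases before the first
#'   complete codon. Amplicons are assumed in-frame by default (offset 0).
#' @param order_index integer, 1-based position in the scheme order.
#' @return A one-row `data.frame` with class `locus_def` columns.
#' @export
locus_def <- function(name, expected_length, frame_offset = 0L, order_index = 1L) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  expected_length <- as.integer(expected_length)
  frame_offset <- as.integer(frame_offset)
  if (is.na(expected_length) || expected_length <= 0L)
    stop("expected_length must be a positive integer")
  if (!frame_offset %in% 0:2)
    stop("frame_offset must be 0, 1 or 2")
  data.frame(name = name, expected_length = expected_length,
             frame_offset = frame_offset, order_index = as.integer(order_index),
             stringsAsFactors = FALSE)
}

#' Default eight-locus scheme for Lactobacillus delbrueckii
#'
#' The eight housekeeping-gene fragments used for typing L. delbrueckii
#' subsp. bulgaricus, with their fragment lengths (clpX 508, dnaA 598,
#' groEL 470, murE 477, pheS 491, pyrG 563, recA 551, rpoB 603 bp; 4261 bp
#' concatenated). All fragments are treated as in-frame (offset 0).
#'
#' @return A `data.frame` with one row per locus (columns `name`,
#'   `expected_length`, `frame_offset`, `order_index`).
#' @export
#' @examples
#' sum(default_loci()$expected_length)  # 4261
default_loci <- function() {
  nm <- c("clpX", "dnaA", "groEL", "murE", "pheS", "pyrG", "recA", "rpoB")
  len <- c(508L, 598L, 470L, 477L, 491L, 563L, 551L, 603L)
  do.call(rbind, lapply(seq_along(nm), function(i)
    locus_def(nm[i], len[i], 0L, i)))
}

.check_loci <- function(loci) {
  stopifnot(is.data.frame(loci),
            all(c("name", "expected_length", "frame_offset", "order_index") %in%
                  names(loci)))
  if (anyDuplicated(loci$name)) stop("duplicate locus names")
  loci[order(loci$order_index), , drop = FALSE]
}

.locus_row <- function(loci, locus) {
  i <- match(locus, loci$name)
  if (is.na(i)) stop("unknown locus: ", locus)
  loci[i, , drop = FALSE]
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Split a sequence into its complete codons
#'
#' @param seq nucleotide string.
#' @param frame_offset integer in 0:2.
#' @return Character vector of complete 3-base codons; trailing incomplete
#'   codons are dropped.
#' @keywords internal
codons_of <- function(seq, frame_offset = 0L) {
  n <- nchar(seq)
  starts <- seq.int(frame_offset + 1L, n, by = 3L)
  starts <- starts[starts + 2L <= n]
  if (!length(starts)) return(character(0))
  substring(seq, starts, starts + 2L)
}

#' Validate a locus sequence
#'
#' Checks a finished nucleotide sequence against the rules the typing scheme
#' assumes: correct fragment length, only unambiguous A/C/G/T characters
#' (ambiguity codes are rejected, not resolved), and no stop codon among the
#' complete codons in the declared reading frame.
#'
#' @param locus a one-row locus definition (see [locus_def()]).
#' @param seq nucleotide string (non-empty).
#' @return Character vector of violation messages; `character(0)` if valid.
#' @export
#' @examples
#' toy <- locus_def("toy", 9)
#' validate_sequence(toy, "ATGTAAGGG")  # internal stop codon (codon 2 = TAA)
validate_sequence <- function(locus, seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  seq <- toupper(seq)
  bad <- character(0)
  if (nchar(seq) != locus$expected_length)
    bad <- c(bad, sprintf("wrong length: expected %d, got %d",
                          locus$expected_length, nchar(seq)))
  if (grepl("[^ACGT]", seq))
    bad <- c(bad, "non-ACGT character")
  cods <- codons_of(seq, locus$frame_offset)
  hit <- which(cods %in% STOP_CODONS)
  if (length(hit))
    bad <- c(bad, sprintf("internal stop codon %s at codon %d",
                          cods[hit[1L]], hit[1L]))
  bad
}
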