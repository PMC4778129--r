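#' Read a per-locus FASTA file
#'
#' One record per isolate; record ids are isolate ids.
#'
#' @param path FASTA file path.
#' @return Named character vector of upper-case sequences.
#' @export
read_locus_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  seqs <- toupper(vapply(as.character(dna), paste, character(1), collapse = ""))
  names(seqs) <- sub("\\s.*$", "", names(dna))
  seqs
}

#' Write a per-locus FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_locus_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", names(seqs)[i]), seqs[i]), con)
  invisible(path)
}

# character matrix (sequences x sites) from a vector of equal-length strings
.aln_matrix <- function(aln) {
  aln <- toupper(unlist(aln, use.names = TRUE))
  n <- nchar(aln)
  if (length(unique(n)) != 1L)
    stop("ragged alignment: sequences differ in length")
  m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}
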