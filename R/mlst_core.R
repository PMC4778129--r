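#' Build an allele database from per-locus sequence collections
#'
#' For each locus, every unique sequence (differing from the others at one or
#' more nucleotides) is assigned an integer allele number in first-occurrence
#' order of the input stream, so numbering is deterministic given input order
#' and re-running on the same input is idempotent.
#'
#' @param seqs_by_locus named list, one element per locus: a named character
#'   vector of nucleotide sequences (names are isolate ids).
#' @param loci locus definition table (default [default_loci()]); only loci
#'   present in `seqs_by_locus` are required to be covered by every isolate
#'   at typing time, but each supplied sequence must validate.
#' @return An object of class `allele_db`: a list with `loci` and `alleles`
#'   (per locus, a character vector of allele sequences; position = allele id).
#' @export
build_allele_database <- function(seqs_by_locus, loci = default_loci()) {
  loci <- .check_loci(loci)
  stopifnot(is.list(seqs_by_locus), !is.null(names(seqs_by_locus)))
  unknown <- setdiff(names(seqs_by_locus), loci$name)
  if (length(unknown)) stop("unknown locus: ", paste(unknown, collapse = ", "))
  alleles <- list()
  for (lc in names(seqs_by_locus)) {
    ldef <- .locus_row(loci, lc)
    seqs <- toupper(seqs_by_locus[[lc]])
    for (i in seq_along(seqs)) {
      viol <- validate_sequence(ldef, seqs[i])
      if (length(viol)) {
        iso <- names(seqs)[i]
        stop(sprintf("invalid sequence for isolate '%s' at locus '%s': %s",
                     if (is.null(iso)) as.character(i) else iso, lc,
                     paste(viol, collapse = "; ")), call. = FALSE)
      }
    }
    alleles[[lc]] <- unique(unname(seqs))
  }
  structure(list(loci = loci, alleles = alleles), class = "allele_db")
}

#' @export
print.allele_db <- function(x, ...) {
  cat("Allele database:", nrow(x$loci), "loci\n")
  for (lc in x$loci$name)
    cat(sprintf("  %-6s %4d bp  %3d allele(s)\n", lc,
                x$loci$expected_length[x$loci$name == lc],
                length(x$alleles[[lc]])))
  invisible(x)
}

#' Look up (or register) an allele
#'
#' Exact-match lookup of a sequence against the registry. In `query` mode an
#' unseen sequence is reported as novel (`NA` allele id); in `extend` mode it
#' is registered under the next contiguous id.
#'
#' @param db an `allele_db`.
#' @param locus locus name.
#' @param seq nucleotide string (must validate for the locus).
#' @param extend logical; register novel alleles (default `FALSE` = query).
#' @return List with `allele_id` (integer, `NA` when novel in query mode),
#'   `novel` (logical) and `db` (the possibly extended database).
#' @export
call_allele <- function(db, locus, seq, extend = FALSE) {
  stopifnot(inherits(db, "allele_db"))
  if (!locus %in% db$loci$name) stop("unknown locus: ", locus)
  ldef <- .locus_row(db$loci, locus)
  seq <- toupper(seq)
  viol <- validate_sequence(ldef, seq)
  if (length(viol)) stop("invalid sequence for locus '", locus, "': ",
                         paste(viol, collapse = "; "))
  id <- match(seq, db$alleles[[locus]])
  if (!is.na(id)) return(list(allele_id = as.integer(id), novel = FALSE, db = db))
  if (!extend) return(list(allele_id = NA_integer_, novel = TRUE, db = db))
  db$alleles[[locus]] <- c(db$alleles[[locus]], seq)
  list(allele_id = length(db$alleles[[locus]]), novel = TRUE, db = db)
}

#' Type isolates: build profiles from per-locus sequences
#'
#' Builds (or extends) the allele database and returns the integer allele
#' profile of every isolate. All scheme loci must be present for an isolate
#' to be typed.
#'
#' @param seqs_by_locus named list locus -> named character vector of
#'   sequences (names = isolate ids); every isolate must appear at all loci.
#' @param loci locus definition table.
#' @param db optional existing `allele_db` to extend; default builds fresh.
#' @return List with `profiles` (integer matrix, isolates x loci in scheme
#'   order) and `db`.
#' @export
type_isolates <- function(seqs_by_locus, loci = default_loci(), db = NULL) {
  loci <- .check_loci(loci)
  missing_loci <- setdiff(loci$name, names(seqs_by_locus))
  if (length(missing_loci))
    stop("missing locus: ", paste(missing_loci, collapse = ", "))
  isolates <- names(seqs_by_locus[[loci$name[1L]]])
  for (lc in loci$name) {
    miss <- setdiff(isolates, names(seqs_by_locus[[lc]]))
    if (length(miss))
      stop(sprintf("isolate '%s' missing locus '%s'", miss[1L], lc))
  }
  if (is.null(db)) db <- build_allele_database(seqs_by_locus[loci$name], loci)
  prof <- matrix(NA_integer_, nrow = length(isolates), ncol = nrow(loci),
                 dimnames = list(isolates, loci$name))
  for (lc in loci$name) {
    seqs <- toupper(seqs_by_locus[[lc]][isolates])
    for (i in seq_along(seqs)) {
      res <- call_allele(db, lc, seqs[i], extend = TRUE)
      db <- res$db
      prof[i, lc] <- res$allele_id
    }
  }
  list(profiles = prof, db = db)
}

#' Assign sequence types to allele profiles
#'
#' Identical allele vectors share one ST; st ids are 1..m in first-occurrence
#' order, so the number of STs equals the number of distinct profiles.
#'
#' @param profiles integer matrix (isolates x loci), no missing entries.
#' @return List with `st_of` (named integer vector, ST id per isolate) and
#'   `registry` (integer matrix, one row per ST, rownames = ST ids).
#' @export
assign_sts <- function(profiles) {
  profiles <- .as_profile_matrix(profiles)
  key <- apply(profiles, 1L, paste, collapse = "_")
  first <- !duplicated(key)
  st_of <- match(key, key[first])
  names(st_of) <- rownames(profiles)
  registry <- profiles[first, , drop = FALSE]
  rownames(registry) <- as.character(seq_len(nrow(registry)))
  list(st_of = st_of, registry = registry)
}

.as_profile_matrix <- function(profiles) {
  if (is.data.frame(profiles)) profiles <- as.matrix(profiles)
  stopifnot(is.matrix(profiles))
  storage.mode(profiles) <- "integer"
  if (anyNA(profiles) || any(profiles <= 0L))
    stop("profiles must contain positive allele ids only")
  profiles
}

#' Concatenate the locus fragments of one isolate
#'
#' Joins the eight fragments in scheme order; for the default loci the result
#' is the 4261-bp multi-locus fragment.
#'
#' @param sequences named character vector or list, locus -> sequence. Allele
#'   ids may be given instead when `db` is supplied.
#' @param loci locus definition table.
#' @param db optional `allele_db` used to resolve integer allele ids.
#' @return A single nucleotide string.
#' @export
concatenate_record <- function(sequences, loci = default_loci(), db = NULL) {
  loci <- .check_loci(loci)
  miss <- setdiff(loci$name, names(sequences))
  if (length(miss)) stop("missing locus: ", paste(miss, collapse = ", "))
  parts <- vapply(loci$name, function(lc) {
    s <- sequences[[lc]]
    if (is.numeric(s)) {
      if (is.null(db)) stop("allele ids given but no db supplied")
      if (s < 1 || s > length(db$alleles[[lc]]))
        stop("unknown allele id ", s, " for locus ", lc)
      s <- db$alleles[[lc]][s]
    }
    as.character(s)
  }, character(1))
  paste(parts, collapse = "")
}

#' Read / write PubMLST-style profile tables
#'
#' Tab-separated table with header `ST` followed by the locus names, one row
#' per sequence type. `write_profiles()` then `read_profiles()` is the
#' identity.
#'
#' @param path file path.
#' @param loci locus definition table (checked against the header).
#' @return For `read_profiles`, an integer matrix with rownames = ST ids.
#' @export
read_profiles <- function(path, loci = default_loci()) {
  loci <- .check_loci(loci)
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (!identical(names(tab)[1L], "ST"))
    stop("malformed header: first column must be 'ST'")
  miss <- setdiff(loci$name, names(tab))
  if (length(miss)) stop("header missing locus: ", paste(miss, collapse = ", "))
  cells <- as.matrix(tab[, c("ST", loci$name)])
  if (any(!grepl("^[0-9]+$", cells)))
    stop("non-integer cell in profile table")
  st <- as.integer(tab$ST)
  if (anyDuplicated(st)) stop("duplicated ST id in profile table")
  m <- matrix(as.integer(as.matrix(tab[, loci$name])), nrow = nrow(tab),
              dimnames = list(as.character(st), loci$name))
  m
}

#' @rdname read_profiles
#' @param registry integer matrix of profiles, rownames = ST ids.
#' @export
write_profiles <- function(registry, path, loci = default_loci()) {
  loci <- .check_loci(loci)
  registry <- registry[, loci$name, drop = FALSE]
  out <- data.frame(ST = rownames(registry), registry, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
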