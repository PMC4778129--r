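test_that("sequence validation reports length, alphabet and stop-codon violations", {
  toy <- locus_def("toy", 9)
  ok <- "ATGGGGCCC"
  expect_length(validate_sequence(toy, ok), 0)
  expect_match(validate_sequence(toy, "ATGGGGCC"), "wrong length")
  expect_match(validate_sequence(toy, "ATGGGGCCN"), "non-ACGT")
  # codon 2 = TAA read off the codon table by hand
  expect_match(validate_sequence(toy, "ATGTAAGGG"), "stop codon TAA at codon 2")
  # stop straddling the declared frame offset is not a stop in frame 1
  toy1 <- locus_def("toy1", 10, frame_offset = 1)
  expect_length(validate_sequence(toy1, "TATGGGGCCC"), 0)
  # trailing incomplete codon is not scanned
  toy10 <- locus_def("toy10", 10)
  expect_length(validate_sequence(toy10, "ATGGGGCCCT"), 0)
})

test_that("allele numbering is first-occurrence order, idempotent, and collapses duplicates", {
  loci <- toy_loci(1, 9)
  s <- c("ATGGGGCCC", "ATGGGGCCA", "ATGGGGCCC", "ATGCCCCCA")
  db <- build_allele_database(list(L1 = setNames(s, paste0("i", 1:4))), loci)
  expect_identical(db$alleles$L1, unique(s))
  db2 <- build_allele_database(list(L1 = setNames(s, paste0("i", 1:4))), loci)
  expect_identical(db$alleles, db2$alleles)
  # 10 sequences, 4 unique: ids equal the order-preserving dedup oracle
  set.seed(5)
  pool <- replicate(4, random_coding_seq(9))
  seqs <- sample(pool, 10, replace = TRUE)
  seqs <- c(pool, seqs)[1:10]  # ensure all four appear
  db3 <- build_allele_database(list(L1 = setNames(seqs, paste0("i", 1:10))), loci)
  ids <- vapply(seqs, function(x) match(x, db3$alleles$L1), integer(1))
  expect_identical(unname(ids), dedup_oracle(seqs))
})

test_that("invalid input is rejected naming isolate and locus", {
  loci <- toy_loci(1, 9)
  expect_error(
    build_allele_database(list(L1 = c(iso7 = "ATGTAAGGG")), loci),
    "iso7.*L1|L1.*iso7")
  expect_error(build_allele_database(list(bogus = c(a = "AAA")), loci),
               "unknown locus")
})

test_that("allele calling distinguishes query and extend modes", {
  loci <- toy_loci(1, 9)
  s1 <- "ATGGGGCCC"; s3 <- "ATGCCCGGG"
  db <- build_allele_database(list(L1 = c(a = s1)), loci)
  expect_identical(call_allele(db, "L1", s1)$allele_id, 1L)
  q <- call_allele(db, "L1", s3)
  expect_true(q$novel)
  expect_true(is.na(q$allele_id))
  e <- call_allele(db, "L1", s3, extend = TRUE)
  expect_identical(e$allele_id, 2L)
  expect_length(e$db$alleles$L1, 2L)
  expect_error(call_allele(db, "nope", s1), "unknown locus")
})

test_that("ST assignment groups identical profiles with contiguous first-occurrence ids", {
  p <- rbind(a = c(1,1,1,1,1,1,1,1), b = c(1,1,1,1,1,1,1,2),
             c = c(1,1,1,1,1,1,1,1))
  sts <- assign_sts(p)
  expect_identical(unname(sts$st_of), c(1L, 2L, 1L))
  expect_identical(nrow(sts$registry), 2L)
  expect_identical(assign_sts(p[1, , drop = FALSE])$st_of[["a"]], 1L)
  expect_error(assign_sts(rbind(c(1, NA, 1, 1, 1, 1, 1, 1))), "positive")
})

test_that("allele and ST numbering are permutation-covariant: classes never merge or split", {
  set.seed(11)
  prof <- matrix(sample.int(3, 30 * 4, replace = TRUE), 30, 4)
  rownames(prof) <- paste0("i", 1:30)
  sts1 <- assign_sts(prof)
  perm <- sample.int(30)
  sts2 <- assign_sts(prof[perm, ])
  # same partition of isolates into ST classes: compare each isolate's
  # canonical class signature (sorted co-members)
  signature <- function(sts) {
    classes <- split(names(sts$st_of), sts$st_of)
    sig <- vapply(classes, function(m) paste(sort(m), collapse = ","),
                  character(1))
    out <- sig[as.character(sts$st_of)]
    names(out) <- names(sts$st_of)
    out[sort(names(out))]
  }
  expect_identical(signature(sts1), signature(sts2))
  expect_lte(nrow(sts1$registry), nrow(prof))
})

test_that("concatenation follows scheme order and sums locus lengths", {
  loci <- toy_loci(8, 3)
  rec <- setNames(rep(list("ATG"), 8), loci$name)
  expect_identical(nchar(concatenate_record(rec, loci)), 24L)
  expect_error(concatenate_record(rec[-8], loci), "L8")
  # default scheme gives the 4261-bp multi-locus fragment
  cfg <- simulation_config(n_isolates = 1, n_lineages = 1, seed = 3)
  anc <- make_ancestors(cfg)
  expect_identical(nchar(concatenate_record(anc$A1)), 4261L)
})

test_that("profile TSV round-trips and rejects malformed tables", {
  loci <- toy_loci(8, 3)
  reg <- matrix(sample.int(4, 24, replace = TRUE), 3, 8,
                dimnames = list(1:3, loci$name))
  f <- tempfile(fileext = ".tsv")
  write_profiles(reg, f, loci)
  back <- read_profiles(f, loci)
  expect_identical(back, reg)
  # byte-stable after canonical sorting by ST id
  f2 <- tempfile(fileext = ".tsv")
  write_profiles(back[order(as.integer(rownames(back))), ], f2, loci)
  expect_identical(readLines(f), readLines(f2))
  # malformed: missing locus, non-integer cell, duplicated ST
  tab <- read.delim(f, check.names = FALSE)
  writeLines(c(paste(c("ST", loci$name[-1]), collapse = "\t"), "1\t1\t1\t1\t1\t1\t1\t1"), f2)
  expect_error(read_profiles(f2, loci), "missing locus")
  tab2 <- tab; tab2$L1[1] <- "x"
  write.table(tab2, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_profiles(f2, loci), "non-integer")
  tab3 <- rbind(tab, tab[1, ])
  write.table(tab3, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_profiles(f2, loci), "duplicated ST")
})

test_that("typing from per-locus sequence sets matches allele database contents", {
  loci <- toy_loci(3, 9)
  set.seed(21)
  pool <- lapply(1:3, function(i) replicate(3, random_coding_seq(9)))
  seqs <- setNames(lapply(pool, function(p)
    setNames(sample(p, 6, replace = TRUE), paste0("i", 1:6))), loci$name)
  typed <- type_isolates(seqs, loci)
  for (lc in loci$name) {
    expect_identical(length(typed$db$alleles[[lc]]),
                     length(unique(seqs[[lc]])))
    expect_identical(unname(typed$profiles[, lc]),
                     dedup_oracle(unname(seqs[[lc]])))
  }
  expect_error(type_isolates(seqs[-1], loci), "missing locus")
})
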