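test_that("polymorphic sites are columns with two or more observed bases", {
  aln <- c("AAAAAAAAAAAA", "AAAAAAAAAAAA")
  expect_length(polymorphic_sites(aln), 0)
  # 4x12 alignment built with exactly 3 segregating columns (2, 7, 12)
  aln <- c("AAAAAAAAAAAA",
           "ACAAAAGAAAAA",
           "AAAAAACAAAAT",
           "ACAAAAAAAAAA")
  expect_identical(polymorphic_sites(aln), c(2L, 7L, 12L))
  expect_error(polymorphic_sites(c("AAA", "AAAA")), "ragged")
})

test_that("GC content is the percent of G+C over all bases", {
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content(c("ATGC", "ATGC")), 50)
})

test_that("nucleotide diversity equals the brute-force all-pairs average", {
  expect_equal(nucleotide_diversity(c("ACGTACGTAC", "ACGTACGTAC")), 0)
  expect_equal(nucleotide_diversity(c("ACGTACGTAC", "ACGTACGTAT")), 0.1)
  set.seed(31)
  aln <- replicate(5, paste(sample(c("A","C","G","T"), 30, TRUE), collapse = ""))
  expect_equal(nucleotide_diversity(aln), pi_oracle(aln), tolerance = 1e-12)
  # invariant under sequence permutation
  expect_equal(nucleotide_diversity(aln[c(3, 1, 5, 2, 4)]),
               nucleotide_diversity(aln), tolerance = 1e-15)
  expect_error(nucleotide_diversity("ACGT"), "at least 2")
})

test_that("SNP sites are classified by amino-acid effect of the varying position", {
  # GAA <-> GAG: third position, Glu/Glu -> synonymous
  s <- classify_snp_sites(c("GAA", "GAG"))
  expect_identical(c(s$n_nsnp, s$n_ssnp), c(0L, 1L))
  # GAA <-> GGA: second position, Glu/Gly -> nonsynonymous
  s <- classify_snp_sites(c("GAA", "GGA"))
  expect_identical(c(s$n_nsnp, s$n_ssnp), c(1L, 0L))
  # monomorphic alignment -> (0, 0)
  s <- classify_snp_sites(c("ATGGGG", "ATGGGG"))
  expect_identical(c(s$n_nsnp, s$n_ssnp), c(0L, 0L))
  # a site outside any complete codon is left unclassified
  s <- classify_snp_sites(c("ATGG", "ATGT"))
  expect_identical(c(s$n_nsnp, s$n_ssnp), c(0L, 0L))
  expect_identical(s$sites$position, 4L)
  expect_error(classify_snp_sites(c("TAAGGG", "TATGGG")), "stop codon")
})

test_that("Nei-Gojobori counts match the hand-enumerated two-codon oracle", {
  # TTT GAA vs TTC GGA, worked through the codon table by hand:
  # sites (stop-excluded): S(TTT)=1/3, S(GAA)=1/3, S(TTC)=1/3, S(GGA)=1,
  # pair average S = 1, N = 5; diffs: TTT->TTC synonymous, GAA->GGA
  # nonsynonymous, so sd = 1 (pS = 1, Jukes-Cantor undefined), nd = 1 (pN = 0.2)
  r <- dn_ds(c("TTTGAA", "TTCGGA"))
  expect_equal(r$syn_sites, 1)
  expect_equal(r$nonsyn_sites, 5)
  expect_equal(r$syn_diffs, 1)
  expect_equal(r$nonsyn_diffs, 1)
  expect_equal(r$ps, 1)
  expect_equal(r$pn, 0.2)
  expect_true(is.nan(r$ds))
  expect_true(r$undefined)
})

test_that("dN/dS follows the stated ratio conventions", {
  # only synonymous differences -> dN = 0, ratio 0
  r <- dn_ds(c("GAAGAA", "GAGGAA"))
  expect_equal(r$dn, 0)
  expect_equal(r$ratio, 0)
  # identical sequences -> flagged, ratio 0 by the dN = 0 convention
  r <- dn_ds(c("GAAGAA", "GAAGAA"))
  expect_true(r$identical)
  expect_equal(r$ratio, 0)
  expect_error(dn_ds(c("TA", "TA")), "shorter than one codon")
})

test_that("dN/dS is order-symmetric and matches an independent pairwise oracle", {
  set.seed(41)
  base <- random_coding_seq(30)
  aln <- vapply(1:5, function(i) {
    s <- base
    for (k in sample.int(30, 3)) {
      repeat {
        b <- sample(c("A","C","G","T"), 1)
        cand <- s; substr(cand, k, k) <- b
        if (length(validate_sequence(locus_def("x", 30), cand)) == 0) break
      }
      s <- cand
    }
    s
  }, character(1))
  r1 <- dn_ds(aln)
  r2 <- dn_ds(rev(aln))
  expect_equal(r1$dn, r2$dn, tolerance = 1e-12)
  expect_equal(r1$ds, r2$ds, tolerance = 1e-12)
  orc <- ng86_oracle(aln)
  expect_equal(r1$dn, orc$dn, tolerance = 1e-10)
  expect_equal(r1$ds, orc$ds, tolerance = 1e-10)
})

test_that("diversity table rows agree with the allele registry and simulator truth", {
  loci <- toy_loci(3, 60)
  cfg <- simulation_config(loci = loci, n_lineages = 2,
                           ancestor_divergence = 0.02, n_isolates = 30,
                           mu = 2e-3, rho = 0, seed = 17)
  sim <- evolve_population(cfg)
  typed <- type_isolates(sim$sequences, loci)
  tab <- diversity_table(sim$sequences, loci)
  for (lc in loci$name) {
    row <- tab[tab$locus == lc, ]
    expect_identical(row$n_alleles, length(unique(sim$sequences[[lc]])))
    expect_identical(row$n_alleles, length(typed$db$alleles[[lc]]))
    expect_identical(row$n_polymorphic,
                     length(polymorphic_sites(sim$sequences[[lc]])))
  }
  crow <- tab[tab$locus == "concatenated", ]
  expect_identical(crow$n_alleles,
                   nrow(assign_sts(typed$profiles)$registry))
  expect_identical(crow$n_polymorphic,
                   sum(tab$n_polymorphic[tab$locus != "concatenated"]))
  # single-isolate subset: one allele everywhere, pi undefined
  tab1 <- diversity_table(sim$sequences, loci, subset = "iso001")
  expect_true(all(tab1$n_alleles == 1L))
  expect_true(all(is.na(tab1$pi)))
  expect_error(diversity_table(sim$sequences, loci, subset = "nobody"),
               "empty subset")
})

test_that("pi of the concatenation is the length-weighted mean of per-locus pi", {
  loci <- toy_loci(3, 45)
  loci$expected_length <- c(45L, 90L, 30L)
  loci2 <- do.call(rbind, lapply(1:3, function(i)
    locus_def(paste0("L", i), c(45L, 90L, 30L)[i], 0, i)))
  cfg <- simulation_config(loci = loci2, n_lineages = 2,
                           ancestor_divergence = 0.03, n_isolates = 12,
                           mu = 3e-3, rho = 0, seed = 23)
  sim <- evolve_population(cfg)
  iso <- names(sim$sequences$L1)
  concat <- vapply(iso, function(i)
    concatenate_record(lapply(sim$sequences, `[[`, i), loci2), character(1))
  per_locus <- vapply(sim$sequences, nucleotide_diversity, numeric(1))
  lens <- loci2$expected_length
  expect_equal(nucleotide_diversity(concat),
               sum(per_locus * lens) / sum(lens), tolerance = 1e-12)
})
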