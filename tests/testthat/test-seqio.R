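test_that("alignment construction validates symbols, names and lengths", {
  aln <- alignment(c(tax1 = "ACGT", tax2 = "ACGA"))
  expect_equal(n_sites(aln), 4L)
  expect_equal(taxa(aln), c("tax1", "tax2"))
  # case folding and U -> T on construction
  aln2 <- alignment(c(a = "acgu", b = "ACGT"))
  expect_equal(unclass(aln2)[1, ], unclass(aln2)[2, ], ignore_attr = TRUE)
  expect_error(alignment(c(a = "ACGX")), "illegal symbol 'X'.*column 4")
  expect_error(alignment(c(a = "ACGT", a = "ACGT")), "duplicate")
  expect_error(alignment(c(a = "ACGT", b = "ACG")), "unequal")
})

test_that("PHYLIP read handles sequential, interleaved and wrapped layouts", {
  d <- withr::local_tempdir()
  seqs <- c(alpha = "ACGTACGTAC", beta = "ACGAACGTAC", gamma = "TCGTACGAAC")
  # sequential with wrapped lines
  f1 <- file.path(d, "seq.phy")
  writeLines(c("3 10", "alpha ACGTA", "CGTAC",
               "beta ACGAACGTAC", "gamma TCGTA", "CGAAC"), f1)
  a1 <- read_alignment(f1, "phylip")
  expect_equal(apply(a1, 1, paste, collapse = ""), seqs)
  # interleaved in two blocks
  f2 <- file.path(d, "int.phy")
  writeLines(c("3 10", "alpha ACGTA", "beta  ACGAA", "gamma TCGTA",
               "", "CGTAC", "CGTAC", "CGAAC"), f2)
  a2 <- read_alignment(f2, "phylip")
  expect_equal(apply(a2, 1, paste, collapse = ""), seqs)
  # header/sequence mismatches are reported
  f3 <- file.path(d, "bad.phy")
  writeLines(c("2 12", "a ACGT", "b ACGT"), f3)
  expect_error(read_alignment(f3, "phylip"), "could not parse")
  f4 <- file.path(d, "badsym.phy")
  writeLines(c("1 4", "a ACXT"), f4)
  expect_error(read_alignment(f4, "phylip"), "illegal symbol")
})

test_that("read/write round-trips preserve alignments in both formats", {
  d <- withr::local_tempdir()
  set.seed(7)
  aln <- random_alignment(6, 40, symbols = c("A", "C", "G", "T", "N", "-",
                                             "R", "M"))
  for (fmt in c("phylip", "fasta")) {
    p <- file.path(d, paste0("rt.", fmt))
    write_alignment(aln, p, fmt)
    back <- read_alignment(p, fmt)
    expect_identical(unclass(back), unclass(aln), label = fmt)
  }
})

test_that("a 20 x 20000 PHYLIP alignment reads with full dimensions", {
  d <- withr::local_tempdir()
  aln <- bernoulli_snp_alignment(20, 20000, 0.05, seed = 11)
  p <- file.path(d, "big.phy")
  write_alignment(aln, p, "phylip")
  expect_identical(readLines(p, n = 1L), "20 20000")
  back <- read_alignment(p, "phylip")
  expect_equal(dim(back), c(20L, 20000L))
})

test_that("pattern compression conserves site counts and multiplicities", {
  aln <- alignment(c(a = "AAAA", b = "AAAA"))
  pat <- compress_patterns(aln)
  expect_equal(length(pat$weights), 1L)
  expect_equal(pat$weights, 4L)
  aln2 <- alignment(c(a = "AAA", b = "ACA"))
  pat2 <- compress_patterns(aln2)
  expect_equal(pat2$weights, c(2L, 1L))
  expect_equal(pat2$patterns[, 1], c(a = "A", b = "A"))
  set.seed(3)
  big <- random_alignment(20, 1000)
  expect_equal(sum(compress_patterns(big)$weights), 1000L)
})

test_that("snp_density counts resolved polymorphisms per kilobase", {
  expect_equal(snp_density(alignment(c(a = "AAAA", b = "AAAA"))), 0)
  expect_equal(snp_density(alignment(c(a = "AAAAAAAAAA",
                                       b = "AAAAAAAAAC"))), 100)
  expect_equal(snp_density(alignment(c(a = "ACGT", b = "CGTA"))), 1000)
  # ambiguity codes and missing data never segregate
  expect_equal(snp_density(alignment(c(a = "ANR-", b = "AN?M"))), 0)
  # invariant to row and column order
  set.seed(5)
  aln <- random_alignment(8, 200)
  shuf <- alignment(unclass(aln)[sample(8), sample(200)])
  expect_equal(snp_density(shuf), snp_density(aln))
})
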