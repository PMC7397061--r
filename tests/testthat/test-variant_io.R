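test_that("GT fields decode to alternate allele counts", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "sA", "sB", sep = "\t"),
    paste("chr1", "100", ".", "A", "G", ".", ".", ".", "GT", "0/1", "1/1",
          sep = "\t"),
    paste("chr1", "200", ".", "C", "T", ".", ".", ".", "GT", "./.", "0|1",
          sep = "\t")), vcf)
  gm <- read_vcf(vcf)$matrix
  expect_equal(unname(gm$calls[1, ]), c(1L, 2L))
  expect_equal(unname(gm$calls[2, ]), c(NA_integer_, 1L))
})

test_that("non-diploid genotypes and missing GT keys are rejected", {
  base <- c("##fileformat=VCFv4.2",
            paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                  "INFO", "FORMAT", "sA", sep = "\t"))
  v1 <- tempfile(fileext = ".vcf")
  writeLines(c(base, paste("chr1", "5", ".", "A", "G", ".", ".", ".", "GT",
                           "0/1/1", sep = "\t")), v1)
  expect_error(read_vcf(v1), "non-diploid")
  v2 <- tempfile(fileext = ".vcf")
  writeLines(c(base, paste("chr1", "5", ".", "A", "G", ".", ".", ".", "DP",
                           "13", sep = "\t")), v2)
  expect_error(read_vcf(v2), "no GT key")
})

test_that("a sample sheet sample absent from the VCF is reported", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "sA", sep = "\t"),
               paste("chr1", "5", ".", "A", "G", ".", ".", ".", "GT", "0/1",
                     sep = "\t")), vcf)
  sheet <- make_sheet(c("sA", "ghost"), n_cases = 1L)
  expect_error(read_vcf(vcf, sheet), "ghost")
})

test_that("write/read round-trip is the identity, including missing calls", {
  set.seed(11)
  for (rep in 1:3) {
    gm <- make_random_matrix(n_var = 20L, samples = paste0("s", 1:5))
    path <- tempfile(fileext = ".vcf")
    write_vcf(gm, path)
    back <- read_vcf(path)$matrix
    expect_equal(back$variants[c("contig", "pos", "ref", "alt")],
                 gm$variants[c("contig", "pos", "ref", "alt")])
    expect_equal(back$calls, gm$calls)
    expect_equal(back$samples, gm$samples)
  }
})

test_that("an empty matrix writes a header-only VCF that reads back empty", {
  gm <- genotype_matrix(casevar:::empty_variant_table(), c("a", "b"),
                        matrix(integer(0), 0, 2))
  path <- tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  expect_false(any(!startsWith(readLines(path), "#")))
  expect_equal(nrow(read_vcf(path)$matrix$variants), 0L)
})

test_that("unsorted records are sorted on write, with a notice", {
  v <- variant_table(c("chr2", "chr1"), c(50L, 100L), c("A", "C"),
                     c("G", "T"))
  gm <- genotype_matrix(v, "s1", matrix(c(1L, 2L), 2, 1))
  path <- tempfile(fileext = ".vcf")
  expect_message(write_vcf(gm, path), "sorting on write")
  back <- read_vcf(path)$matrix
  expect_equal(back$variants$contig, c("chr1", "chr2"))
  expect_equal(unname(back$calls[, 1]), c(2L, 1L))
})

test_that("parsed matrix agrees with an independent line-by-line text parse", {
  set.seed(21)
  gm <- make_random_matrix(n_var = 20L, samples = paste0("s", 1:5))
  path <- tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  ora <- oracle_parse_vcf(path)
  got <- read_vcf(path)$matrix
  expect_equal(got$variants$pos, ora$variants$pos)
  expect_equal(got$variants$alt, ora$variants$alt)
  expect_equal(unname(got$calls), unname(ora$calls))
})

test_that("multiallelic records split into per-allele biallelic rows", {
  # REF=A ALT=C,G with GT 1/2 counts each allele once
  sp <- split_multiallelic("chr1", 100L, "A", c("C", "G"),
                           c("1/2", "0/1", "2/2"))
  expect_equal(nrow(sp$variants), 2L)
  expect_equal(sp$calls[1, ], c(1L, 1L, 0L))  # allele C
  expect_equal(sp$calls[2, ], c(1L, 0L, 2L))  # allele G
  # biallelic record passes through unchanged
  sp1 <- split_multiallelic("chr1", 100L, "A", "C", c("0/1", "1/1"))
  expect_equal(sp1$calls[1, ], c(1L, 2L))
})

test_that("multiallelic split conserves per-sample total ALT allele count", {
  set.seed(31)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    gts <- vapply(1:6, function(j)
      paste(sample(0:k, 2, TRUE), collapse = "/"), character(1))
    sp <- split_multiallelic("c", 1L, "A",
                             c("C", "G", "T", "AA")[seq_len(k)], gts)
    tally <- vapply(gts, function(g) {
      al <- as.integer(strsplit(g, "/")[[1]])
      sum(al > 0L)
    }, integer(1))
    expect_equal(unname(colSums(sp$calls)), unname(tally))
  }
})

test_that("variant normalization matches examples and the brute-force search", {
  ref <- c(chr1 = paste0(strrep("ACGT", 24), "A",  # 97 bases
                         "CATTTTTGCC", strrep("GATC", 10)))
  # minimal SNV is untouched (position 98 is 'C')
  n <- normalize_variant("chr1", 98L, "C", "G", ref)
  expect_equal(n[c("pos", "ref", "alt")], list(pos = 98L, ref = "C",
                                               alt = "G"))
  # shared leading base trimmed: CA>CG at 98 -> 99 A>G
  n2 <- normalize_variant("chr1", 98L, "CA", "CG", ref)
  expect_equal(n2[c("pos", "ref", "alt")],
               oracle_normalize("chr1", 98L, "CA", "CG", ref))
  expect_equal(n2$pos, 99L)
  # homopolymer deletion left-aligns to the run's anchor
  # run of T at 100..104; delete one T at the right edge
  n3 <- normalize_variant("chr1", 103L, "TT", "T", ref)
  expect_equal(n3[c("pos", "ref", "alt")],
               oracle_normalize("chr1", 103L, "TT", "T", ref))
  expect_lt(n3$pos, 103L)
  # REF disagreement is an error carrying both strings
  expect_error(normalize_variant("chr1", 98L, "T", "G", ref),
               "disagrees with reference")
})

test_that("normalization equals the brute-force oracle and is idempotent", {
  set.seed(41)
  ref <- c(chr1 = rand_seq(400L))
  for (rep in 1:40) {
    pos <- sample(50:300, 1)
    lr <- sample(1:4, 1)
    r <- substr(ref[["chr1"]], pos, pos + lr - 1L)
    repeat {
      a <- rand_seq(sample(1:4, 1))
      if (a != r) break
    }
    n1 <- normalize_variant("chr1", pos, r, a, ref)
    ora <- oracle_normalize("chr1", pos, r, a, ref)
    expect_equal(n1[c("pos", "ref", "alt")], ora)
    n2 <- normalize_variant(n1$contig, n1$pos, n1$ref, n1$alt, ref)
    expect_equal(n2, n1)
  }
})
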