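test_that("genomic positions map into CDS coordinates on both strands", {
  set.seed(61)
  ref <- c(chr1 = rand_seq(300L))
  tm <- transcript_model("t", "g", "chr1", "+", c(101L, 201L),
                         c(150L, 252L))
  expect_equal(genomic_to_cds(tm, 101L), 1L)
  expect_equal(genomic_to_cds(tm, 201L), 51L)   # spans the intron
  expect_true(is.na(genomic_to_cds(tm, 175L)))  # intronic
  tm_m <- transcript_model("t", "g", "chr1", "-", c(101L, 201L),
                           c(150L, 252L))
  expect_equal(genomic_to_cds(tm_m, 252L), 1L)  # first antisense CDS base
  expect_equal(genomic_to_cds(tm_m, 150L), 53L)
})

test_that("genomic_to_cds is a bijection onto 1..CDS_length", {
  set.seed(62)
  for (strand in c("+", "-")) {
    fx <- make_random_tx(n_codons = 20L, strand = strand, n_exons = 3L)
    tm <- fx$tm
    gpos <- unlist(lapply(seq_along(tm$cds_starts), function(i)
      tm$cds_starts[i]:tm$cds_ends[i]))
    cds <- genomic_to_cds(tm, gpos)
    expect_setequal(cds, seq_len(tm$cds_length))
    expect_false(anyDuplicated(cds) > 0)
  }
})

test_that("a G>A at CDS 1658 of a CGA codon 553 is missense Arg553Gln", {
  # forward-strand transcript of 560 codons, one long exon
  set.seed(63)
  n_codons <- 560L
  start <- 1001L
  tm <- transcript_model("tx", "PCK2", "chr1", "+", start,
                         start + 3L * n_codons - 1L)
  seq <- rand_seq(start + 3L * n_codons + 500L)
  # plant CGA at codon 553 (CDS bases 1657-1659)
  g <- start + 1656L
  substr(seq, g, g + 2L) <- "CGA"
  ref <- c(chr1 = seq)
  eff <- annotate_snv(tm, ref, "chr1", g + 1L, "G", "A")
  expect_equal(eff$cds_pos, 1658L)
  expect_equal(eff$residue_index, 553L)
  expect_equal(eff$ref_aa, "Arg")
  expect_equal(eff$alt_aa, "Gln")
  expect_equal(eff$effect_class, "missense")
  expect_equal(eff$c_hgvs, "c.1658G>A")
  expect_equal(eff$p_hgvs, "p.(Arg553Gln)")
  expect_equal(annotate_snv(tm, ref, "chr1", g + 1L, "G", "A",
                            parenthesized = FALSE)$p_hgvs, "p.Arg553Gln")
  # third-position CGA>CGG stays arginine: synonymous
  eff_syn <- annotate_snv(tm, ref, "chr1", g + 2L, "A", "G")
  expect_equal(eff_syn$effect_class, "synonymous")
  expect_equal(eff_syn$ref_aa, "Arg")
})

test_that("reference-base disagreement at the locus is an error", {
  ref <- c(chr1 = strrep("ACG", 40))
  tm <- transcript_model("t", "g", "chr1", "+", 1L, 30L)
  expect_error(annotate_snv(tm, ref, "chr1", 1L, "C", "T"), "reference base")
})

test_that("annotator agrees with a whole-CDS translate-and-diff oracle", {
  set.seed(64)
  n_checked <- 0L
  while (n_checked < 200L) {
    strand <- sample(c("+", "-"), 1)
    fx <- make_random_tx(n_codons = 30L, strand = strand,
                         n_exons = sample(2:3, 1))
    tm <- fx$tm; ref <- fx$reference
    # several SNVs per transcript, anywhere in its span plus flanks
    for (k in 1:10) {
      pos <- sample(nchar(ref[[1]]), 1)
      r <- substr(ref[[1]], pos, pos)
      a <- sample(setdiff(c("A", "C", "G", "T"), r), 1)
      got <- annotate_snv(tm, ref, "chr1", pos, r, a)
      ora <- oracle_annotate(tm, ref, "chr1", pos, r, a)
      expect_equal(got$effect_class, ora$effect_class)
      if (!is.na(got$cds_pos)) {
        expect_equal(got$residue_index, ora$residue_index)
        if (got$effect_class != "synonymous") {
          expect_equal(got$ref_aa, aa_three_letter(ora$ref_aa))
          expect_equal(got$alt_aa, aa_three_letter(ora$alt_aa))
        }
      }
      n_checked <- n_checked + 1L
    }
  }
})

test_that("annotation is invariant under strand mirroring of the fixture", {
  set.seed(65)
  for (rep in 1:20) {
    fx <- make_random_tx(n_codons = 15L, strand = "+", n_exons = 2L)
    tm <- fx$tm; ref <- fx$reference
    L <- nchar(ref[[1]])
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    # mirrored fixture: reverse-complement contig, flip intervals
    ref_m <- c(chr1 = as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(ref[[1]]))))
    tm_m <- transcript_model("t", "g", "chr1", "-",
                             L - tm$cds_ends + 1L, L - tm$cds_starts + 1L)
    # a coding SNV and its mirror
    cds_pos <- sample(tm$cds_length, 1)
    pos <- casevar:::cds_genomic_positions(tm)[cds_pos]
    r <- substr(ref[[1]], pos, pos)
    a <- sample(setdiff(c("A", "C", "G", "T"), r), 1)
    e1 <- annotate_snv(tm, ref, "chr1", pos, r, a)
    e2 <- annotate_snv(tm_m, ref_m, "chr1", L - pos + 1L,
                       comp[[r]], comp[[a]])
    expect_equal(e2[c("effect_class", "cds_pos", "ref_codon", "alt_codon",
                      "ref_aa", "alt_aa", "residue_index", "c_hgvs",
                      "p_hgvs")],
                 e1[c("effect_class", "cds_pos", "ref_codon", "alt_codon",
                      "ref_aa", "alt_aa", "residue_index", "c_hgvs",
                      "p_hgvs")])
  }
})

test_that("protein-changing classes are exactly the amino-acid-altering ones", {
  expect_true(all(is_protein_changing(c("missense", "nonsense", "stop_loss",
                                        "start_loss"))))
  expect_false(any(is_protein_changing(c("synonymous", "intronic",
                                         "utr_or_noncoding", "intergenic"))))
})

test_that("multi-transcript annotation reports the most severe class", {
  set.seed(66)
  ref <- c(chr1 = rand_seq(400L))
  # two overlapping-gene models: position 150 is coding in tm1, intronic in tm2
  tm1 <- transcript_model("t1", "g1", "chr1", "+", c(101L, 301L),
                          c(200L, 302L))
  tm2 <- transcript_model("t2", "g2", "chr1", "+", c(50L, 350L),
                          c(100L, 352L))
  r <- substr(ref[[1]], 150L, 150L)
  a <- setdiff(c("A", "C", "G", "T"), r)[1]
  eff <- annotate_snv_multi(list(tm1, tm2), ref, "chr1", 150L, r, a)
  expect_true(eff$effect_class %in%
                c("synonymous", "missense", "nonsense", "stop_loss"))
  expect_equal(eff$tx_id, "t1")
  # no overlapping transcript: intergenic
  eff2 <- annotate_snv_multi(list(tm1, tm2), ref, "chr2", 150L, "A", "G")
  expect_equal(eff2$effect_class, "intergenic")
})
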