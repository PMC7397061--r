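test_that("the same spec yields byte-identical bundles", {
  spec <- small_sim_spec(seed = 101L)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_fixture(spec, d1)
  simulate_fixture(spec, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
})

test_that("truth-table category totals equal the spec counts", {
  spec <- small_sim_spec(seed = 102L)
  fx <- simulate_fixture(spec, tempfile())
  tr <- fx$truth
  expect_equal(sum(tr$category == "het_shared"), spec$het_shared)
  expect_equal(sum(tr$category == "hom_shared"), spec$hom_shared)
  expect_equal(sum(tr$category == "het_shared" & tr$protein_changing),
               spec$protein_changing_het)
  expect_equal(sum(tr$category == "hom_shared" & tr$protein_changing),
               spec$protein_changing_hom)
  expect_equal(sum(tr$category == "background"), spec$n_background)
  expect_equal(sum(startsWith(tr$category, "singleton:")),
               (spec$n_cases + spec$n_controls) *
                 spec$n_singletons_per_sample)
  expect_equal(sum(tr$causal), 1L)
  # no two planted variants collide in position
  expect_false(anyDuplicated(paste(tr$contig, tr$pos)) > 0)
})

test_that("the planted causal variant annotates as the expected missense", {
  fx <- simulate_fixture(small_sim_spec(seed = 103L), tempfile())
  tms <- read_transcripts_gff3(fx$paths$gff3)
  cz <- fx$causal
  eff <- annotate_snv_multi(tms, fx$reference, cz$contig, cz$pos, cz$ref,
                            cz$alt)
  expect_equal(eff$effect_class, "missense")
  expect_equal(eff$gene, "PCK2")
  expect_equal(eff$residue_index, 553L)
  expect_equal(eff$cds_pos, 1658L)
  expect_equal(eff$ref_aa, "Arg")
  expect_equal(eff$alt_aa, "Gln")
  expect_equal(eff$c_hgvs, "c.1658G>A")
})

test_that("generated VCF round-trips and genotypes honor the plant design", {
  fx <- simulate_fixture(small_sim_spec(seed = 104L), tempfile())
  sheet <- read_sample_sheet(fx$paths$sample_sheet)
  gm <- read_vcf(fx$paths$vcf, sheet)$matrix
  # round-trip through variant_io
  p2 <- tempfile(fileext = ".vcf")
  write_vcf(gm, p2)
  gm2 <- read_vcf(p2)$matrix
  expect_equal(gm2$calls, gm$calls)
  expect_equal(gm2$variants[c("contig", "pos", "ref", "alt")],
               gm$variants[c("contig", "pos", "ref", "alt")])
  # planted zygosity: case-exclusive rows are het/hom in cases, 0 in controls
  key <- variant_key(gm$variants)
  tr <- fx$truth
  cases <- sheet$sample[sheet$status == "case"]
  controls <- sheet$sample[sheet$status == "control"]
  for (cat_zyg in list(c("het_shared", 1L), c("hom_shared", 2L))) {
    rows <- match(variant_key(tr[tr$category == cat_zyg[1], ]), key)
    expect_true(all(gm$calls[rows, cases] == as.integer(cat_zyg[2])))
    expect_true(all(gm$calls[rows, controls] == 0L))
  }
  bg <- match(variant_key(tr[tr$category == "background", ]), key)
  expect_true(all(rowSums(gm$calls[bg, controls, drop = FALSE] > 0) >= 1))
})

test_that("gene models exercise both strands and the reference validates", {
  fx <- simulate_fixture(small_sim_spec(seed = 105L), tempfile())
  tms <- read_transcripts_gff3(fx$paths$gff3)
  strands <- vapply(tms, function(t) t$strand, character(1))
  contigs <- vapply(tms, function(t) t$contig, character(1))
  for (ct in unique(contigs))
    expect_true("-" %in% strands[contigs == ct])
  # GFF3 geometry matches the in-memory models
  mem <- fx$transcripts
  for (tx in names(mem)) {
    expect_equal(sort(tms[[tx]]$cds_starts), sort(mem[[tx]]$cds_starts))
    expect_equal(tms[[tx]]$gene, mem[[tx]]$gene)
  }
  # reference FASTA matches contig lengths
  ref <- Biostrings::readDNAStringSet(fx$paths$reference)
  expect_equal(stats::setNames(Biostrings::width(ref), names(ref)),
               fx$spec$contig_lengths)
})

test_that("full-pipeline parameter recovery holds across seeds", {
  for (seed in c(201L, 202L, 203L, 204L, 205L)) {
    spec <- small_sim_spec(seed = seed)
    fx <- simulate_fixture(spec, tempfile())
    sheet <- read_sample_sheet(fx$paths$sample_sheet)
    gm <- read_vcf(fx$paths$vcf, sheet)$matrix
    tms <- read_transcripts_gff3(fx$paths$gff3)
    eff <- annotate_matrix(gm, tms, fx$reference)
    fs <- summarize_filter(gm, sheet, eff$effect_class)
    expect_equal(fs$n_het_shared, spec$het_shared)
    expect_equal(fs$n_hom_shared, spec$hom_shared)
    expect_equal(fs$n_case_exclusive_total,
                 spec$het_shared + spec$hom_shared)
    expect_equal(fs$n_protein_changing_het, spec$protein_changing_het)
    expect_equal(fs$n_protein_changing_hom, spec$protein_changing_hom)
  }
})

test_that("simulated alignments reproduce their construction parameters", {
  set.seed(110)
  prot <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 80L,
                       TRUE), collapse = "")
  target <- 40L
  msa <- simulate_msa(prot, target, n_species = 9L, conserved = TRUE)
  expect_length(msa, 9L)
  col <- map_residue_to_column(msa, "dog", target)
  res <- column_conservation(msa, "dog", target)
  expect_equal(res$fraction_identical, 1)
  expect_true(res$strictly_conserved)
  # 2 mutated rows of 10 -> 0.8
  msa2 <- simulate_msa(prot, target, n_species = 10L, conserved = FALSE,
                       n_mutated = 2L)
  res2 <- column_conservation(msa2, "dog", target)
  expect_equal(res2$fraction_identical, 0.8)
  expect_false(res2$strictly_conserved)
})

test_that("sim specs read back from YAML configs", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("seed: 9", "n_controls: 4", "het_shared: 12",
               "hom_shared: 6", "protein_changing_het: 2",
               "n_background: 5", "n_singletons_per_sample: 1",
               "genes_per_contig: 3",
               "contig_lengths:", "  chrZ: 120000"), cfg)
  spec <- read_sim_spec(cfg)
  expect_s3_class(spec, "cohort_sim_spec")
  expect_equal(spec$seed, 9L)
  expect_equal(spec$contig_lengths, c(chrZ = 120000L))
  expect_equal(spec$het_shared, 12L)
})

test_that("impossible spec geometry and counts are rejected", {
  expect_error(cohort_sim_spec(protein_changing_het = 50L, het_shared = 10L),
               "cannot exceed")
  expect_error(cohort_sim_spec(n_cases = 1L), "at least 2 cases")
  expect_error(cohort_sim_spec(causal = list(gene = "G", residue = 553L,
                                             cds_pos = 1657L,
                                             ref_aa = "Arg", alt_aa = "Gln",
                                             strand = "+")),
               "second base")
  tiny <- cohort_sim_spec(contig_lengths = c(c1 = 3000L, c2 = 3000L))
  expect_error(simulate_fixture(tiny, tempfile()), "too short")
})
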