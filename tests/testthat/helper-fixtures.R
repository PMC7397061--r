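# Shared builders for in-memory fixtures.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# a random multi-exon transcript embedded in a random contig
make_random_tx <- function(n_codons = 30L, strand = "+", n_exons = 2L,
                           contig = "chr1", pad = 50L) {
  cds_len <- 3L * n_codons
  cuts <- sort(sample(seq(3L, cds_len - 3L, by = 3L), n_exons - 1L))
  exon_lens <- diff(c(0L, cuts, cds_len))
  introns <- sample(20:60, n_exons - 1L, replace = TRUE)
  starts <- integer(n_exons); ends <- integer(n_exons)
  p <- pad + 1L
  for (e in seq_len(n_exons)) {
    starts[e] <- p; ends[e] <- p + exon_lens[e] - 1L
    p <- ends[e] + 1L + if (e < n_exons) introns[e] else 0L
  }
  total <- p - 1L + pad
  ref <- stats::setNames(rand_seq(total), contig)
  list(tm = transcript_model("tx1", "G1", contig, strand, starts, ends),
       reference = ref)
}

# random genotype matrix over a tiny cohort
make_random_matrix <- function(n_var = 50L, samples = paste0("s", 1:8),
                               p_missing = 0.05) {
  refs <- sample(c("A", "C", "G", "T"), n_var, TRUE)
  alts <- vapply(refs, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
  v <- variant_table(contig = "chr1", pos = sort(sample(10000L, n_var)),
                     ref = refs, alt = alts)
  calls <- matrix(sample(c(0L, 0L, 0L, 1L, 1L, 2L, NA),
                         n_var * length(samples), TRUE,
                         prob = c(rep((1 - p_missing) / 6, 6), p_missing)),
                  n_var, length(samples))
  genotype_matrix(v, samples, calls)
}

make_sheet <- function(samples, n_cases = 2L, n_unknown = 0L) {
  status <- rep("control", length(samples))
  status[seq_len(n_cases)] <- "case"
  if (n_unknown > 0L)
    status[length(samples) - seq_len(n_unknown) + 1L] <- "unknown"
  data.frame(sample = samples, status = status, breed = "b",
             family = NA_character_, stringsAsFactors = FALSE)
}

# small desk-scale simulation spec used across tests
small_sim_spec <- function(seed) {
  cohort_sim_spec(seed = seed,
                  contig_lengths = c(chrA = 150000L, chrB = 150000L),
                  n_cases = 2L, n_controls = 6L,
                  het_shared = 40L, hom_shared = 12L,
                  protein_changing_het = 4L, protein_changing_hom = 0L,
                  n_background = 30L, n_singletons_per_sample = 3L,
                  genes_per_contig = 4L)
}

# Fig-1-style dominant family: affected dam het, affected offspring het,
# unaffected relatives hom-ref, one unknown-phenotype dog
family_pedigree <- function() {
  data.frame(
    family = "F1",
    id = c("sire", "dam", "kid1", "kid2", "kid3", "kid4"),
    sire = c(NA, NA, "sire", "sire", "sire", "sire"),
    dam = c(NA, NA, "dam", "dam", "dam", "dam"),
    sex = c("male", "female", "female", "female", "male", "male"),
    phenotype = c("unaffected", "affected", "affected", "affected",
                  "unaffected", "unknown"),
    stringsAsFactors = FALSE)
}
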