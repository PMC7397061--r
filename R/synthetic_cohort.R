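#' Specification for a synthetic discovery cohort
#'
#' Defines the study conditions a generated fixture emulates: two sequenced
#' cases against a control-genome panel, a planted number of case-exclusive
#' heterozygous and homozygous variants of which a stated subset is
#' protein-changing, background variants carried by controls, per-sample
#' private singletons, and a causal missense SNV placed at a fixed residue
#' of a designated gene (an arginine codon `CGA` whose second base is
#' mutated `G>A`, giving Arg>Gln).
#'
#' @param seed integer seed; the whole bundle is a deterministic function
#'   of the spec.
#' @param contig_lengths named integer vector of contig lengths in bases.
#' @param n_cases,n_controls cohort sizes.
#' @param het_shared,hom_shared planted case-exclusive variant counts per
#'   zygosity model.
#' @param protein_changing_het,protein_changing_hom how many of each
#'   planted category are protein-changing coding SNVs (the rest are
#'   intergenic, intronic or synonymous).
#' @param n_background variants carried by at least one control (excluded
#'   by the case-exclusive filter by construction).
#' @param n_singletons_per_sample private heterozygous variants per sample.
#' @param genes_per_contig synthetic multi-exon genes per contig; at least
#'   one per contig is placed on the minus strand.
#' @param causal list describing the causal variant: `gene`, `residue`
#'   (1-based codon index), `cds_pos` (1-based CDS base, must equal
#'   `(residue-1)*3 + 2`), `ref_aa`, `alt_aa`, `strand`.
#' @return object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(seed = 1L,
                            contig_lengths = c(chrA = 500000L,
                                               chrB = 500000L),
                            n_cases = 2L, n_controls = 20L,
                            het_shared = 1030L, hom_shared = 36L,
                            protein_changing_het = 10L,
                            protein_changing_hom = 0L,
                            n_background = 400L,
                            n_singletons_per_sample = 10L,
                            genes_per_contig = 10L,
                            causal = list(gene = "PCK2", residue = 553L,
                                          cds_pos = 1658L, ref_aa = "Arg",
                                          alt_aa = "Gln", strand = "+")) {
  spec <- list(seed = as.integer(seed), contig_lengths = contig_lengths,
               n_cases = as.integer(n_cases),
               n_controls = as.integer(n_controls),
               het_shared = as.integer(het_shared),
               hom_shared = as.integer(hom_shared),
               protein_changing_het = as.integer(protein_changing_het),
               protein_changing_hom = as.integer(protein_changing_hom),
               n_background = as.integer(n_background),
               n_singletons_per_sample = as.integer(n_singletons_per_sample),
               genes_per_contig = as.integer(genes_per_contig),
               causal = causal)
  if (spec$protein_changing_het > spec$het_shared ||
      spec$protein_changing_hom > spec$hom_shared)
    stop("protein-changing counts cannot exceed their category totals")
  if (spec$n_cases < 2L)
    stop("at least 2 cases required (sharing between cases is the filter)")
  if (spec$protein_changing_het < 1L)
    stop("the causal variant itself is protein-changing; need >= 1")
  if (causal$cds_pos != (causal$residue - 1L) * 3L + 2L)
    stop("causal cds_pos must be the second base of the causal residue's codon")
  if (is.null(names(contig_lengths)) || anyNA(names(contig_lengths)))
    stop("contig_lengths must be named")
  class(spec) <- "cohort_sim_spec"
  spec
}

#' Read a cohort simulation spec from a YAML or JSON file
#'
#' Any subset of the [cohort_sim_spec()] arguments may be given; the rest
#' take their defaults.
#'
#' @param path path to a YAML (or JSON, a YAML subset) config file.
#' @return a `cohort_sim_spec`.
#' @export
read_sim_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$contig_lengths))
    cfg$contig_lengths <- unlist(cfg$contig_lengths)
  do.call(cohort_sim_spec, cfg)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# overwrite 1-based positions of a character-vector genome
poke <- function(seq, pos, bases) {
  for (k in seq_along(pos)) substr(seq, pos[k], pos[k]) <- bases[k]
  seq
}

# write a codon (given in CDS orientation) into the genome for a transcript
write_codon <- function(seq, tm, residue, codon) {
  gpos <- cds_genomic_positions(tm)[(residue - 1L) * 3L + 1:3]
  bases <- strsplit(codon, "")[[1]]
  if (tm$strand == "-") bases <- vapply(bases, comp1, character(1))
  poke(seq, gpos, bases)
}

# partition cds_len bases into n_exons chunks of >= 6 each
partition_exons <- function(cds_len, n_exons) {
  cuts <- sort(sample(seq_len(cds_len - 1L)[-seq_len(5L)], n_exons - 1L))
  lens <- diff(c(0L, cuts, cds_len))
  while (any(lens < 6L)) {  # rare; resample
    cuts <- sort(sample(2:(cds_len - 2L), n_exons - 1L))
    lens <- diff(c(0L, cuts, cds_len))
  }
  lens
}

# lay out genes_per_contig non-overlapping multi-exon genes on each contig
layout_genes <- function(spec) {
  tms <- list()
  for (ci in seq_along(spec$contig_lengths)) {
    contig <- names(spec$contig_lengths)[ci]
    cursor <- 1001L
    for (gi in seq_len(spec$genes_per_contig)) {
      is_causal_gene <- (ci == 1L && gi == 1L)
      n_codons <- if (is_causal_gene)
        max(600L, spec$causal$residue + 47L) else sample(100:200, 1L)
      cds_len <- 3L * n_codons
      n_exons <- sample(2:4, 1L)
      exon_lens <- partition_exons(cds_len, n_exons)
      intron_lens <- sample(100:300, n_exons - 1L, replace = TRUE)
      starts <- integer(n_exons); ends <- integer(n_exons)
      p <- cursor
      for (e in seq_len(n_exons)) {
        starts[e] <- p; ends[e] <- p + exon_lens[e] - 1L
        p <- ends[e] + 1L + if (e < n_exons) intron_lens[e] else 0L
      }
      if (p - 1L > spec$contig_lengths[[ci]])
        stop(sprintf("contig %s too short: need at least %d bases", contig,
                     p - 1L))
      strand <- if (is_causal_gene) spec$causal$strand
                else if (gi == 2L) "-"
                else sample(c("+", "-"), 1L)
      gene <- if (is_causal_gene) spec$causal$gene
              else sprintf("GENE%s%02d", LETTERS[ci], gi)
      tx <- paste0("tx-", gene)
      tms[[tx]] <- transcript_model(tx, gene, contig, strand, starts, ends)
      cursor <- p + sample(2000:4000, 1L)
    }
  }
  tms
}

#' Generate a complete synthetic discovery fixture
#'
#' Emits, under `dir`: `reference.fa`, `genes.gff3`, `cohort.vcf`,
#' `samples.tsv`, `pedigree.ped`, `pedigree_genotypes.tsv`,
#' `protein_alignment.fa` and `truth.tsv`, all deterministic functions of
#' the spec (identical bytes for the same spec).  Planted case-exclusive
#' variants have the required zygosity in every case and allele count 0 in
#' every control; background variants are carried by at least one control;
#' singletons are private to one sample.  The causal missense variant is
#' realized by planting a `CGA` (Arg) codon at the causal residue and
#' substituting its middle base `G>A` (Gln).
#'
#' @param spec a `cohort_sim_spec`.
#' @param dir output directory (created if needed).
#' @return invisible list (`fixture_bundle`) with `paths` (named file
#'   paths), `truth` (the truth table), `transcripts`, `reference` (named
#'   character vector), `spec`, and the causal variant row.
#' @export
simulate_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)

  reference <- vapply(spec$contig_lengths, random_dna, character(1))
  names(reference) <- names(spec$contig_lengths)

  tms <- layout_genes(spec)

  # overlay start / stop codons, and the causal Arg codon
  for (tm in tms) {
    n_codons <- tm$cds_length %/% 3L
    reference[[tm$contig]] <- write_codon(reference[[tm$contig]], tm, 1L,
                                          "ATG")
    reference[[tm$contig]] <- write_codon(reference[[tm$contig]], tm,
                                          n_codons, "TAA")
    if (tm$gene == spec$causal$gene)
      reference[[tm$contig]] <-
        write_codon(reference[[tm$contig]], tm, spec$causal$residue, "CGA")
  }

  samples <- c(sprintf("case%d", seq_len(spec$n_cases)),
               sprintf("ctrl%02d", seq_len(spec$n_controls)))
  status <- c(rep("case", spec$n_cases), rep("control", spec$n_controls))
  sheet <- data.frame(
    sample = samples, status = status,
    breed = ifelse(status == "case", "Shetland_Sheepdog", "various"),
    family = ifelse(status == "case", "FAM1", NA_character_),
    stringsAsFactors = FALSE)

  used <- new.env(parent = emptyenv())
  mark_used <- function(contig, pos) {
    assign(paste0(contig, ":", pos), TRUE, envir = used)
  }
  is_used <- function(contig, pos) {
    exists(paste0(contig, ":", pos), envir = used)
  }

  # precompute geometry lookups
  cds_pos_by_tx <- lapply(tms, cds_genomic_positions)
  spans <- lapply(tms, transcript_span)
  in_any_span <- function(contig, pos) {
    for (tx in names(tms)) {
      if (tms[[tx]]$contig != contig) next
      if (pos >= spans[[tx]][1] && pos <= spans[[tx]][2]) return(TRUE)
    }
    FALSE
  }
  # codon context of a CDS position of one transcript
  codon_at <- function(tm, cds_pos) {
    residue <- (cds_pos - 1L) %/% 3L + 1L
    within <- (cds_pos - 1L) %% 3L + 1L
    gpos <- cds_pos_by_tx[[tm$tx_id]][(residue - 1L) * 3L + 1:3]
    bases <- vapply(gpos, function(p)
      substr(reference[[tm$contig]], p, p), character(1))
    if (tm$strand == "-") bases <- vapply(bases, comp1, character(1))
    list(residue = residue, within = within, gpos = gpos,
         codon = paste(bases, collapse = ""))
  }

  truth <- list()
  add_truth <- function(contig, pos, ref, alt, category, zygosity,
                        protein_changing, gene = NA_character_,
                        causal = FALSE) {
    truth[[length(truth) + 1L]] <<- data.frame(
      contig = contig, pos = pos, ref = ref, alt = alt,
      category = category, zygosity = zygosity,
      protein_changing = protein_changing, gene = gene, causal = causal,
      stringsAsFactors = FALSE)
    mark_used(contig, pos)
  }

  # --- causal variant -------------------------------------------------
  causal_tm <- tms[[paste0("tx-", spec$causal$gene)]]
  ctx <- codon_at(causal_tm, spec$causal$cds_pos)
  stopifnot(ctx$codon == "CGA", ctx$within == 2L)
  causal_gpos <- ctx$gpos[2L]
  g_ref <- substr(reference[[causal_tm$contig]], causal_gpos, causal_gpos)
  g_alt <- if (causal_tm$strand == "-") "T" else "A"  # CDS G>A
  add_truth(causal_tm$contig, causal_gpos, g_ref, g_alt, "het_shared",
            "het", TRUE, gene = spec$causal$gene, causal = TRUE)

  # --- planted coding protein-changing / synonymous sites --------------
  # draw a coding SNV of the requested kind (changing / synonymous)
  draw_coding <- function(changing) {
    repeat {
      tm <- tms[[sample(length(tms), 1L)]]
      n_codons <- tm$cds_length %/% 3L
      cds_pos <- sample(4:(tm$cds_length - 3L), 1L)  # spare start/stop codons
      ctx <- codon_at(tm, cds_pos)
      if (tm$gene == spec$causal$gene && ctx$residue == spec$causal$residue)
        next
      gpos <- ctx$gpos[ctx$within]
      if (is_used(tm$contig, gpos)) next
      ref_cds <- substr(ctx$codon, ctx$within, ctx$within)
      ref_aa <- translate_codon(ctx$codon)
      for (alt_cds in sample(setdiff(c("A", "C", "G", "T"), ref_cds))) {
        alt_codon <- ctx$codon
        substr(alt_codon, ctx$within, ctx$within) <- alt_cds
        alt_aa <- translate_codon(alt_codon)
        if ((alt_aa != ref_aa) == changing) {
          g_ref <- if (tm$strand == "-") comp1(ref_cds) else ref_cds
          g_alt <- if (tm$strand == "-") comp1(alt_cds) else alt_cds
          return(list(contig = tm$contig, pos = gpos, ref = g_ref,
                      alt = g_alt, gene = tm$gene))
        }
      }
    }
  }

  plant_category <- function(n_total, n_pc, zygosity, category) {
    n_syn <- min(10L, n_total - n_pc)
    n_intronic <- min(10L, n_total - n_pc - n_syn)
    n_intergenic <- n_total - n_pc - n_syn - n_intronic
    for (i in seq_len(n_pc)) {
      d <- draw_coding(changing = TRUE)
      add_truth(d$contig, d$pos, d$ref, d$alt, category, zygosity, TRUE,
                gene = d$gene)
    }
    for (i in seq_len(n_syn)) {
      d <- draw_coding(changing = FALSE)
      add_truth(d$contig, d$pos, d$ref, d$alt, category, zygosity, FALSE,
                gene = d$gene)
    }
    for (i in seq_len(n_intronic)) {
      repeat {
        tm <- tms[[sample(length(tms), 1L)]]
        sp <- spans[[tm$tx_id]]
        pos <- sample(sp[1]:sp[2], 1L)
        if (!is.na(genomic_to_cds(tm, pos)) || is_used(tm$contig, pos)) next
        ref <- substr(reference[[tm$contig]], pos, pos)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
        add_truth(tm$contig, pos, ref, alt, category, zygosity, FALSE,
                  gene = tm$gene)
        break
      }
    }
    for (i in seq_len(n_intergenic)) {
      repeat {
        contig <- sample(names(reference), 1L)
        pos <- sample(spec$contig_lengths[[contig]], 1L)
        if (in_any_span(contig, pos) || is_used(contig, pos)) next
        ref <- substr(reference[[contig]], pos, pos)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
        add_truth(contig, pos, ref, alt, category, zygosity, FALSE)
        break
      }
    }
  }

  # causal variant already accounts for one protein-changing het
  plant_category(spec$het_shared - 1L, spec$protein_changing_het - 1L,
                 "het", "het_shared")
  plant_category(spec$hom_shared, spec$protein_changing_hom,
                 "hom", "hom_shared")

  # --- background (carried by >= 1 control) and singletons --------------
  draw_anywhere <- function() {
    repeat {
      contig <- sample(names(reference), 1L)
      pos <- sample(spec$contig_lengths[[contig]], 1L)
      if (is_used(contig, pos)) next
      ref <- substr(reference[[contig]], pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      return(list(contig = contig, pos = pos, ref = ref, alt = alt))
    }
  }
  for (i in seq_len(spec$n_background)) {
    d <- draw_anywhere()
    add_truth(d$contig, d$pos, d$ref, d$alt, "background", "het", NA)
  }
  for (s in samples) {
    for (i in seq_len(spec$n_singletons_per_sample)) {
      d <- draw_anywhere()
      add_truth(d$contig, d$pos, d$ref, d$alt, paste0("singleton:", s),
                "het", NA)
    }
  }

  truth <- do.call(rbind, truth)

  # --- genotypes --------------------------------------------------------
  n_var <- nrow(truth)
  calls <- matrix(0L, n_var, length(samples),
                  dimnames = list(NULL, samples))
  is_case <- status == "case"
  for (i in seq_len(n_var)) {
    cat_i <- truth$category[i]
    if (cat_i %in% c("het_shared", "hom_shared")) {
      calls[i, is_case] <- if (truth$zygosity[i] == "het") 1L else 2L
    } else if (cat_i == "background") {
      repeat {
        carrier <- stats::runif(length(samples)) < 0.3
        gt <- ifelse(carrier, sample(1:2, length(samples), replace = TRUE,
                                     prob = c(0.9, 0.1)), 0L)
        if (any(gt[!is_case] > 0L)) break
      }
      calls[i, ] <- gt
    } else {  # singleton:<sample>
      s <- sub("^singleton:", "", cat_i)
      calls[i, s] <- 1L
    }
  }

  gm <- genotype_matrix(
    variant_table(truth$contig, truth$pos, truth$ref, truth$alt),
    samples, calls)

  # --- pedigree around the causal variant (dominant family) -------------
  ped <- data.frame(
    family = c("FAM1", "FAM1", "FAM1", "FAM1", "FAM1", "FAM1", "FAM2"),
    id = c("sire1", "dam1", "case1", "case2", "unaff1", "unknown1",
           "case_de"),
    sire = c(NA, NA, "sire1", "sire1", "sire1", "sire1", NA),
    dam = c(NA, NA, "dam1", "dam1", "dam1", "dam1", NA),
    sex = c("male", "female", "female", "female", "male", "male", "female"),
    phenotype = c("unaffected", "affected", "affected", "affected",
                  "unaffected", "unknown", "affected"),
    stringsAsFactors = FALSE)
  ped_gts <- c(sire1 = 0L, dam1 = 1L, case1 = 1L, case2 = 1L, unaff1 = 0L,
               case_de = 1L)

  # --- protein alignment around the causal residue ----------------------
  prot <- sub("\\*$", "", translate_cds(causal_tm, reference))
  msa <- simulate_msa(prot, spec$causal$residue, n_species = 9L,
                      conserved = TRUE)

  paths <- list(
    reference = file.path(dir, "reference.fa"),
    gff3 = file.path(dir, "genes.gff3"),
    vcf = file.path(dir, "cohort.vcf"),
    sample_sheet = file.path(dir, "samples.tsv"),
    pedigree = file.path(dir, "pedigree.ped"),
    pedigree_genotypes = file.path(dir, "pedigree_genotypes.tsv"),
    alignment = file.path(dir, "protein_alignment.fa"),
    truth = file.path(dir, "truth.tsv"))

  dna <- Biostrings::DNAStringSet(reference)
  Biostrings::writeXStringSet(dna, paths$reference, width = 70L)
  write_transcripts_gff3(tms, paths$gff3)
  suppressMessages(write_vcf(gm, paths$vcf,
                             contig_lengths = spec$contig_lengths))
  write_sample_sheet(sheet, paths$sample_sheet)
  write_pedigree(ped, paths$pedigree)
  utils::write.table(
    data.frame(id = names(ped_gts), alt_count = unname(ped_gts)),
    paths$pedigree_genotypes, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(as.vector(rbind(paste0(">", names(msa)), unname(msa))),
             paths$alignment)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(structure(
    list(paths = paths, truth = truth, transcripts = tms,
         reference = reference, sheet = sheet, pedigree = ped,
         pedigree_genotypes = ped_gts, spec = spec,
         causal = truth[truth$causal, , drop = FALSE]),
    class = "fixture_bundle"))
}

#' Translate the CDS of a transcript model against a reference
#'
#' @param tm a `transcript_model`.
#' @param reference named `DNAStringSet` or character vector.
#' @return single-letter protein string (stop codons as `*`).
#' @export
translate_cds <- function(tm, reference) {
  seq <- contig_string(reference, tm$contig)
  gpos <- cds_genomic_positions(tm)
  bases <- vapply(gpos, function(p) substr(seq, p, p), character(1))
  if (tm$strand == "-") bases <- vapply(bases, comp1, character(1))
  cds <- paste(bases, collapse = "")
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     if.fuzzy.codon = "X"))
}

#' Simulate a protein multiple alignment around a target residue
#'
#' The first row is the reference protein itself (ungapped).  Each other
#' species row is derived from it by random substitutions at a controlled
#' rate and an occasional short gap run, never touching the target column.
#' With `conserved = TRUE` the target column is identical in every row;
#' otherwise it is mutated in `n_mutated` rows.
#'
#' @param ref_protein single-letter reference protein string.
#' @param target_residue 1-based residue index of the column of interest.
#' @param n_species total number of rows (>= 2).
#' @param conserved keep the target column identical in all rows.
#' @param n_mutated rows whose target column is mutated when
#'   `conserved = FALSE`.
#' @param sub_rate per-column substitution probability in non-reference
#'   rows.
#' @param ref_id name of the reference row.
#' @return named character vector of aligned sequences (equal lengths).
#' @export
simulate_msa <- function(ref_protein, target_residue, n_species = 9L,
                         conserved = TRUE, n_mutated = 2L, sub_rate = 0.1,
                         ref_id = "dog") {
  stopifnot(n_species >= 2L, n_species <= 12L)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ref_chars <- strsplit(ref_protein, "")[[1]]
  L <- length(ref_chars)
  stopifnot(target_residue >= 1L, target_residue <= L)
  species <- c(ref_id, "human", "mouse", "rat", "cattle", "chicken",
               "xenopus", "zebrafish", "celegans", "drosophila",
               "danio2", "gallus2")[seq_len(n_species)]
  target_aa <- ref_chars[target_residue]
  rows <- list()
  rows[[ref_id]] <- ref_protein
  mutate_rows <- if (conserved) character(0)
                 else utils::tail(species, n_mutated)
  for (sp in species[-1]) {
    chars <- ref_chars
    swap <- stats::runif(L) < sub_rate
    swap[target_residue] <- FALSE
    chars[swap] <- vapply(which(swap), function(i)
      sample(setdiff(aas, ref_chars[i]), 1L), character(1))
    # one short gap run away from the target column, in half the rows
    if (stats::runif(1) < 0.5 && L > 30L) {
      repeat {
        g0 <- sample(L - 4L, 1L)
        if (g0 > target_residue + 2L || g0 + 3L < target_residue - 2L) break
      }
      chars[g0:(g0 + 3L)] <- "-"
    }
    if (sp %in% mutate_rows)
      chars[target_residue] <- sample(setdiff(aas, target_aa), 1L)
    rows[[sp]] <- paste(chars, collapse = "")
  }
  unlist(rows)
}

#' Simulate a genotyping cohort with a perfect association pattern
#'
#' Emulates a validation cohort in which every case is heterozygous for the
#' candidate allele and every control is homozygous reference: the breed
#' cohort and a multi-breed control panel.
#'
#' @param n_cases number of affected carriers (het).
#' @param n_breed_controls hom-ref controls of the affected breed.
#' @param n_other_controls hom-ref controls of other breeds.
#' @return list with `genotypes` (named integer vector) and `sheet`.
#' @export
simulate_genotyping_cohort <- function(n_cases = 4L, n_breed_controls = 117L,
                                       n_other_controls = 515L) {
  ids <- c(sprintf("case%d", seq_len(n_cases)),
           sprintf("shet%03d", seq_len(n_breed_controls)),
           sprintf("othr%03d", seq_len(n_other_controls)))
  status <- c(rep("case", n_cases),
              rep("control", n_breed_controls + n_other_controls))
  breed <- c(rep("Shetland_Sheepdog", n_cases + n_breed_controls),
             rep("other", n_other_controls))
  genotypes <- stats::setNames(
    c(rep(1L, n_cases), rep(0L, n_breed_controls + n_other_controls)), ids)
  list(genotypes = genotypes,
       sheet = data.frame(sample = ids, status = status, breed = breed,
                          family = NA_character_, stringsAsFactors = FALSE))
}
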