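#' Run the full discovery pipeline
#'
#' Orchestrates every stage of the case-exclusive discovery analysis and
#' writes a report directory:
#' \itemize{
#'   \item `filter_summary.tsv` — case-exclusive counts per zygosity model
#'     and their protein-changing subsets;
#'   \item `candidates.tsv` — ranked protein-changing candidates with HGVS
#'     names and conservation of the causal-gene residue where available;
#'   \item `association.tsv` — genotype-by-phenotype counts for the
#'     genotyping cohort;
#'   \item `segregation.tsv` — verdict and any violations of the dominant
#'     model in the pedigree;
#'   \item `run_log.txt` — every decision policy in force plus per-stage
#'     counts.
#' }
#'
#' @param config list (or path to a YAML file) with entries:
#'   `vcf`, `sample_sheet`, `reference`, `gff3` (input paths; alternatively
#'   `fixture_dir` + `sim` to generate a fixture first), optional
#'   `pedigree` + `pedigree_genotypes`, optional `alignment` +
#'   `conservation_residue` + `conservation_ref_id`, `out_dir`,
#'   `missing_control` (`"ref"`/`"drop"`), `weights`, `gene_list`.
#' @return invisible list with the in-memory results (`summary`,
#'   `effects`, `candidates`, `association`, `segregation`, paths).
#' @export
run_discovery <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config must name an out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log_add <- function(...) log_lines <<- c(log_lines, sprintf(...))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  if (!is.null(config$sim)) {
    fx <- stage("simulate", {
      spec <- if (is.character(config$sim)) read_sim_spec(config$sim)
              else do.call(cohort_sim_spec, config$sim)
      simulate_fixture(spec, config$fixture_dir %||% file.path(out_dir,
                                                               "fixture"))
    })
    config$vcf <- fx$paths$vcf
    config$sample_sheet <- fx$paths$sample_sheet
    config$reference <- fx$paths$reference
    config$gff3 <- fx$paths$gff3
    config$pedigree <- fx$paths$pedigree
    config$pedigree_genotypes <- fx$paths$pedigree_genotypes
    config$alignment <- fx$paths$alignment
    config$conservation_residue <- fx$spec$causal$residue
    config$conservation_ref_id <- "dog"
    log_add("simulate: fixture written under %s (seed %d)",
            dirname(fx$paths$vcf), fx$spec$seed)
  }

  missing_control <- config$missing_control %||% "ref"
  log_add("policy: missing_control=%s", missing_control)
  log_add("policy: protein-changing classes = %s",
          "missense, nonsense, stop_loss, start_loss")

  sheet <- stage("read_sample_sheet", read_sample_sheet(config$sample_sheet))
  if (!any(sheet$status == "case"))
    stop("stage 'read_sample_sheet' failed: no case samples in sheet")
  vcf <- stage("read_vcf", read_vcf(config$vcf, sheet))
  gm <- vcf$matrix
  log_add("read_vcf: %d variants x %d samples (%d cases, %d controls)",
          nrow(gm$variants), length(gm$samples),
          sum(sheet$status == "case"), sum(sheet$status == "control"))

  reference <- stage("read_reference", {
    r <- Biostrings::readDNAStringSet(config$reference)
    names(r) <- sub("\\s.*$", "", names(r))
    stats::setNames(as.character(r), names(r))
  })
  gm <- stage("normalize", normalize_matrix(gm, reference))
  tms <- stage("read_transcripts", read_transcripts_gff3(config$gff3))
  log_add("read_transcripts: %d transcript model(s)", length(tms))

  effects <- stage("annotate", annotate_matrix(gm, tms, reference))
  fs <- stage("filter", suppressMessages(
    summarize_filter(gm, sheet, effects$effect_class, missing_control)))
  log_add("filter: het-shared %d, hom-shared %d, total %d",
          fs$n_het_shared, fs$n_hom_shared, fs$n_case_exclusive_total)
  log_add("filter: protein-changing het %d, hom %d",
          fs$n_protein_changing_het, fs$n_protein_changing_hom)
  write_filter_summary(fs, file.path(out_dir, "filter_summary.tsv"))

  # conservation of the designated residue, if an alignment is supplied
  cons <- NULL
  if (!is.null(config$alignment)) {
    cons <- stage("conserve", {
      aln <- read_alignment(config$alignment)
      column_conservation(aln, config$conservation_ref_id %||% names(aln)[1],
                          config$conservation_residue)
    })
    write_conservation(cons, file.path(out_dir, "conservation.tsv"))
    log_add("conserve: column %d fraction_identical %.3f (n=%d)",
            cons$column, cons$fraction_identical, cons$n_nongap)
  }

  # candidate table: protein-changing survivors of either model
  surv <- c(fs$idx_het, fs$idx_hom)
  pc <- surv[is_protein_changing(effects$effect_class[surv])]
  candidates <- NULL
  if (length(pc)) {
    rows <- cbind(gm$variants[pc, c("contig", "pos", "ref", "alt")],
                  effects[pc, c("gene", "effect_class", "c_hgvs", "p_hgvs",
                                "residue_index")])
    rows$conservation <- NA_real_
    if (!is.null(cons) && !is.null(config$sim))
      rows$conservation[rows$gene == fx$spec$causal$gene &
                          rows$residue_index == fx$spec$causal$residue] <-
        cons$fraction_identical
    candidates <- rank_candidates(
      rows,
      weights = config$weights %||% c(severity = 1, conservation = 0,
                                      prior = 0),
      gene_list = config$gene_list %||% character(0))
    utils::write.table(candidates, file.path(out_dir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_add("rank: %d protein-changing candidate(s); top = %s %s",
            nrow(candidates), candidates$gene[1], candidates$p_hgvs[1])
  } else log_add("rank: no protein-changing candidates")

  # association on the genotyping cohort (fixture mode: perfect pattern)
  assoc <- NULL
  if (!is.null(config$sim)) {
    cohort <- simulate_genotyping_cohort()
    assoc <- stage("associate",
                   association_table(cohort$genotypes, cohort$sheet))
    utils::write.table(cbind(genotype = rownames(assoc),
                             as.data.frame(unclass(assoc))),
                       file.path(out_dir, "association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_add("associate: perfect association = %s",
            is_perfectly_associated(assoc))
  }

  seg <- NULL
  if (!is.null(config$pedigree)) {
    seg <- stage("segregate", {
      ped <- read_pedigree(config$pedigree)
      g <- utils::read.table(config$pedigree_genotypes, header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
      check_dominant_segregation(ped,
                                 stats::setNames(as.integer(g$alt_count),
                                                 g$id))
    })
    utils::write.table(
      data.frame(consistent = seg$consistent,
                 n_violations = nrow(seg$violations)),
      file.path(out_dir, "segregation.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    log_add("segregate: consistent with dominant model = %s",
            seg$consistent)
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(summary = fs, effects = effects, candidates = candidates,
                 association = assoc, segregation = seg, cons = cons,
                 out_dir = out_dir, log = log_lines))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
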