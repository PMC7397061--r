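# Independent oracles, deliberately written as naive per-element scans so
# they share no code path with the implementation they check.

# line-by-line VCF text parser (no vcfR): returns variant table + calls
oracle_parse_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  samples <- header[-(1:9)]
  vars <- list(); calls <- list()
  for (ln in body[-1]) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    keys <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_i <- which(keys == "GT")
    for (k in seq_along(alts)) {
      row_calls <- integer(0)
      for (j in seq_along(samples)) {
        gt <- strsplit(f[9 + j], ":", fixed = TRUE)[[1]][gt_i]
        al <- strsplit(gt, "[/|]")[[1]]
        if (any(al == ".")) row_calls[j] <- NA_integer_
        else row_calls[j] <- sum(as.integer(al) == k)
      }
      vars[[length(vars) + 1L]] <- data.frame(
        contig = f[1], pos = as.integer(f[2]), ref = f[4], alt = alts[k],
        stringsAsFactors = FALSE)
      calls[[length(calls) + 1L]] <- row_calls
    }
  }
  list(variants = do.call(rbind, vars),
       calls = do.call(rbind, calls))
}

# brute-force leftmost-minimal representation of a substitution/indel:
# enumerate candidate (pos', ref', alt') that reproduce the same mutant
# haplotype; pick minimal total allele length, then smallest position
oracle_normalize <- function(contig, pos, ref, alt, reference) {
  R <- if (is.character(reference)) reference[[contig]]
       else as.character(reference[[contig]])
  M <- paste0(substr(R, 1, pos - 1), alt,
              substr(R, pos + nchar(ref), nchar(R)))
  d <- nchar(M) - nchar(R)
  best <- NULL
  lo <- max(1L, pos - 40L); hi <- min(nchar(R), pos + 40L)
  for (p in lo:hi) {
    if (substr(R, 1, p - 1) != substr(M, 1, p - 1)) next
    for (lr in 1:15) {
      la <- lr + d
      if (la < 1L || p + lr - 1L > nchar(R)) next
      rp <- substr(R, p, p + lr - 1L)
      ap <- substr(M, p, p + la - 1L)
      if (rp == ap) next
      if (substr(R, p + lr, nchar(R)) != substr(M, p + la, nchar(M))) next
      cand <- list(pos = p, ref = rp, alt = ap, size = lr + la)
      if (is.null(best) || cand$size < best$size ||
          (cand$size == best$size && cand$pos < best$pos)) best <- cand
    }
  }
  best[c("pos", "ref", "alt")]
}

# exhaustive per-variant scan for the case-exclusive filter
oracle_case_exclusive <- function(gm, sheet, model, missing_control = "ref") {
  need <- if (model == "DOMINANT_HET") 1L else 2L
  cases <- sheet$sample[sheet$status == "case"]
  controls <- sheet$sample[sheet$status == "control"]
  keep <- integer(0)
  for (i in seq_len(nrow(gm$variants))) {
    ok <- TRUE
    for (s in cases) {
      g <- gm$calls[i, s]
      if (is.na(g) || g != need) { ok <- FALSE; break }
    }
    if (ok) for (s in controls) {
      g <- gm$calls[i, s]
      if (is.na(g)) {
        if (missing_control == "drop") { ok <- FALSE; break }
      } else if (g > 0L) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, i)
  }
  keep
}

# whole-CDS translate-and-diff consequence oracle
oracle_annotate <- function(tm, reference, contig, pos, ref, alt) {
  seq <- if (is.character(reference)) reference[[contig]]
         else as.character(reference[[contig]])
  gpos <- integer(0)
  ord <- seq_along(tm$cds_starts)
  for (i in ord) {
    p <- tm$cds_starts[i]:tm$cds_ends[i]
    if (tm$strand == "-") p <- rev(p)
    gpos <- c(gpos, p)
  }
  idx <- which(gpos == pos)
  if (length(idx) == 0L) {
    span <- range(c(tm$cds_starts, tm$cds_ends))
    cls <- if (contig == tm$contig && pos >= span[1] && pos <= span[2])
      "intronic" else "intergenic"
    return(list(effect_class = cls))
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  base_at <- function(p) substr(seq, p, p)
  cds <- vapply(gpos, base_at, character(1))
  if (tm$strand == "-") cds <- comp[cds]
  mut <- cds
  mut[idx] <- if (tm$strand == "-") comp[[alt]] else alt
  tr <- function(x) as.character(Biostrings::translate(
    Biostrings::DNAString(paste(x, collapse = ""))))
  p_ref <- strsplit(tr(cds), "")[[1]]
  p_alt <- strsplit(tr(mut), "")[[1]]
  diffs <- which(p_ref != p_alt)
  if (length(diffs) == 0L)
    return(list(effect_class = "synonymous",
                residue_index = (idx - 1L) %/% 3L + 1L))
  stopifnot(length(diffs) == 1L)
  r <- diffs[1]
  cls <- if (r == 1L && p_ref[1] == "M") "start_loss"
         else if (p_alt[r] == "*") "nonsense"
         else if (p_ref[r] == "*") "stop_loss"
         else "missense"
  list(effect_class = cls, residue_index = r,
       ref_aa = p_ref[r], alt_aa = p_alt[r])
}

# exhaustive dominant-model rule table for one individual in a trio
oracle_trio_violations <- function(gt, phe, sire_gt, dam_gt) {
  rules <- character(0)
  if (!is.na(gt)) {
    if (phe == "affected" && gt == 0L)
      rules <- c(rules, "affected_without_alt_allele")
    if (phe == "unaffected" && gt > 0L)
      rules <- c(rules, "unaffected_carrier")
    from <- function(g) if (is.na(g)) list(0L, 1L)
                        else if (g == 0L) list(0L)
                        else if (g == 1L) list(0L, 1L) else list(1L)
    achievable <- FALSE
    for (a in from(sire_gt)) for (b in from(dam_gt))
      if (a + b == gt) achievable <- TRUE
    if (!achievable)
      rules <- c(rules, "mendelian_impossible_given_parents")
  }
  rules
}

# naive genotype x phenotype tally
oracle_association <- function(genotypes, sheet) {
  tab <- matrix(0L, 3, 2, dimnames = list(c("hom_ref", "het", "hom_alt"),
                                          c("case", "control")))
  for (s in names(genotypes)) {
    g <- genotypes[[s]]
    if (is.na(g)) next
    st <- sheet$status[sheet$sample == s]
    if (st == "unknown") next
    tab[g + 1L, st] <- tab[g + 1L, st] + 1L
  }
  tab
}
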