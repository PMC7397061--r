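#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}), splits multiallelic records into
#' biallelic ones, and decodes diploid GT fields into alternate allele counts
#' (0, 1, 2; missing calls become `NA`).  Phased separators are treated as
#' unphased.  Haploid or higher-ploidy genotypes are rejected: the target
#' analysis is autosomal diploid.
#'
#' @param path path to a VCF file.
#' @param sample_sheet optional sample sheet `data.frame` (see
#'   [read_sample_sheet()]).  When given, its samples must all be present in
#'   the VCF and the returned matrix is restricted to them, in sheet order.
#' @param pass_only if `TRUE`, keep only records whose FILTER column is
#'   `PASS` or `.`.  Default `FALSE`: site-level filters are ignored.
#' @return a list with elements `matrix` (a `genotype_matrix`) and `sheet`
#'   (the sample sheet, or a minimal all-`unknown` sheet when none given).
#' @export
read_vcf <- function(path, sample_sheet = NULL, pass_only = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt
  samples <- colnames(gt)[-1]
  if (!is.null(sample_sheet)) {
    sample_sheet <- validate_sample_sheet(sample_sheet)
    absent <- setdiff(sample_sheet$sample, samples)
    if (length(absent))
      stop("sample sheet sample(s) absent from VCF: ",
           paste(absent, collapse = ", "))
  } else {
    sample_sheet <- data.frame(sample = samples, status = "unknown",
                               breed = NA_character_, family = NA_character_,
                               stringsAsFactors = FALSE)
  }

  n <- nrow(fix)
  if (is.null(n) || n == 0L) {
    gm <- genotype_matrix(empty_variant_table(), sample_sheet$sample,
                          matrix(integer(0), 0, nrow(sample_sheet)))
    return(list(matrix = gm, sheet = sample_sheet))
  }

  if (pass_only) {
    keep <- is.na(fix[, "FILTER"]) | fix[, "FILTER"] %in% c("PASS", ".")
    fix <- fix[keep, , drop = FALSE]
    gt <- gt[keep, , drop = FALSE]
    n <- nrow(fix)
  }

  out_var <- vector("list", n)
  out_calls <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- split_vcf_record(
      contig = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
      vid = fix[i, "ID"], ref = fix[i, "REF"], alt = fix[i, "ALT"],
      format = gt[i, 1], sample_fields = gt[i, -1, drop = TRUE],
      samples = samples
    )
    out_var[[i]] <- rec$variants
    out_calls[[i]] <- rec$calls
  }
  variants <- do.call(rbind, out_var)
  rownames(variants) <- NULL
  calls <- do.call(rbind, out_calls)
  colnames(calls) <- samples
  gm <- genotype_matrix(variants, samples, calls)
  # restrict and reorder to sheet samples
  gm <- genotype_matrix(gm$variants, sample_sheet$sample,
                        gm$calls[, sample_sheet$sample, drop = FALSE])
  list(matrix = gm, sheet = sample_sheet)
}

empty_variant_table <- function() {
  data.frame(contig = character(0), pos = integer(0), ref = character(0),
             alt = character(0), vid = character(0), stringsAsFactors = FALSE)
}

# Decode one VCF record into one-or-more biallelic rows plus a call matrix.
split_vcf_record <- function(contig, pos, vid, ref, alt, format,
                             sample_fields, samples) {
  alts <- strsplit(alt, ",", fixed = TRUE)[[1]]
  keys <- if (is.na(format)) character(0)
          else strsplit(format, ":", fixed = TRUE)[[1]]
  gt_idx <- match("GT", keys)
  if (is.na(gt_idx))
    stop(sprintf("record %s:%d has no GT key in FORMAT", contig, pos))
  allele_counts <- vapply(seq_along(samples), function(j) {
    f <- sample_fields[[j]]
    if (is.na(f)) return(rep(NA_integer_, length(alts)))
    gt_str <- strsplit(f, ":", fixed = TRUE)[[1]][gt_idx]
    decode_gt(gt_str, length(alts), contig, pos)
  }, integer(length(alts)))
  if (length(alts) == 1L) allele_counts <- matrix(allele_counts, nrow = 1L)
  variants <- data.frame(contig = unname(contig), pos = unname(pos),
                         ref = toupper(unname(ref)), alt = toupper(alts),
                         vid = if (is.na(vid)) NA_character_ else unname(vid),
                         stringsAsFactors = FALSE)
  list(variants = variants, calls = allele_counts)
}

# GT string -> per-ALT-allele counts (length n_alt); NA for missing.
decode_gt <- function(gt_str, n_alt, contig, pos) {
  if (is.na(gt_str) || gt_str %in% c(".", "./.", ".|."))
    return(rep(NA_integer_, n_alt))
  alleles <- strsplit(gt_str, "[/|]")[[1]]
  if (length(alleles) != 2L)
    stop(sprintf("non-diploid genotype '%s' at %s:%d", gt_str, contig, pos))
  if (any(alleles == ".")) return(rep(NA_integer_, n_alt))
  ai <- suppressWarnings(as.integer(alleles))
  if (anyNA(ai) || any(ai < 0L) || any(ai > n_alt))
    stop(sprintf("invalid genotype '%s' at %s:%d", gt_str, contig, pos))
  vapply(seq_len(n_alt), function(k) sum(ai == k), integer(1))
}

#' Split a multiallelic record into biallelic variant rows
#'
#' For each ALT allele a separate record is produced whose per-sample call
#' counts only that allele; other ALT alleles at the same sample count as 0
#' for that record.  Biallelic records pass through unchanged.
#'
#' @param contig,pos,ref single contig / position / REF allele.
#' @param alts character vector of ALT alleles (length k >= 1).
#' @param gt_strings character vector of diploid GT strings, one per sample.
#' @return list with `variants` (k-row variant table) and `calls`
#'   (k x n_samples integer matrix).
#' @export
split_multiallelic <- function(contig, pos, ref, alts, gt_strings) {
  calls <- vapply(gt_strings, function(g)
    decode_gt(g, length(alts), contig, pos), integer(length(alts)))
  if (length(alts) == 1L) calls <- matrix(calls, nrow = 1L)
  list(
    variants = data.frame(contig = contig, pos = as.integer(pos),
                          ref = toupper(ref), alt = toupper(alts),
                          vid = NA_character_, stringsAsFactors = FALSE),
    calls = unname(calls)
  )
}

#' Write a genotype matrix as a VCF 4.2 file
#'
#' Emits a GT-only FORMAT.  Records are sorted by `(contig, pos)`; when the
#' input order differs a notice is emitted via `message()`.
#'
#' @param gm a `genotype_matrix`.
#' @param path output path.
#' @param contig_lengths optional named integer vector used for `##contig`
#'   header lines.
#' @return the path, invisibly.
#' @export
write_vcf <- function(gm, path, contig_lengths = NULL) {
  v <- gm$variants
  ord <- order(v$contig, v$pos, v$ref, v$alt)
  if (nrow(v) > 0L && !identical(ord, seq_len(nrow(v)))) {
    message("write_vcf: records were not coordinate-sorted; sorting on write")
    v <- v[ord, , drop = FALSE]
    gm <- genotype_matrix(v, gm$samples, gm$calls[ord, , drop = FALSE])
  }
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=casevar_%s",
                   as.character(utils::packageVersion("casevar"))))
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  hdr <- c(hdr,
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples), collapse = "\t"))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- character(0)
  if (nrow(v) > 0L) {
    gts <- matrix("./.", nrow(v), length(gm$samples))
    ok <- !is.na(gm$calls)
    gts[ok] <- gt_code[as.character(gm$calls[ok])]
    body <- vapply(seq_len(nrow(v)), function(i) {
      paste(c(v$contig[i], v$pos[i],
              if (is.na(v$vid[i])) "." else v$vid[i],
              v$ref[i], v$alt[i], ".", ".", ".", "GT", gts[i, ]),
            collapse = "\t")
    }, character(1))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
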