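#' Effect classes recognized by the annotator
#'
#' @format character vector of the class vocabulary.
#' @export
EFFECT_CLASSES <- c("synonymous", "missense", "nonsense", "stop_loss",
                    "start_loss", "intronic", "utr_or_noncoding",
                    "intergenic")

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Ter")

#' Three-letter amino-acid code
#' @param aa one-letter amino-acid codes (`*` for a stop).
#' @return three-letter codes (`Ter` for a stop).
#' @export
aa_three_letter <- function(aa) unname(AA3[aa])

translate_codon <- function(codon) {
  Biostrings::GENETIC_CODE[[codon]]
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
comp1 <- function(b) c(A = "T", C = "G", G = "C", T = "A", N = "N")[[b]]

#' Is an effect class protein-changing?
#'
#' The protein-changing set is `missense`, `nonsense`, `stop_loss`,
#' `start_loss`; everything else (synonymous and non-coding classes) is not.
#'
#' @param effect_class character vector of effect classes.
#' @return logical vector.
#' @export
is_protein_changing <- function(effect_class) {
  effect_class %in% c("missense", "nonsense", "stop_loss", "start_loss")
}

#' Annotate a single-nucleotide variant against a transcript model
#'
#' Maps the genomic position into the CDS, assembles the affected codon
#' (across CDS interval boundaries where needed, complementing alleles on
#' the minus strand), substitutes the alternate base and classifies the
#' amino-acid change.  HGVS-style names are produced on both levels:
#' `c.<pos><REF>><ALT>` with CDS-strand alleles and `p.(Xxx<idx>Yyy)`
#' (`p.Xxx<idx>Yyy` with `parenthesized = FALSE`; a stop gain is written
#' with `*`).
#'
#' Variants outside the CDS are classified `intronic` when they fall between
#' CDS intervals of the transcript and `intergenic` otherwise; such results
#' carry `NA` codon fields.
#'
#' @param tm a `transcript_model`.
#' @param reference named `DNAStringSet` or character vector of contigs.
#' @param contig,pos,ref,alt the SNV (single-base `ref` and `alt`).
#' @param parenthesized emit the predicted-form `p.(...)` spelling
#'   (default) or the bare `p....` spelling.
#' @return a list of class `coding_effect` with fields `effect_class`,
#'   `cds_pos`, `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`,
#'   `residue_index`, `c_hgvs`, `p_hgvs`, `gene`, `tx_id`.
#' @export
annotate_snv <- function(tm, reference, contig, pos, ref, alt,
                         parenthesized = TRUE) {
  ref <- toupper(ref); alt <- toupper(alt); pos <- as.integer(pos)
  if (nchar(ref) != 1L || nchar(alt) != 1L)
    stop("annotate_snv handles single-nucleotide variants only")
  if (ref == alt) stop("ref and alt alleles must differ")
  non_coding <- function(cls) {
    structure(list(effect_class = cls, cds_pos = NA_integer_,
                   ref_codon = NA_character_, alt_codon = NA_character_,
                   ref_aa = NA_character_, alt_aa = NA_character_,
                   residue_index = NA_integer_, c_hgvs = NA_character_,
                   p_hgvs = NA_character_, gene = tm$gene, tx_id = tm$tx_id),
              class = "coding_effect")
  }
  if (contig != tm$contig) return(non_coding("intergenic"))
  seq <- contig_string(reference, contig)
  obs <- substr(seq, pos, pos)
  if (obs != ref)
    stop(sprintf("reference base '%s' != variant REF '%s' at %s:%d",
                 obs, ref, contig, pos))
  cds_pos <- genomic_to_cds(tm, pos)
  if (is.na(cds_pos)) {
    span <- transcript_span(tm)
    cls <- if (pos >= span[1] && pos <= span[2]) "intronic" else "intergenic"
    return(non_coding(cls))
  }
  residue <- (cds_pos - 1L) %/% 3L + 1L
  within <- (cds_pos - 1L) %% 3L + 1L
  codon_cds <- (residue - 1L) * 3L + 1:3
  gpos <- cds_genomic_positions(tm)[codon_cds]
  bases <- vapply(gpos, function(p) substr(seq, p, p), character(1))
  if (tm$strand == "-") bases <- vapply(bases, comp1, character(1))
  ref_codon <- paste(bases, collapse = "")
  cds_ref <- if (tm$strand == "-") comp1(ref) else ref
  cds_alt <- if (tm$strand == "-") comp1(alt) else alt
  stopifnot(substr(ref_codon, within, within) == cds_ref)
  alt_bases <- bases
  alt_bases[within] <- cds_alt
  alt_codon <- paste(alt_bases, collapse = "")
  ref_aa1 <- translate_codon(ref_codon)
  alt_aa1 <- translate_codon(alt_codon)
  cls <- if (ref_aa1 == alt_aa1) "synonymous"
         else if (residue == 1L && ref_aa1 == "M") "start_loss"
         else if (alt_aa1 == "*") "nonsense"
         else if (ref_aa1 == "*") "stop_loss"
         else "missense"
  p_core <- sprintf("%s%d%s", aa_three_letter(ref_aa1), residue,
                    if (alt_aa1 == "*") "*" else aa_three_letter(alt_aa1))
  structure(list(
    effect_class = cls,
    cds_pos = cds_pos,
    ref_codon = ref_codon, alt_codon = alt_codon,
    ref_aa = aa_three_letter(ref_aa1), alt_aa = aa_three_letter(alt_aa1),
    residue_index = residue,
    c_hgvs = sprintf("c.%d%s>%s", cds_pos, cds_ref, cds_alt),
    p_hgvs = if (parenthesized) sprintf("p.(%s)", p_core)
             else sprintf("p.%s", p_core),
    gene = tm$gene, tx_id = tm$tx_id
  ), class = "coding_effect")
}

#' @export
print.coding_effect <- function(x, ...) {
  if (is.na(x$cds_pos)) {
    cat(sprintf("%s (%s/%s)\n", x$effect_class, x$gene, x$tx_id))
  } else {
    cat(sprintf("%s %s %s %s [%s, codon %s>%s]\n", x$gene, x$c_hgvs,
                x$p_hgvs, x$effect_class, x$tx_id, x$ref_codon, x$alt_codon))
  }
  invisible(x)
}

#' Annotate an SNV against a set of transcript models
#'
#' Each transcript overlapping the variant is annotated; the effect with
#' the most severe class is returned (severity order: start/stop
#' loss = nonsense > missense > synonymous > intronic > other).  With no
#' overlapping transcript an `intergenic` effect is returned.
#'
#' @param tms list of `transcript_model` objects.
#' @param reference named `DNAStringSet` or character vector.
#' @param contig,pos,ref,alt the SNV.
#' @param parenthesized HGVS p. spelling flag, see [annotate_snv()].
#' @return a `coding_effect`.
#' @export
annotate_snv_multi <- function(tms, reference, contig, pos, ref, alt,
                               parenthesized = TRUE) {
  sev <- c(nonsense = 5, start_loss = 5, stop_loss = 5, missense = 4,
           synonymous = 3, intronic = 2, utr_or_noncoding = 1,
           intergenic = 0)
  best <- NULL
  for (tm in tms) {
    if (tm$contig != contig) next
    span <- transcript_span(tm)
    if (pos < span[1] || pos > span[2]) next
    eff <- annotate_snv(tm, reference, contig, pos, ref, alt, parenthesized)
    if (is.null(best) || sev[[eff$effect_class]] > sev[[best$effect_class]])
      best <- eff
  }
  if (is.null(best))
    best <- structure(list(effect_class = "intergenic", cds_pos = NA_integer_,
                           ref_codon = NA_character_, alt_codon = NA_character_,
                           ref_aa = NA_character_, alt_aa = NA_character_,
                           residue_index = NA_integer_, c_hgvs = NA_character_,
                           p_hgvs = NA_character_, gene = NA_character_,
                           tx_id = NA_character_),
                      class = "coding_effect")
  best
}

#' Annotate every variant row of a genotype matrix
#'
#' @param gm a `genotype_matrix` of normalized biallelic variants; rows that
#'   are not SNVs are classified `NA`.
#' @param tms list of `transcript_model` objects.
#' @param reference named `DNAStringSet` or character vector.
#' @return a `data.frame` parallel to the variant rows with columns
#'   `effect_class`, `gene`, `cds_pos`, `residue_index`, `c_hgvs`, `p_hgvs`.
#' @export
annotate_matrix <- function(gm, tms, reference) {
  if (inherits(reference, "DNAStringSet"))
    reference <- stats::setNames(as.character(reference), names(reference))
  v <- gm$variants
  n <- nrow(v)
  out <- data.frame(effect_class = rep(NA_character_, n),
                    gene = NA_character_, cds_pos = NA_integer_,
                    residue_index = NA_integer_, c_hgvs = NA_character_,
                    p_hgvs = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (nchar(v$ref[i]) != 1L || nchar(v$alt[i]) != 1L) next
    eff <- annotate_snv_multi(tms, reference, v$contig[i], v$pos[i],
                              v$ref[i], v$alt[i])
    out$effect_class[i] <- eff$effect_class
    out$gene[i] <- eff$gene
    out$cds_pos[i] <- eff$cds_pos
    out$residue_index[i] <- eff$residue_index
    out$c_hgvs[i] <- eff$c_hgvs
    out$p_hgvs[i] <- eff$p_hgvs
  }
  out
}
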