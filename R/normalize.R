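#' Normalize a variant to its left-aligned minimal representation
#'
#' Implements the standard normalization used before any cross-cohort variant
#' comparison: shared trailing bases are trimmed (extending to the left from
#' the reference where an allele would become empty, which left-aligns
#' indels), then shared leading bases are trimmed keeping at least one base
#' in each allele.  SNVs already in minimal form pass through unchanged.
#' The procedure is idempotent.
#'
#' @param contig,pos,ref,alt the variant to normalize (1-based `pos`).
#' @param reference a named `Biostrings::DNAStringSet` (or named character
#'   vector) of contig sequences covering the variant span.
#' @return list with fields `contig`, `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(contig, pos, ref, alt, reference) {
  ref <- toupper(ref); alt <- toupper(alt)
  pos <- as.integer(pos)
  seq <- contig_string(reference, contig)
  if (pos + nchar(ref) - 1L > nchar(seq))
    stop("variant span exceeds reference contig length")
  obs <- substr(seq, pos, pos + nchar(ref) - 1L)
  if (obs != ref)
    stop(sprintf("REF allele '%s' disagrees with reference sequence '%s' at %s:%d",
                 ref, obs, contig, pos))
  if (ref == alt) stop("ref and alt alleles must differ")
  repeat {
    lr <- nchar(ref); la <- nchar(alt)
    # trim shared trailing base; left-extend when one allele would empty
    if (lr > 0L && la > 0L &&
        substr(ref, lr, lr) == substr(alt, la, la)) {
      if (lr == 1L || la == 1L) {
        if (pos == 1L) break
        pos <- pos - 1L
        b <- substr(seq, pos, pos)
        ref <- paste0(b, substr(ref, 1L, lr - 1L))
        alt <- paste0(b, substr(alt, 1L, la - 1L))
      } else {
        ref <- substr(ref, 1L, lr - 1L)
        alt <- substr(alt, 1L, la - 1L)
      }
    } else break
  }
  # trim shared leading bases, keeping >= 1 base each
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(contig = contig, pos = pos, ref = ref, alt = alt)
}

#' Normalize every variant row of a genotype matrix
#'
#' @param gm a `genotype_matrix`.
#' @param reference named `DNAStringSet` or character vector of contigs.
#' @return the matrix with normalized variant rows (calls untouched).
#' @export
normalize_matrix <- function(gm, reference) {
  v <- gm$variants
  for (i in seq_len(nrow(v))) {
    n <- normalize_variant(v$contig[i], v$pos[i], v$ref[i], v$alt[i],
                           reference)
    v$pos[i] <- n$pos; v$ref[i] <- n$ref; v$alt[i] <- n$alt
  }
  genotype_matrix(v, gm$samples, gm$calls)
}

# Fetch a contig as a plain character string from a DNAStringSet or a named
# character vector.
contig_string <- function(reference, contig) {
  if (inherits(reference, "DNAStringSet")) {
    if (!contig %in% names(reference))
      stop("contig not in reference: ", contig)
    return(as.character(reference[[contig]]))
  }
  if (is.character(reference)) {
    if (!contig %in% names(reference))
      stop("contig not in reference: ", contig)
    return(toupper(reference[[contig]]))
  }
  stop("reference must be a named DNAStringSet or character vector")
}
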