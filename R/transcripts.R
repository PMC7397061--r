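#' Construct a transcript model
#'
#' A transcript model holds the CDS geometry needed for coding-consequence
#' annotation: ordered CDS intervals (1-based inclusive, given in
#' transcription order), the strand, and the gene symbol.  The concatenated
#' CDS must translate cleanly, so its total length must be divisible by 3.
#'
#' @param tx_id transcript identifier.
#' @param gene gene symbol.
#' @param contig contig identifier.
#' @param strand `"+"` or `"-"`.
#' @param cds_starts,cds_ends integer vectors of interval bounds (1-based
#'   inclusive, genomic coordinates).  Order is normalized internally to
#'   transcription order (ascending for `+`, descending for `-`).
#' @param codon_table NCBI genetic code id; only the standard code (1) is
#'   supported.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(tx_id, gene, contig, strand, cds_starts,
                             cds_ends, codon_table = 1L) {
  stopifnot(strand %in% c("+", "-"), length(cds_starts) == length(cds_ends),
            length(cds_starts) >= 1L)
  if (codon_table != 1L)
    stop("only the standard codon table (id 1) is supported")
  cds_starts <- as.integer(cds_starts); cds_ends <- as.integer(cds_ends)
  if (any(cds_ends < cds_starts)) stop("CDS interval end < start")
  o <- order(cds_starts, decreasing = (strand == "-"))
  cds_starts <- cds_starts[o]; cds_ends <- cds_ends[o]
  # overlap check on genomically sorted intervals
  gs <- sort(cds_starts); ge <- cds_ends[order(cds_starts)]
  if (length(gs) > 1L && any(gs[-1L] <= ge[-length(ge)]))
    stop("CDS intervals overlap")
  len <- sum(cds_ends - cds_starts + 1L)
  if (len %% 3L != 0L)
    stop(sprintf("total CDS length (%d) not divisible by 3", len))
  structure(list(tx_id = tx_id, gene = gene, contig = contig,
                 strand = strand, cds_starts = cds_starts,
                 cds_ends = cds_ends, cds_length = len,
                 codon_table = 1L),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s) %s:%s, %d CDS interval(s), CDS %d bp\n",
              x$tx_id, x$gene, x$contig, x$strand,
              length(x$cds_starts), x$cds_length))
  invisible(x)
}

# Genomic positions of CDS bases in transcription order.
cds_genomic_positions <- function(tm) {
  unlist(lapply(seq_along(tm$cds_starts), function(i) {
    p <- tm$cds_starts[i]:tm$cds_ends[i]
    if (tm$strand == "-") rev(p) else p
  }), use.names = FALSE)
}

#' Map a genomic position to a CDS coordinate
#'
#' On the plus strand, CDS bases are counted from the CDS start through the
#' intervals in ascending genomic order; on the minus strand, from the
#' genomic CDS end backwards.  Positions outside every CDS interval map to
#' `NA`.
#'
#' @param tm a `transcript_model`.
#' @param genomic_pos integer vector of 1-based genomic positions.
#' @return integer vector of 1-based CDS positions, `NA` when non-coding.
#' @export
genomic_to_cds <- function(tm, genomic_pos) {
  match(as.integer(genomic_pos), cds_genomic_positions(tm))
}

#' Genomic span of a transcript's CDS (1-based inclusive)
#' @param tm a `transcript_model`.
#' @return integer vector `c(start, end)` in genomic coordinates.
#' @export
transcript_span <- function(tm) {
  c(min(tm$cds_starts), max(tm$cds_ends))
}

#' Read transcript models from a GFF3 file
#'
#' Expects `CDS` features with a `Parent` attribute naming the transcript;
#' the transcript feature's own `Parent` (or a `gene_name`/`Name` attribute)
#' supplies the gene symbol, falling back to the transcript id.
#'
#' @param path path to a GFF3 file.
#' @return named list of `transcript_model` objects (names = transcript ids).
#' @export
read_transcripts_gff3 <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(g)
  is_cds <- as.character(md$type) == "CDS"
  if (!any(is_cds)) stop("no CDS features in GFF3: ", path)
  cds <- g[is_cds]
  parents <- vapply(S4Vectors::mcols(cds)$Parent, function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  if (anyNA(parents)) stop("CDS feature without Parent attribute")
  # transcript id -> gene symbol: follow the transcript's Parent to the gene
  # feature and prefer its Name attribute, falling back to ids
  ids <- as.character(md$ID)
  names_attr <- if (!is.null(md$Name)) as.character(md$Name) else
    rep(NA_character_, length(g))
  gene_symbol_for <- function(tx) {
    i <- match(tx, ids)
    if (is.na(i)) return(tx)
    p <- md$Parent[[i]]
    if (!length(p)) return(tx)
    j <- match(as.character(p[[1]]), ids)
    if (!is.na(j) && !is.na(names_attr[j]) && nzchar(names_attr[j]))
      return(names_attr[j])
    as.character(p[[1]])
  }
  out <- lapply(split(seq_along(cds), parents), function(ii) {
    cc <- cds[ii]
    tx <- parents[ii[1]]
    transcript_model(
      tx_id = tx, gene = gene_symbol_for(tx),
      contig = as.character(GenomicRanges::seqnames(cc))[1],
      strand = as.character(GenomicRanges::strand(cc))[1],
      cds_starts = GenomicRanges::start(cc),
      cds_ends = GenomicRanges::end(cc)
    )
  })
  out
}

#' Read transcript models from a 6-column interval TSV
#'
#' Columns: `contig`, `start`, `end`, `transcript`, `strand`, `frame`
#' (header optional, detected).  Coordinates are 1-based inclusive.  The
#' gene symbol defaults to the transcript id.
#'
#' @param path path to the TSV file.
#' @return named list of `transcript_model` objects.
#' @export
read_transcripts_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("contig", first, fixed = TRUE)
  df <- utils::read.table(path, header = has_header, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!has_header)
    names(df) <- c("contig", "start", "end", "transcript", "strand", "frame")
  lapply(split(df, df$transcript), function(d)
    transcript_model(d$transcript[1], d$transcript[1], d$contig[1],
                     d$strand[1], d$start, d$end))
}

#' Write transcript models as GFF3
#'
#' @param tms list of `transcript_model` objects.
#' @param path output path.
#' @export
write_transcripts_gff3 <- function(tms, path) {
  lines <- "##gff-version 3"
  for (tm in tms) {
    span <- transcript_span(tm)
    gid <- paste0("gene-", tm$gene)
    lines <- c(lines,
      sprintf("%s\tcasevar\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
              tm$contig, span[1], span[2], tm$strand, gid, tm$gene),
      sprintf("%s\tcasevar\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              tm$contig, span[1], span[2], tm$strand, tm$tx_id, gid))
    gs <- sort(tm$cds_starts)
    ge <- tm$cds_ends[order(tm$cds_starts)]
    for (i in seq_along(gs))
      lines <- c(lines,
        sprintf("%s\tcasevar\tCDS\t%d\t%d\t.\t%s\t0\tID=cds-%s;Parent=%s",
                tm$contig, gs[i], ge[i], tm$strand, tm$tx_id, tm$tx_id))
  }
  writeLines(lines, path)
  invisible(path)
}
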