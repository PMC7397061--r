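#' Read a protein multiple alignment from aligned FASTA
#'
#' @param path path to an aligned FASTA file (gap character `-`).
#' @return named character vector of aligned amino-acid strings.
#' @export
read_alignment <- function(path) {
  aln <- Biostrings::readAAStringSet(path)
  out <- stats::setNames(toupper(as.character(aln)), names(aln))
  validate_alignment(out)
}

validate_alignment <- function(aln) {
  if (length(aln) < 2L) stop("alignment needs at least 2 sequences")
  if (length(unique(nchar(aln))) != 1L)
    stop("aligned sequences must all have equal length")
  aln
}

#' Map an ungapped residue index to its alignment column
#'
#' @param aln named character vector of aligned sequences.
#' @param seq_id identifier of the reference row.
#' @param residue_index 1-based index into the ungapped sequence.
#' @return 1-based alignment column index.
#' @export
map_residue_to_column <- function(aln, seq_id, residue_index) {
  validate_alignment(aln)
  if (!seq_id %in% names(aln)) stop("sequence id not in alignment: ", seq_id)
  chars <- strsplit(aln[[seq_id]], "", fixed = TRUE)[[1]]
  nongap <- cumsum(chars != "-")
  if (residue_index < 1L || residue_index > nongap[length(nongap)])
    stop(sprintf("residue index %d beyond ungapped length %d of %s",
                 residue_index, nongap[length(nongap)], seq_id))
  which(nongap == residue_index & chars != "-")[1]
}

#' Conservation of the alignment column holding a reference residue
#'
#' Scores binary identity to the reference residue over all non-gap rows of
#' the column (the reference row is included in the denominator); the column
#' is strictly conserved when every non-gap row matches.
#'
#' @param aln named character vector of aligned sequences.
#' @param ref_seq_id identifier of the reference row.
#' @param residue_index 1-based residue index in the ungapped reference.
#' @return list with `column` (1-based), `ref_residue`,
#'   `fraction_identical`, `strictly_conserved`, `n_nongap`.
#' @export
column_conservation <- function(aln, ref_seq_id, residue_index) {
  col <- map_residue_to_column(aln, ref_seq_id, residue_index)
  chars <- vapply(aln, function(s) substr(s, col, col), character(1))
  nongap <- chars != "-"
  if (!any(nongap)) stop("all-gap column")
  ref_res <- chars[[ref_seq_id]]
  frac <- sum(chars[nongap] == ref_res) / sum(nongap)
  list(column = col, ref_residue = ref_res, fraction_identical = frac,
       strictly_conserved = (frac == 1), n_nongap = sum(nongap))
}

#' Write a conservation result as a one-row TSV
#' @param res result of [column_conservation()].
#' @param path output path.
#' @export
write_conservation <- function(res, path) {
  utils::write.table(
    data.frame(column = res$column, ref_residue = res$ref_residue,
               n_species = res$n_nongap,
               fraction_identical = res$fraction_identical,
               strictly_conserved = res$strictly_conserved),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
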