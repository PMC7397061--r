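#' Construct a table of normalized biallelic variant records
#'
#' A variant table is a plain `data.frame` with one row per biallelic variant
#' and columns `contig`, `pos` (1-based), `ref`, `alt` and `vid` (optional
#' identifier, `NA` when absent).  All downstream set operations identify a
#' variant by its normalized `(contig, pos, ref, alt)` tuple.
#'
#' @param contig character vector of contig identifiers.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt allele strings, uppercase over `A`,`C`,`G`,`T`,`N`.
#' @param vid optional variant identifiers (recycled `NA` by default).
#' @return a `data.frame` with columns `contig`, `pos`, `ref`, `alt`, `vid`.
#' @export
variant_table <- function(contig, pos, ref, alt, vid = NA_character_) {
  df <- data.frame(
    contig = as.character(contig),
    pos = as.integer(pos),
    ref = toupper(as.character(ref)),
    alt = toupper(as.character(alt)),
    vid = as.character(vid),
    stringsAsFactors = FALSE
  )
  validate_variant_table(df)
  df
}

validate_variant_table <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("contig", "pos", "ref", "alt") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$pos < 1L)) stop("variant positions must be >= 1")
  ok_allele <- function(a) nzchar(a) & !grepl("[^ACGTN]", a)
  if (!all(ok_allele(df$ref)) || !all(ok_allele(df$alt)))
    stop("alleles must be non-empty uppercase strings over {A,C,G,T,N}")
  if (any(df$ref == df$alt)) stop("ref and alt alleles must differ")
  invisible(df)
}

#' Variant identity key used for set operations
#'
#' @param variants a variant table (see [variant_table()]).
#' @return character vector `"contig:pos:ref:alt"`, one per row.
#' @export
variant_key <- function(variants) {
  paste(variants$contig, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' Construct a genotype matrix
#'
#' The central container for multi-sample genotype data: an ordered variant
#' table plus a `variants x samples` integer matrix of per-sample alternate
#' allele counts (0, 1, 2, or `NA` for a missing call).
#'
#' @param variants a variant table (see [variant_table()]).
#' @param samples character vector of unique sample identifiers.
#' @param calls integer matrix, `nrow(variants)` x `length(samples)`, with
#'   entries in `{0, 1, 2, NA}`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(variants, samples, calls) {
  validate_variant_table(variants)
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("sample ids must be unique")
  calls <- matrix(as.integer(calls), nrow = nrow(variants),
                  ncol = length(samples))
  colnames(calls) <- samples
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) stop("allele counts must be 0, 1, 2 or NA")
  structure(list(variants = variants, samples = samples, calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d variants x %d samples\n",
              nrow(x$variants), length(x$samples)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(nrow(x$variants), length(x$samples))

#' Subset a genotype matrix by variant rows
#'
#' @param gm a `genotype_matrix`.
#' @param i integer or logical row index over variants.
#' @return a `genotype_matrix` restricted to the selected variants.
#' @export
subset_variants <- function(gm, i) {
  genotype_matrix(gm$variants[i, , drop = FALSE], gm$samples,
                  gm$calls[i, , drop = FALSE])
}

#' Read a sample sheet
#'
#' Tab-separated file with header `sample`, `status`, `breed`, `family`.
#' `status` must be one of `case`, `control`, `unknown`; `family` may be
#' empty.
#'
#' @param path path to the TSV file.
#' @return `data.frame` with columns `sample`, `status`, `breed`, `family`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "")
  need <- c("sample", "status")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns 'sample' and 'status'")
  if (is.null(df$breed)) df$breed <- NA_character_
  if (is.null(df$family)) df$family <- NA_character_
  validate_sample_sheet(df[c("sample", "status", "breed", "family")])
}

validate_sample_sheet <- function(sheet) {
  if (anyDuplicated(sheet$sample))
    stop("duplicate sample ids in sample sheet")
  bad <- setdiff(unique(sheet$status), c("case", "control", "unknown"))
  if (length(bad))
    stop("invalid status value(s): ", paste(bad, collapse = ", "))
  sheet
}

#' Write a sample sheet
#' @param sheet sample sheet `data.frame`.
#' @param path output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
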