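#' Inheritance models for case-exclusive filtering
#'
#' `DOMINANT_HET` requires every case to be heterozygous; `RECESSIVE_HOM`
#' requires every case to be homozygous for the alternate allele.  Under
#' either model every control must carry zero alternate alleles.
#'
#' @format character constants.
#' @name inheritance_models
NULL

#' @rdname inheritance_models
#' @export
DOMINANT_HET <- "DOMINANT_HET"

#' @rdname inheritance_models
#' @export
RECESSIVE_HOM <- "RECESSIVE_HOM"

#' Variants exclusively shared by all cases and absent from all controls
#'
#' The core discovery filter for a rare Mendelian trait: keep variants at
#' which every case shows the model genotype (het for a dominant model,
#' hom-alt for a recessive one) and no control carries the alternate allele.
#' A missing call in a case always fails the sharing requirement (sharing
#' must be observed).  A missing call in a control is governed by
#' `missing_control`: `"ref"` (default) treats it as non-carriage, so the
#' variant may survive; `"drop"` discards any variant with a missing control
#' call.
#'
#' @param gm a `genotype_matrix` of normalized biallelic variants.
#' @param sheet sample sheet with `sample` and `status` columns; must
#'   contain at least one case.
#' @param model `DOMINANT_HET` or `RECESSIVE_HOM`.
#' @param missing_control `"ref"` or `"drop"` (see Details).
#' @return integer vector of surviving variant row indices, in input order.
#' @export
case_exclusive_variants <- function(gm, sheet, model = DOMINANT_HET,
                                    missing_control = c("ref", "drop")) {
  missing_control <- match.arg(missing_control)
  model <- match.arg(model, c(DOMINANT_HET, RECESSIVE_HOM))
  sheet <- validate_sample_sheet(sheet)
  if (!all(sheet$sample %in% gm$samples))
    stop("sample sheet sample(s) missing from genotype matrix: ",
         paste(setdiff(sheet$sample, gm$samples), collapse = ", "))
  cases <- sheet$sample[sheet$status == "case"]
  controls <- sheet$sample[sheet$status == "control"]
  n_unknown <- sum(sheet$status == "unknown")
  if (length(cases) == 0L) stop("no case samples in sample sheet")
  if (n_unknown > 0L)
    message(sprintf("case_exclusive_variants: ignoring %d unknown-status sample(s)",
                    n_unknown))
  need <- if (model == DOMINANT_HET) 1L else 2L
  cc <- gm$calls[, cases, drop = FALSE]
  case_ok <- rowSums(!is.na(cc) & cc == need) == length(cases)
  ctl <- gm$calls[, controls, drop = FALSE]
  ctl_ok <- if (missing_control == "ref") {
    rowSums(!is.na(ctl) & ctl > 0L) == 0L
  } else {
    rowSums(is.na(ctl) | ctl > 0L) == 0L
  }
  which(case_ok & ctl_ok)
}

#' Summarize case-exclusive filtering across both zygosity models
#'
#' Produces the two-row count ledger of the discovery analysis: total
#' case-exclusive variants split by zygosity model, and how many of each are
#' protein-changing.  The two model sets are disjoint by construction (a
#' case genotype cannot be both het and hom-alt), so the total is their sum.
#'
#' @param gm a `genotype_matrix`.
#' @param sheet sample sheet.
#' @param effects character vector of effect classes, parallel to the
#'   variant rows of `gm` (`NA` allowed for variants that do not survive
#'   filtering).  See [EFFECT_CLASSES].
#' @param missing_control missing-control policy, see
#'   [case_exclusive_variants()].
#' @return object of class `filter_summary`: a list with counts
#'   `n_case_exclusive_total`, `n_het_shared`, `n_hom_shared`,
#'   `n_protein_changing_het`, `n_protein_changing_hom` and the surviving
#'   row indices per model (`idx_het`, `idx_hom`).
#' @export
summarize_filter <- function(gm, sheet, effects,
                             missing_control = c("ref", "drop")) {
  missing_control <- match.arg(missing_control)
  idx_het <- case_exclusive_variants(gm, sheet, DOMINANT_HET, missing_control)
  idx_hom <- case_exclusive_variants(gm, sheet, RECESSIVE_HOM, missing_control)
  surv <- c(idx_het, idx_hom)
  if (length(effects) != nrow(gm$variants))
    stop("effects must be parallel to the variant rows")
  miss <- surv[is.na(effects[surv])]
  if (length(miss))
    stop("effect class missing for surviving variant(s): ",
         paste(variant_key(gm$variants[miss, , drop = FALSE]), collapse = ", "))
  res <- list(
    n_case_exclusive_total = length(idx_het) + length(idx_hom),
    n_het_shared = length(idx_het),
    n_hom_shared = length(idx_hom),
    n_protein_changing_het = sum(is_protein_changing(effects[idx_het])),
    n_protein_changing_hom = sum(is_protein_changing(effects[idx_hom])),
    idx_het = idx_het,
    idx_hom = idx_hom
  )
  class(res) <- "filter_summary"
  res
}

#' @export
print.filter_summary <- function(x, ...) {
  cat("Filtering step                         Het     Hom\n")
  cat(sprintf("Case-exclusive variants             %6d  %6d\n",
              x$n_het_shared, x$n_hom_shared))
  cat(sprintf("Case-exclusive protein-changing     %6d  %6d\n",
              x$n_protein_changing_het, x$n_protein_changing_hom))
  cat(sprintf("Total case-exclusive: %d\n", x$n_case_exclusive_total))
  invisible(x)
}

#' Write a filter summary as a two-row TSV
#'
#' @param fs a `filter_summary`.
#' @param path output path.
#' @export
write_filter_summary <- function(fs, path) {
  df <- data.frame(
    filtering_step = c("case_exclusive", "case_exclusive_protein_changing"),
    heterozygous = c(fs$n_het_shared, fs$n_protein_changing_het),
    homozygous = c(fs$n_hom_shared, fs$n_protein_changing_hom)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write surviving variants with per-sample calls as TSV
#'
#' @param gm genotype matrix.
#' @param idx row indices of surviving variants.
#' @param model model label recorded in the output.
#' @param path output path.
#' @export
write_survivors <- function(gm, idx, model, path) {
  v <- gm$variants[idx, , drop = FALSE]
  calls <- gm$calls[idx, , drop = FALSE]
  df <- cbind(v[c("contig", "pos", "ref", "alt")],
              model = model,
              as.data.frame(calls, optional = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
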