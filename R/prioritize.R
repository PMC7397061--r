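#' Severity rank of an effect class
#'
#' Fixed ordinal severity used by the candidate score: nonsense and
#' start/stop loss rank 3, missense 2, everything else 0.
#'
#' @param effect_class character vector of effect classes.
#' @return numeric vector of severity ranks.
#' @export
severity_rank <- function(effect_class) {
  r <- c(nonsense = 3, start_loss = 3, stop_loss = 3, missense = 2)
  out <- unname(r[effect_class])
  out[is.na(out)] <- 0
  out
}

#' Rank candidate protein-changing variants by a configurable linear score
#'
#' The score is
#' `severity * severity_rank + conservation * fraction_identical +
#'  prior * in_gene_list`.
#' The original study's prioritization among its candidates was expert
#' biological judgment; this score formalizes it as an explicit, tunable
#' surrogate.  The gene-list prior weight is 0 by default, so biological
#' knowledge only enters when deliberately switched on.
#'
#' Rows are sorted by decreasing score with a deterministic tie-break on
#' `(gene, contig, pos)`; the sort is stable, so equal rows keep their
#' input order.
#'
#' @param rows `data.frame` of candidates with columns `gene`, `contig`,
#'   `pos`, `effect_class` and optionally `conservation` (fraction in
#'   `[0, 1]`, `NA` treated as 0).
#' @param weights named list/vector with any of `severity`, `conservation`,
#'   `prior`; unknown names are an error.
#' @param gene_list character vector of prior candidate genes.
#' @return the rows, ordered, with columns `score` and `rank` appended.
#' @export
rank_candidates <- function(rows,
                            weights = c(severity = 1, conservation = 0,
                                        prior = 0),
                            gene_list = character(0)) {
  if (nrow(rows) == 0L) stop("no candidate rows to rank")
  known <- c("severity", "conservation", "prior")
  bad <- setdiff(names(weights), known)
  if (length(bad)) stop("unknown weight key(s): ", paste(bad, collapse = ", "))
  w <- c(severity = 0, conservation = 0, prior = 0)
  w[names(weights)] <- unlist(weights)
  cons <- if ("conservation" %in% names(rows)) rows$conservation else
    rep(NA_real_, nrow(rows))
  cons[is.na(cons)] <- 0
  in_list <- !is.na(rows$gene) & rows$gene %in% gene_list
  score <- w[["severity"]] * severity_rank(rows$effect_class) +
    w[["conservation"]] * cons + w[["prior"]] * as.numeric(in_list)
  ord <- order(-score, rows$gene, rows$contig, rows$pos, method = "radix")
  out <- rows[ord, , drop = FALSE]
  out$in_gene_list <- in_list[ord]
  out$score <- score[ord]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
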