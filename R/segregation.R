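#' Read a PED-like pedigree file
#'
#' Tab-separated columns `family`, `id`, `sire`, `dam`, `sex`, `phenotype`
#' with `0` meaning missing.  Sex may be coded `1`/`2`/`0` or
#' `male`/`female`/`unknown`; phenotype `2`/`1`/`0` (or `-9`) or
#' `affected`/`unaffected`/`unknown`.
#'
#' @param path path to the pedigree file.
#' @return a `data.frame` with columns `family`, `id`, `sire`, `dam`
#'   (`NA` = missing parent), `sex`, `phenotype`.
#' @export
read_pedigree <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("family", first, fixed = TRUE)
  df <- utils::read.table(path, header = has_header, sep = "\t",
                          colClasses = "character")
  if (!has_header)
    names(df) <- c("family", "id", "sire", "dam", "sex", "phenotype")
  df$sire[df$sire == "0"] <- NA_character_
  df$dam[df$dam == "0"] <- NA_character_
  sex_map <- c(`1` = "male", `2` = "female", `0` = "unknown",
               male = "male", female = "female", unknown = "unknown")
  phe_map <- c(`2` = "affected", `1` = "unaffected", `0` = "unknown",
               `-9` = "unknown", affected = "affected",
               unaffected = "unaffected", unknown = "unknown")
  df$sex <- unname(sex_map[df$sex])
  df$phenotype <- unname(phe_map[df$phenotype])
  validate_pedigree(df)
}

validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$id)) stop("duplicate individual ids in pedigree")
  for (col in c("sire", "dam")) {
    refd <- stats::na.omit(ped[[col]])
    missing <- setdiff(refd, ped$id)
    if (length(missing))
      stop("pedigree references unknown ", col, "(s): ",
           paste(missing, collapse = ", "))
  }
  # sire male / dam female when sex known
  sire_sex <- ped$sex[match(ped$sire, ped$id)]
  dam_sex <- ped$sex[match(ped$dam, ped$id)]
  if (any(!is.na(sire_sex) & sire_sex == "female"))
    stop("a female individual is recorded as sire")
  if (any(!is.na(dam_sex) & dam_sex == "male"))
    stop("a male individual is recorded as dam")
  # cycle check by iterative founder elimination
  remaining <- ped$id
  repeat {
    parents_of <- function(i) {
      r <- ped[match(i, ped$id), ]
      stats::na.omit(c(r$sire, r$dam))
    }
    founders <- remaining[vapply(remaining, function(i)
      !any(parents_of(i) %in% remaining), logical(1))]
    if (!length(founders)) break
    remaining <- setdiff(remaining, founders)
  }
  if (length(remaining))
    stop("pedigree contains an ancestry cycle involving: ",
         paste(remaining, collapse = ", "))
  ped
}

#' Write a pedigree as PED-like TSV (numeric codes, 0 = missing)
#' @param ped pedigree `data.frame` (see [read_pedigree()]).
#' @param path output path.
#' @export
write_pedigree <- function(ped, path) {
  out <- ped
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  out$sex <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  out$phenotype <- c(affected = "2", unaffected = "1",
                     unknown = "0")[ped$phenotype]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# allele counts a genotyped (or ungenotyped, NA) parent can transmit
transmissible <- function(gt) {
  if (is.na(gt)) return(c(0L, 1L))
  switch(as.character(gt), `0` = 0L, `1` = c(0L, 1L), `2` = 1L)
}

#' Check compatibility with fully penetrant autosomal dominant inheritance
#'
#' Scans a pedigree plus a (possibly partial) genotype map for violations
#' of a fully penetrant dominant model at a biallelic locus:
#' \itemize{
#'   \item an affected individual carrying no alternate allele;
#'   \item an unaffected individual carrying an alternate allele (reported
#'     as a warning instead of a violation with `allow_nonpenetrant`);
#'   \item a Mendelian impossibility given the genotyped parents (e.g. a
#'     het offspring of two hom-ref parents).
#' }
#' Unknown-phenotype individuals never trigger phenotype violations;
#' ungenotyped individuals are skipped.
#'
#' @param ped pedigree `data.frame` (see [read_pedigree()]).
#' @param genotypes named integer vector of alt-allele counts (0/1/2),
#'   keyed by individual id; may cover a subset of the pedigree.
#' @param allow_nonpenetrant downgrade unaffected-carrier violations to
#'   warnings.
#' @return list with `consistent` (logical) and `violations`, a
#'   `data.frame` with columns `id` and `rule`.
#' @export
check_dominant_segregation <- function(ped, genotypes,
                                       allow_nonpenetrant = FALSE) {
  ped <- validate_pedigree(ped)
  unknown_ids <- setdiff(names(genotypes), ped$id)
  if (length(unknown_ids))
    stop("genotype(s) for id(s) not in pedigree: ",
         paste(unknown_ids, collapse = ", "))
  viol <- list()
  add <- function(id, rule) viol[[length(viol) + 1L]] <<- list(id = id,
                                                               rule = rule)
  for (i in seq_len(nrow(ped))) {
    id <- ped$id[i]
    gt <- if (id %in% names(genotypes)) genotypes[[id]] else NA_integer_
    if (is.na(gt)) next
    phe <- ped$phenotype[i]
    if (phe == "affected" && gt == 0L)
      add(id, "affected_without_alt_allele")
    if (phe == "unaffected" && gt >= 1L) {
      if (allow_nonpenetrant)
        warning("unaffected carrier (non-penetrance allowed): ", id,
                call. = FALSE)
      else add(id, "unaffected_carrier")
    }
    sire_gt <- if (!is.na(ped$sire[i]) && ped$sire[i] %in% names(genotypes))
      genotypes[[ped$sire[i]]] else NA_integer_
    dam_gt <- if (!is.na(ped$dam[i]) && ped$dam[i] %in% names(genotypes))
      genotypes[[ped$dam[i]]] else NA_integer_
    possible <- unique(outer(transmissible(sire_gt), transmissible(dam_gt),
                             "+"))
    if (!(gt %in% possible))
      add(id, "mendelian_impossible_given_parents")
  }
  violations <- if (length(viol))
    data.frame(id = vapply(viol, `[[`, "", "id"),
               rule = vapply(viol, `[[`, "", "rule"),
               stringsAsFactors = FALSE)
  else data.frame(id = character(0), rule = character(0))
  list(consistent = nrow(violations) == 0L, violations = violations)
}

#' Genotype-by-phenotype association table
#'
#' Tabulates genotype class (hom-ref / het / hom-alt) against case/control
#' status for a genotyped cohort.  Unknown-status samples are excluded with
#' a logged count; samples without a genotype are ignored.
#'
#' @param genotypes named integer vector of alt-allele counts keyed by
#'   sample id.
#' @param sheet sample sheet with `sample` and `status`.
#' @return integer matrix with rows `hom_ref`, `het`, `hom_alt` and columns
#'   `case`, `control`, of class `association_table`.
#' @export
association_table <- function(genotypes, sheet) {
  sheet <- validate_sample_sheet(sheet)
  no_status <- setdiff(names(genotypes), sheet$sample)
  if (length(no_status))
    stop("genotyped sample(s) without status: ",
         paste(no_status, collapse = ", "))
  tab <- matrix(0L, nrow = 3L, ncol = 2L,
                dimnames = list(c("hom_ref", "het", "hom_alt"),
                                c("case", "control")))
  n_excluded <- 0L
  for (s in names(genotypes)) {
    gt <- genotypes[[s]]
    if (is.na(gt)) next
    status <- sheet$status[match(s, sheet$sample)]
    if (status == "unknown") { n_excluded <- n_excluded + 1L; next }
    row <- c("hom_ref", "het", "hom_alt")[gt + 1L]
    tab[row, status] <- tab[row, status] + 1L
  }
  if (n_excluded > 0L)
    message(sprintf("association_table: excluded %d unknown-status sample(s)",
                    n_excluded))
  structure(tab, class = c("association_table", class(tab)))
}

#' Perfect genotype-phenotype association?
#'
#' `TRUE` when every case carries at least one alternate allele and every
#' control carries none.
#'
#' @param tab an `association_table`.
#' @return logical scalar.
#' @export
is_perfectly_associated <- function(tab) {
  tab["hom_ref", "case"] == 0L &&
    sum(tab[c("het", "hom_alt"), "case"]) > 0L &&
    sum(tab[c("het", "hom_alt"), "control"]) == 0L
}

#' Two-sided exact test on the carrier-by-phenotype 2x2 collapse
#'
#' Collapses het and hom-alt into a carrier class and runs Fisher's exact
#' test.  Provided for reporting only.
#'
#' @param tab an `association_table`.
#' @return the `htest` object from [stats::fisher.test()].
#' @export
association_exact_test <- function(tab) {
  m <- rbind(carrier = colSums(tab[c("het", "hom_alt"), , drop = FALSE]),
             hom_ref = tab["hom_ref", ])
  stats::fisher.test(m)
}
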