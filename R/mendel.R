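#' Detect Mendelian inconsistencies in trio genotypes
#'
#' Flags a (child, father, mother) trio at a variant when the child's
#' biallelic autosomal genotype is impossible given both parental
#' genotypes: a child cannot be homozygous reference if either parent is
#' homozygous alternate (and vice versa), and cannot be heterozygous when
#' both parents are the same homozygote. Trios with any missing member
#' genotype — or with a parent absent from the genotype matrix — are
#' skipped, never flagged.
#'
#' @param geno a genotype matrix object (see [genotype_matrix()]): dosages
#'   in \{0, 1, 2, NA\}, individuals x variants.
#' @param ped pedigree covering every genotyped individual.
#' @return data frame (class `famvar_mendel_report`) with one row per
#'   inconsistent trio x variant: `variant`, `child`, `father`, `mother`,
#'   `family`. Attribute `variants` holds all variant ids scanned so clean
#'   variants can be reported with a zero count.
#' @export
find_mendel_errors <- function(geno, ped) {
  stopifnot(inherits(ped, "famvar_pedigree"))
  dos <- geno$dosage
  unknown <- setdiff(rownames(dos), ped$id)
  if (length(unknown)) {
    stop("genotyped individual(s) absent from pedigree: ",
         paste(unknown, collapse = ", "))
  }
  trios <- ped[!is.na(ped$father) & !is.na(ped$mother), c("id", "father", "mother", "family")]
  if (anyDuplicated(trios$id)) stop("duplicate trio for child: ",
                                    paste(trios$id[duplicated(trios$id)], collapse = ", "))
  keep <- trios$id %in% rownames(dos) &
    trios$father %in% rownames(dos) & trios$mother %in% rownames(dos)
  trios <- trios[keep, , drop = FALSE]
  empty <- data.frame(variant = character(), child = character(),
                      father = character(), mother = character(),
                      family = character(), stringsAsFactors = FALSE)
  if (!nrow(trios)) return(mendel_report(empty, colnames(dos)))

  C <- dos[trios$id, , drop = FALSE]
  Fa <- dos[trios$father, , drop = FALSE]
  Mo <- dos[trios$mother, , drop = FALSE]
  bad <- (C == 0 & (Fa == 2 | Mo == 2)) |
         (C == 2 & (Fa == 0 | Mo == 0)) |
         (C == 1 & ((Fa == 0 & Mo == 0) | (Fa == 2 & Mo == 2)))
  bad[is.na(C) | is.na(Fa) | is.na(Mo)] <- FALSE  # any missing member: skip
  bad[is.na(bad)] <- FALSE
  hit <- which(bad, arr.ind = TRUE)
  rep <- data.frame(
    variant = colnames(dos)[hit[, 2]],
    child = trios$id[hit[, 1]],
    father = trios$father[hit[, 1]],
    mother = trios$mother[hit[, 1]],
    family = trios$family[hit[, 1]],
    stringsAsFactors = FALSE
  )
  mendel_report(rep[order(rep$variant, rep$child), , drop = FALSE], colnames(dos))
}

mendel_report <- function(df, variants) {
  rownames(df) <- NULL
  attr(df, "variants") <- variants
  class(df) <- c("famvar_mendel_report", "data.frame")
  df
}

#' Count families with Mendelian errors per variant
#'
#' Each family is counted at most once per variant regardless of how many
#' of its trios are inconsistent; clean variants get 0. This is the count
#' the MAF-stratified Mendel-error filter thresholds apply to.
#'
#' @param report output of [find_mendel_errors()].
#' @return named integer vector over all scanned variants.
#' @export
mendel_family_counts <- function(report) {
  variants <- attr(report, "variants")
  counts <- stats::setNames(integer(length(variants)), variants)
  if (nrow(report)) {
    tab <- tapply(report$family, report$variant,
                  function(f) length(unique(f)))
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}
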