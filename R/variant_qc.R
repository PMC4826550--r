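#' Genotype matrix container
#'
#' Bundles an individuals x variants additive dosage matrix with its
#' per-variant annotation table. Dosages count alternate alleles
#' (0/1/2, NA missing).
#'
#' @param dosage numeric matrix, rownames = individual ids, colnames =
#'   variant ids (`chrom:pos:ref:alt`).
#' @param variants data frame with one row per column of `dosage`; must
#'   contain `variant`; typical columns: `chrom`, `pos`, `ref`, `alt`,
#'   `rsid`, `gene`, `function_class`, `mean_coverage`, `quality`,
#'   `call_rate`, `maf`, `mac`, `mendel_family_count`.
#' @return object of class `famvar_genotypes` (list with `dosage`,
#'   `variants`).
#' @export
genotype_matrix <- function(dosage, variants) {
  stopifnot(is.matrix(dosage), !is.null(rownames(dosage)), !is.null(colnames(dosage)))
  if (!"variant" %in% names(variants)) stop("variants table needs a 'variant' column")
  if (!identical(colnames(dosage), as.character(variants$variant))) {
    stop("variant ids of dosage columns and annotation table disagree")
  }
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  rownames(variants) <- NULL
  structure(list(dosage = dosage, variants = variants),
            class = "famvar_genotypes")
}

#' @export
print.famvar_genotypes <- function(x, ...) {
  cat("famvar genotype matrix:", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "variants\n")
  invisible(x)
}

#' Minor allele frequency and count
#'
#' Alternate-allele frequency over non-missing alleles, folded to the
#' minor allele; `mac` is the minor-allele count.
#'
#' @param dosages vector of dosages in \{0, 1, 2, NA\}.
#' @return list with `maf` and `mac`.
#' @examples
#' compute_maf(c(0, 0, 1, 2))  # maf 0.375, mac 3
#' @export
compute_maf <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (!length(d)) stop("all genotypes missing")
  alt <- sum(d)
  tot <- 2L * length(d)
  if (2 * alt > tot) alt <- tot - alt
  list(maf = alt / tot, mac = as.integer(alt))
}

#' Variant filter configuration
#'
#' Thresholds of the filter cascade: minimum per-variant mean coverage,
#' phred-like quality, call rate; for burden ("rare functional") mode a
#' maximum MAF and the retained functional classes; and the MAF-stratified
#' Mendel-error family-count cutoffs. The Mendel table excludes a variant
#' when errors occur in at least the stated number of families: >= 3
#' families for MAF in [0, 0.01), then >= 7, 12, 26, 30, 32 and 38 for the
#' successive bins up to 0.51.
#'
#' @param mode `"single"` (coverage/quality/call-rate/Mendel) or
#'   `"burden"` (additionally MAF <= `burden_max_maf` and functional class).
#' @param min_coverage,min_quality,min_call_rate,burden_max_maf thresholds;
#'   coverage/quality/call-rate comparisons are strict (`< threshold`
#'   fails), the MAF comparison removes `maf > burden_max_maf`.
#' @param functional_classes classes retained in burden mode.
#' @return list of class `famvar_filter_config`.
#' @export
filter_config <- function(mode = c("single", "burden"),
                          min_coverage = 5, min_quality = 45,
                          min_call_rate = 0.60, burden_max_maf = 0.01,
                          functional_classes = c("nsyn-exonic", "syn-exonic",
                                                 "stopgain", "stoploss",
                                                 "UTR3", "UTR5", "splicing",
                                                 "ncRNA")) {
  structure(list(
    mode = match.arg(mode),
    min_coverage = min_coverage,
    min_quality = min_quality,
    min_call_rate = min_call_rate,
    burden_max_maf = burden_max_maf,
    functional_classes = functional_classes,
    mendel_bins = data.frame(
      lower = c(0, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4),
      upper = c(0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.51),
      min_families = c(3L, 7L, 12L, 26L, 30L, 32L, 38L)
    )
  ), class = "famvar_filter_config")
}

#' Mendel-error exclusion cutoff for a given MAF
#'
#' Smallest number of error-bearing families at which a variant of the
#' given minor allele frequency is excluded.
#'
#' @param maf minor allele frequency in [0, 0.51).
#' @param config a [filter_config()].
#' @return integer family-count threshold.
#' @examples
#' mendel_cutoff_for(0.005)  # 3
#' mendel_cutoff_for(0.03)   # 7
#' @export
mendel_cutoff_for <- function(maf, config = filter_config()) {
  bins <- config$mendel_bins
  out <- vapply(maf, function(m) {
    if (is.na(m) || m < 0 || m >= max(bins$upper)) {
      stop("maf outside [0, ", max(bins$upper), "): ", m)
    }
    bins$min_families[m >= bins$lower & m < bins$upper]
  }, integer(1))
  out
}

#' Annotate per-variant QC statistics
#'
#' Fills `call_rate`, `maf`, `mac` from the dosage matrix and
#' `mendel_family_count` from the pedigree (0 everywhere when `ped` is
#' NULL).
#'
#' @param geno `famvar_genotypes`.
#' @param ped pedigree for Mendel-error counting, or NULL.
#' @return `famvar_genotypes` with the QC columns populated.
#' @export
variant_qc_annotate <- function(geno, ped = NULL) {
  dos <- geno$dosage
  v <- geno$variants
  v$call_rate <- colMeans(!is.na(dos))
  mafmac <- apply(dos, 2, function(x) unlist(compute_maf(x)))
  v$maf <- mafmac["maf", ]
  v$mac <- as.integer(mafmac["mac", ])
  if (!is.null(ped)) {
    v$mendel_family_count <- as.integer(
      mendel_family_counts(find_mendel_errors(geno, ped)))
  } else if (is.null(v$mendel_family_count)) {
    v$mendel_family_count <- 0L
  }
  genotype_matrix(dos, v)
}

#' Apply the variant filter cascade
#'
#' Filters in the printed order — coverage, quality, call rate, (burden:
#' MAF), Mendel errors, (burden: nonfunctional class) — attributing each
#' removed variant to the first failing filter. The retained set is
#' order-invariant; only the attribution log depends on order.
#'
#' @param geno annotated `famvar_genotypes` (see [variant_qc_annotate()]).
#' @param config a [filter_config()].
#' @return list with `retained` (`famvar_genotypes`) and `log` (data frame
#'   `variant`, `filter`, `value`, `threshold` for each removal).
#' @export
apply_filters <- function(geno, config = filter_config()) {
  v <- geno$variants
  n <- nrow(v)
  filt <- rep(NA_character_, n)
  val <- rep(NA_real_, n)
  thr <- rep(NA_real_, n)
  mark <- function(bad, name, values, thresholds) {
    new <- bad & is.na(filt)
    filt[new] <<- name
    val[new] <<- values[new]
    thr[new] <<- thresholds[new]
  }
  mark(v$mean_coverage < config$min_coverage, "coverage",
       v$mean_coverage, rep(config$min_coverage, n))
  mark(v$quality < config$min_quality, "quality",
       v$quality, rep(config$min_quality, n))
  mark(v$call_rate < config$min_call_rate, "call_rate",
       v$call_rate, rep(config$min_call_rate, n))
  if (config$mode == "burden") {
    mark(v$maf > config$burden_max_maf, "maf",
         v$maf, rep(config$burden_max_maf, n))
  }
  cutoffs <- vapply(v$maf, mendel_cutoff_for, integer(1), config = config)
  mark(v$mendel_family_count >= cutoffs, "mendel",
       as.numeric(v$mendel_family_count), as.numeric(cutoffs))
  if (config$mode == "burden") {
    mark(!(v$function_class %in% config$functional_classes), "nonfunctional",
         rep(NA_real_, n), rep(NA_real_, n))
  }
  keep <- is.na(filt)
  log <- data.frame(variant = v$variant[!keep], filter = filt[!keep],
                    value = val[!keep], threshold = thr[!keep],
                    stringsAsFactors = FALSE)
  retained <- genotype_matrix(geno$dosage[, keep, drop = FALSE],
                              v[keep, , drop = FALSE])
  list(retained = retained, log = log)
}

#' Variant class fractions and rarity summary
#'
#' Per-class fractions of the variant set plus the grouped summaries a
#' candidate-gene resequencing report quotes: the coding fraction
#' (exonic + stop-altering), the missense/nonsense fraction, the UTR
#' fraction, the rare fraction (MAF < `rare_maf`) and the singleton
#' fraction (MAC 1) among the rare subset.
#'
#' @param variants per-variant annotation data frame (needs
#'   `function_class`, `maf`, `mac`).
#' @param rare_maf rarity threshold (default 0.01).
#' @return list with `by_class` (named fractions summing to 1), `coding`,
#'   `missense_nonsense`, `utr`, `rare`, `singleton_among_rare`; all as
#'   fractions in [0, 1].
#' @export
class_fractions <- function(variants, rare_maf = 0.01) {
  if (!nrow(variants)) stop("empty variant set")
  cls <- variants$function_class
  n <- length(cls)
  by_class <- table(cls) / n
  coding_classes <- c("nsyn-exonic", "syn-exonic", "stopgain", "stoploss")
  misnon <- c("nsyn-exonic", "stopgain", "stoploss")
  rare <- variants$maf < rare_maf
  list(
    by_class = stats::setNames(as.numeric(by_class), names(by_class)),
    coding = mean(cls %in% coding_classes),
    missense_nonsense = mean(cls %in% misnon),
    utr = mean(cls %in% c("UTR3", "UTR5")),
    rare = mean(rare),
    singleton_among_rare = if (any(rare)) mean(variants$mac[rare] == 1) else NA_real_
  )
}
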