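#' Read genotypes from a VCF file
#'
#' Minimal VCF v4.2 reader for biallelic candidate-gene call sets: GT
#' fields become additive dosages (0/1, 1/1, ./. -> 1, 2, NA; phased
#' separators accepted), QUAL becomes the per-variant quality, and the
#' INFO keys named by `coverage_field` / `gene_field` / `class_field`
#' populate the QC and annotation columns. Multiallelic records are
#' rejected with the offending line number — split them upstream.
#'
#' @param path VCF file path (uncompressed).
#' @param coverage_field INFO key holding mean fold coverage.
#' @param gene_field,class_field INFO keys holding the gene symbol and
#'   functional class.
#' @return `famvar_genotypes`.
#' @export
read_vcf <- function(path, coverage_field = "DP", gene_field = "GENE",
                     class_field = "FUNC") {
  lines <- readLines(path)
  body_at <- which(!startsWith(lines, "#"))
  header_line <- grep("^#CHROM", lines, value = TRUE)
  if (!length(header_line)) stop("no #CHROM header line in ", path)
  cols <- strsplit(sub("^#", "", header_line), "\t")[[1]]
  if (length(cols) < 10) stop("VCF has no sample columns")
  samples <- cols[-(1:9)]

  n <- length(samples); m <- length(body_at)
  dos <- matrix(NA_real_, n, m, dimnames = list(samples, NULL))
  variants <- vector("list", m)
  for (k in seq_len(m)) {
    ln <- body_at[k]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (grepl(",", f[5], fixed = TRUE)) {
      stop("multiallelic record at line ", ln,
           ": split multiallelic sites before loading")
    }
    info <- parse_info(f[8])
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_i <- match("GT", fmt)
    if (is.na(gt_i)) stop("no GT in FORMAT at line ", ln)
    gts <- vapply(strsplit(f[-(1:9)], ":", fixed = TRUE), `[`, character(1), gt_i)
    d <- gt_to_dosage(gts)
    if (anyNA(d) && any(!gts %in% c("./.", ".|.", ".") & is.na(d))) {
      stop("malformed GT at line ", ln, ": ",
           gts[which(!gts %in% c("./.", ".|.", ".") & is.na(d))[1]])
    }
    dos[, k] <- d
    variants[[k]] <- data.frame(
      chrom = f[1], pos = as.integer(f[2]),
      rsid = if (f[3] == ".") NA_character_ else f[3],
      ref = f[4], alt = f[5],
      quality = if (f[6] == ".") NA_real_ else as.numeric(f[6]),
      mean_coverage = as_num_or_na(info[[coverage_field]]),
      gene = if (is.null(info[[gene_field]])) NA_character_ else info[[gene_field]],
      function_class = if (is.null(info[[class_field]])) NA_character_ else info[[class_field]],
      stringsAsFactors = FALSE)
  }
  v <- do.call(rbind, variants)
  v$variant <- with(v, paste(chrom, pos, ref, alt, sep = ":"))
  colnames(dos) <- v$variant
  genotype_matrix(dos, v)
}

parse_info <- function(s) {
  if (s == ".") return(list())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(x) if (length(x) > 1) x[2] else TRUE),
                  vapply(kv, `[`, character(1), 1))
}

as_num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)

gt_to_dosage <- function(gts) {
  gt <- gsub("|", "/", gts, fixed = TRUE)
  out <- rep(NA_real_, length(gt))
  out[gt == "0/0"] <- 0
  out[gt %in% c("0/1", "1/0")] <- 1
  out[gt == "1/1"] <- 2
  out
}

#' Write genotypes to a VCF file
#'
#' Emits VCF v4.2 with QUAL, INFO DP/GENE/FUNC and per-sample GT;
#' `read_vcf(write_vcf(x))` restores dosages and annotations, and
#' rewriting the result reproduces the file byte-for-byte.
#'
#' @param geno `famvar_genotypes`.
#' @param path output path.
#' @export
write_vcf <- function(geno, path) {
  v <- geno$variants
  dos <- geno$dosage
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Float,Description=\"Mean fold coverage\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=FUNC,Number=1,Type=String,Description=\"Functional class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dos)), collapse = "\t"))
  gt <- matrix(c("0/0", "0/1", "1/1")[dos + 1], nrow(dos))
  gt[is.na(gt)] <- "./."
  info <- sprintf("DP=%s;GENE=%s;FUNC=%s",
                  format_num(v$mean_coverage), v$gene, v$function_class)
  body <- paste(v$chrom, v$pos,
                ifelse(is.na(v$rsid) | v$rsid == "", ".", v$rsid),
                v$ref, v$alt, format_num(v$quality), "PASS", info, "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

format_num <- function(x) {
  ifelse(is.na(x), ".", sub("\\.?0+$", "", sprintf("%.6f", x)))
}

#' Tab-delimited table IO with NA token
#'
#' Header row, tab separator, `"NA"` missing token. The reader optionally
#' enforces a unique key column.
#'
#' @param path file path.
#' @param key column that must be unique (e.g. `"id"` for a phenotype
#'   table), or NULL.
#' @export
read_tsv_table <- function(path, key = NULL) {
  df <- utils::read.delim(path, na.strings = "NA", stringsAsFactors = FALSE)
  if (!is.null(key)) {
    if (!key %in% names(df)) stop("missing key column '", key, "'")
    if (anyDuplicated(df[[key]])) {
      stop("duplicate ", key, ": ",
           paste(unique(df[[key]][duplicated(df[[key]])]), collapse = ", "))
    }
  }
  df
}

#' @param df data frame to write.
#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Run the full pipeline on a dataset
#'
#' Orchestrates the analysis stages in study order: variant QC (single and
#' burden modes, with per-filter accounting), phenotype derivation
#' (composite index, derived lipids/pressures, inverse-normal transform,
#' covariate residualization), survival exceptionality scoring,
#' single-variant kinship-LMM association, and the gene-level rare-variant
#' scan. Writes every stage output as TSV plus a JSON manifest with MD5
#' checksums; a rerun with the same inputs and seed is
#' checksum-identical.
#'
#' @param data dataset as produced by [sim_dataset()] (or an equivalent
#'   list with `ped`, `geno`, `phen`, `lifetable`, `genes`).
#' @param out_dir output directory (created if needed).
#' @param tests gene-level tests to run.
#' @param n_perm permutations for the adaptive permutation test.
#' @param seed seed for the permutation stage.
#' @return invisibly, a list with the stage results and the manifest.
#' @export
pipeline_run <- function(data, out_dir, tests = c("famskat", "pwst"),
                         n_perm = 200L, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(data$lifetable)) stop("config error: life table required for survival scoring")
  ws <- withr_seed(seed)
  on.exit(ws(), add = TRUE)
  ped <- data$ped
  K <- 2 * kinship(ped)

  # --- stage 1: QC -------------------------------------------------------
  geno <- variant_qc_annotate(data$geno, ped)
  qc_single <- apply_filters(geno, filter_config("single"))
  qc_burden <- apply_filters(geno, filter_config("burden"))
  counts <- list(
    input = ncol(geno$dosage),
    single_retained = ncol(qc_single$retained$dosage),
    burden_retained = ncol(qc_burden$retained$dosage),
    by_filter_single = as.list(table(qc_single$log$filter)),
    by_filter_burden = as.list(table(qc_burden$log$filter)))
  write_tsv_table(qc_single$log, file.path(out_dir, "qc_single_removals.tsv"))
  write_tsv_table(qc_burden$log, file.path(out_dir, "qc_burden_removals.tsv"))
  write_tsv_table(qc_single$retained$variants,
                  file.path(out_dir, "variants_single.tsv"))

  # --- stage 2: phenotype derivation ------------------------------------
  raw <- data$phen$raw
  derived <- data.frame(
    id = raw$id,
    bmi = bmi(raw$weight, raw$height),
    pulse_pressure = pulse_pressure(raw$sbp, raw$dbp),
    ldl = friedewald_ldl(raw$total_chol, raw$hdl, raw$trig),
    telomere_bp = telomere_bp(raw$ts_ratio),
    t2d = t2d_status(raw$diabetes_meds, raw$fasting_glucose))
  comp <- data.frame(sbp = raw$sbp, fvc = raw$fvc, mmse = raw$mmse,
                     creatinine = raw$creatinine,
                     glucose = raw$fasting_glucose)
  cp <- hai_cutpoints(comp, age = raw$age, sex = raw$sex)
  hs <- hai_score(comp, cp, age = raw$age, sex = raw$sex)
  derived$hai <- hs$hai
  derived$mwhai <- mortality_weighted_hai(hs$scores)
  write_tsv_table(derived, file.path(out_dir, "phenotypes_derived.tsv"))

  # --- stage 3: exceptionality ------------------------------------------
  older <- raw$generation <= 1
  cohort <- data$lifetable$birth_year_cohort[1]
  surv_score <- rep(NA_real_, nrow(raw))
  surv_score[older] <- survival_exceptionality(
    raw$age[older], raw$sex[older], cohort, data$lifetable)
  scores <- data.frame(id = raw$id, survival_score = surv_score)
  scores$survival_resid <- NA_real_
  scores$survival_resid[older] <- residualize_scores(
    surv_score[older],
    data.frame(center = factor(raw$field_center[older])))
  write_tsv_table(scores, file.path(out_dir, "exceptionality.tsv"))

  # --- stage 4: single-variant association ------------------------------
  y <- data$phen$y
  Kk <- K[names(y), names(y)]
  attr(Kk, "family") <- attr(K, "family")[names(y)]
  single <- assoc_single(qc_single$retained, y, K = Kk, min_mac = 1L)
  ann_cols <- intersect(c("variant", "chrom", "pos", "rsid", "gene",
                          "function_class", "ref", "alt"),
                        names(qc_single$retained$variants))
  single <- merge(qc_single$retained$variants[, ann_cols], single,
                  by = "variant", sort = FALSE)
  single$bonferroni <- bonferroni_threshold(sum(!is.na(single$p)))
  lam <- genomic_control(single$p)
  part <- mac_partition(single)
  write_tsv_table(single, file.path(out_dir, "assoc_single.tsv"))

  # --- stage 5: gene-level tests ----------------------------------------
  burden <- gene_scan(data$genes, qc_burden$retained, y, K = Kk,
                      tests = tests, n_perm = n_perm, seed = seed)
  write_tsv_table(burden, file.path(out_dir, "assoc_burden.tsv"))

  files <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    seed = seed,
    counts = counts,
    genomic_control_lambda = lam,
    n_stable = nrow(part$stable), n_unstable = nrow(part$unstable),
    gene_thresholds = list(significant = attr(burden, "significant"),
                           suggestive = attr(burden, "suggestive")),
    files = stats::setNames(as.list(unname(tools::md5sum(files))),
                            basename(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(qc_single = qc_single, qc_burden = qc_burden,
                 derived = derived, scores = scores, single = single,
                 burden = burden, manifest = manifest))
}
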