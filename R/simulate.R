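#' Simulate three-generation study pedigrees
#'
#' Each family mirrors the recruitment design: a long-lived sibship
#' (generation 1, the probands), their married-in spouses (unrelated
#' founders, the study controls), their offspring (generation 2), and the
#' sibship's parents recorded in generation 0 so sib-sharing is encoded.
#' The grandparent generation is typically deceased and can be excluded
#' from genotyping (see `genotyped_ids` attribute) while remaining in the
#' pedigree.
#'
#' @param n_families number of families.
#' @param mean_sibs sibship size is 2 + Poisson(mean_sibs - 2) (>= 2).
#' @param mean_offspring offspring per sib is 1 + Poisson(mean_offspring
#'   - 1) (>= 1).
#' @param spouses include married-in spouses (required for offspring).
#' @param genotype_parents are generation-0 parents genotyped?
#' @return `famvar_pedigree` with attribute `genotyped` (ids of
#'   individuals available for sequencing).
#' @export
sim_pedigree <- function(n_families = 50, mean_sibs = 3,
                         mean_offspring = 2, spouses = TRUE,
                         genotype_parents = FALSE) {
  rows <- list()
  genotyped <- character()
  for (f in seq_len(n_families)) {
    fam <- sprintf("F%03d", f)
    pid <- function(i) sprintf("%s_I%02d", fam, i)
    k <- 0L
    nxt <- function() { k <<- k + 1L; pid(k) }
    dad <- nxt(); mom <- nxt()
    rows[[length(rows) + 1L]] <- data.frame(
      family = fam, id = c(dad, mom), father = NA, mother = NA,
      sex = c("male", "female"))
    if (genotype_parents) genotyped <- c(genotyped, dad, mom)
    n_sibs <- 2L + stats::rpois(1, max(mean_sibs - 2, 0))
    for (s in seq_len(n_sibs)) {
      sib <- nxt()
      sib_sex <- sample(c("male", "female"), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam, id = sib, father = dad, mother = mom, sex = sib_sex)
      genotyped <- c(genotyped, sib)
      if (spouses) {
        sp <- nxt()
        sp_sex <- if (sib_sex == "male") "female" else "male"
        rows[[length(rows) + 1L]] <- data.frame(
          family = fam, id = sp, father = NA, mother = NA, sex = sp_sex)
        genotyped <- c(genotyped, sp)
        n_off <- 1L + stats::rpois(1, max(mean_offspring - 1, 0))
        for (o in seq_len(n_off)) {
          kid <- nxt()
          rows[[length(rows) + 1L]] <- data.frame(
            family = fam, id = kid,
            father = if (sib_sex == "male") sib else sp,
            mother = if (sib_sex == "male") sp else sib,
            sex = sample(c("male", "female"), 1))
          genotyped <- c(genotyped, kid)
        }
      }
    }
  }
  ped <- as_pedigree(do.call(rbind, rows))
  attr(ped, "genotyped") <- genotyped
  ped
}

#' Simulate candidate-gene genotypes by gene dropping
#'
#' Founder genotypes are drawn from a configured site-frequency spectrum
#' (a point mass of pedigree-private singletons, a Beta tail of rare
#' variants and a slice of common ones); descendants receive one allele
#' from each parent with probability 1/2 per parental allele. Sites are
#' unlinked (no LD).
#'
#' @param ped pedigree from [sim_pedigree()].
#' @param n_genes number of genes.
#' @param mean_variants_per_gene variants per gene is 2 +
#'   Poisson(mean - 2).
#' @param p_private probability a variant is pedigree-private (one founder
#'   heterozygote).
#' @param p_common probability a variant is common, MAF ~ U(0.01, 0.3);
#'   the remainder are rare with MAF ~ 0.0005 + 0.0095 * Beta(1, 3).
#' @return `famvar_genotypes` over the genotyped individuals, annotated
#'   with gene, function class, and simulated coverage/quality; the
#'   attribute `truth` records founder frequencies and classes.
#' @export
sim_genotypes <- function(ped, n_genes = 100, mean_variants_per_gene = 12,
                          p_private = 0.55, p_common = 0.10) {
  n_var_per_gene <- 2L + stats::rpois(n_genes, max(mean_variants_per_gene - 2, 0))
  m <- sum(n_var_per_gene)
  gene_of <- rep(sprintf("GENE%03d", seq_len(n_genes)), n_var_per_gene)

  kind <- sample(c("private", "rare", "common"), m, replace = TRUE,
                 prob = c(p_private, 1 - p_private - p_common, p_common))
  founder_maf <- ifelse(kind == "common", stats::runif(m, 0.01, 0.3),
                 ifelse(kind == "rare",
                        0.0005 + 0.0095 * stats::rbeta(m, 1, 3), 0))

  n <- nrow(ped)
  ord <- order(ped$generation)
  idx <- stats::setNames(seq_len(n), ped$id)
  fa <- ifelse(is.na(ped$father), NA_integer_, idx[ped$father])
  mo <- ifelse(is.na(ped$mother), NA_integer_, idx[ped$mother])
  founders <- which(ped$founder)

  # allele pair representation for exact transmission
  a1 <- matrix(0L, n, m); a2 <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    if (kind[j] == "private") {
      carrier <- sample(founders, 1)
      a1[carrier, j] <- 1L
    } else {
      a1[founders, j] <- stats::rbinom(length(founders), 1, founder_maf[j])
      a2[founders, j] <- stats::rbinom(length(founders), 1, founder_maf[j])
    }
  }
  for (i in ord) {
    if (ped$founder[i]) next
    pick1 <- stats::runif(m) < 0.5
    pick2 <- stats::runif(m) < 0.5
    fal <- ifelse(pick1, a1[fa[i], ], a2[fa[i], ])
    mal <- ifelse(pick2, a1[mo[i], ], a2[mo[i], ])
    a1[i, ] <- fal
    a2[i, ] <- mal
  }
  dos <- a1 + a2
  rownames(dos) <- ped$id

  gt_ids <- attr(ped, "genotyped")
  if (is.null(gt_ids)) gt_ids <- ped$id
  dos <- dos[gt_ids, , drop = FALSE]
  storage.mode(dos) <- "double"

  classes <- c("nsyn-exonic", "stopgain", "stoploss", "syn-exonic",
               "UTR3", "UTR5", "splicing", "ncRNA", "intronic", "intergenic")
  probs <- c(0.21, 0.012, 0.004, 0.148, 0.30, 0.206, 0.02, 0.03, 0.07, 0.01)
  fclass <- sample(classes, m, replace = TRUE, prob = probs)
  chrom <- as.character(1L + (match(gene_of, unique(gene_of)) - 1L) %% 22L)
  pos <- 10000L + seq_len(m) * 100L
  variants <- data.frame(
    chrom = chrom, pos = pos,
    ref = sample(c("A", "C", "G", "T"), m, replace = TRUE),
    alt = NA_character_, rsid = NA_character_, gene = gene_of,
    function_class = fclass,
    mean_coverage = round(pmax(stats::rnorm(m, 47, 20), 6), 1),
    quality = round(pmax(stats::rnorm(m, 175, 40), 50)),
    stringsAsFactors = FALSE)
  variants$alt <- vapply(variants$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  variants$variant <- with(variants, paste(chrom, pos, ref, alt, sep = ":"))
  colnames(dos) <- variants$variant
  geno <- genotype_matrix(dos, variants)
  attr(geno, "truth") <- list(founder_maf = founder_maf, kind = kind,
                              gene = gene_of)
  geno
}

#' Simulate phenotypes with additive variant effects and a polygenic term
#'
#' Generates the model the kinship LMM assumes: y = G beta + u + e with
#' u ~ N(0, 2*phi*sigma2_g) drawn through per-family Cholesky factors and
#' e ~ N(0, sigma2_e). One gene can be spiked as causal. Also emits a raw
#' phenotype table (ages, HAI components, lipids, pressures, T/S ratio,
#' onset ages, field center) for the derivation and exceptionality stages.
#'
#' @param ped pedigree.
#' @param geno `famvar_genotypes` over the analysis individuals.
#' @param causal_gene gene symbol whose variants receive effects, or NULL.
#' @param effect_size per-allele effect for causal variants (phenotype
#'   SD units).
#' @param causal_fraction fraction of the causal gene's variants that are
#'   causal.
#' @param h2 narrow-sense polygenic heritability of the residual
#'   (non-variant) variance.
#' @param total_var total residual variance (polygenic + noise).
#' @param K optional pre-computed relationship matrix 2*phi.
#' @return list with `y` (named analysis phenotype), `raw` (raw phenotype
#'   data frame), `truth` (causal variants, effects, polygenic values).
#' @export
sim_phenotypes <- function(ped, geno, causal_gene = NULL, effect_size = 0.5,
                           causal_fraction = 1, h2 = 0.3, total_var = 1,
                           K = NULL) {
  ids <- rownames(geno$dosage)
  if (is.null(K)) K <- 2 * kinship(ped)
  Ksub <- K[ids, ids, drop = FALSE]
  fam <- attr(K, "family")[ids]
  s2g <- h2 * total_var
  s2e <- (1 - h2) * total_var
  u <- stats::setNames(numeric(length(ids)), ids)
  if (s2g > 0) {
    for (f in unique(fam)) {
      i <- which(fam == f)
      L <- chol(Ksub[i, i, drop = FALSE] + diag(1e-10, length(i)))
      u[i] <- drop(crossprod(L, stats::rnorm(length(i)))) * sqrt(s2g)
    }
  }
  beta <- stats::setNames(numeric(ncol(geno$dosage)), colnames(geno$dosage))
  if (!is.null(causal_gene)) {
    v <- geno$variants
    cand <- which(v$gene == causal_gene)
    # the causal burden lives on the gene's rare functional variants
    functional <- v$function_class %in% c("nsyn-exonic", "syn-exonic",
                                          "stopgain", "stoploss", "UTR3",
                                          "UTR5", "splicing", "ncRNA")
    truth_kind <- attr(geno, "truth")$kind
    rare <- if (!is.null(truth_kind)) truth_kind != "common" else rep(TRUE, nrow(v))
    pick <- cand[functional[cand] & rare[cand]]
    if (!length(pick)) pick <- cand
    ncausal <- max(1L, round(length(pick) * causal_fraction))
    causal <- sample(pick, ncausal)
    beta[causal] <- effect_size
  }
  Gd <- geno$dosage
  Gd[is.na(Gd)] <- 0
  gpart <- drop(Gd %*% beta)
  y <- gpart + u + stats::rnorm(length(ids), 0, sqrt(s2e))
  names(y) <- ids

  sex <- ped$sex[match(ids, ped$id)]
  gen <- ped$generation[match(ids, ped$id)]
  age <- ifelse(gen <= 1, stats::rnorm(length(ids), 90, 6),
                stats::rnorm(length(ids), 60, 8))
  age <- pmax(age, 41)
  raw <- data.frame(
    id = ids, sex = sex, generation = gen,
    age = round(age, 1), birth_year = 2006 - round(age),
    field_center = sample(paste0("C", 1:4), length(ids), replace = TRUE),
    weight = round(stats::rnorm(length(ids), 75, 12), 1),
    height = round(stats::rnorm(length(ids), 1.68, 0.09), 2),
    sbp = round(stats::rnorm(length(ids), 130, 18)),
    dbp = round(stats::rnorm(length(ids), 75, 10)),
    fvc = round(stats::rnorm(length(ids), 3.2, 0.7), 2),
    creatinine = round(stats::rnorm(length(ids), 0.95, 0.2), 2),
    fasting_glucose = round(stats::rnorm(length(ids), 98, 14)),
    mmse = pmin(round(stats::rnorm(length(ids), 27, 2.2)), 30),
    total_chol = round(stats::rnorm(length(ids), 195, 32)),
    hdl = round(stats::rnorm(length(ids), 55, 13)),
    trig = round(stats::rlnorm(length(ids), log(110), 0.45)),
    diabetes_meds = stats::runif(length(ids)) < 0.08,
    ts_ratio = round(stats::rnorm(length(ids), 1.0, 0.22), 3),
    stringsAsFactors = FALSE)
  raw$dbp <- pmin(raw$dbp, raw$sbp - 10)
  raw$t2d_onset <- ifelse(stats::runif(length(ids)) < 0.12,
                          round(pmin(age - 2, stats::rnorm(length(ids), 62, 9))),
                          NA_real_)
  list(y = y, raw = raw,
       truth = list(beta = beta, causal = names(beta)[beta != 0],
                    polygenic = u, sigma2_g = s2g, sigma2_e = s2e))
}

#' Gompertz cohort life table
#'
#' Survival S(t) = exp(-(a/b) (exp(b t) - 1)) per sex on an age grid;
#' default parameters give modal ages at death near 81 (men) and 86
#' (women).
#'
#' @param a named baseline hazards per sex.
#' @param b named Gompertz slopes per sex (hazard doubling time
#'   log(2)/b).
#' @param ages age grid in years.
#' @param cohort birth-year cohort label.
#' @return `famvar_lifetable`.
#' @export
sim_lifetable <- function(a = c(male = 6e-5, female = 4e-5),
                          b = c(male = 0.09, female = 0.09),
                          ages = 0:110, cohort = 1915L) {
  rows <- lapply(names(a), function(s) {
    data.frame(sex = s, birth_year_cohort = cohort, age = ages,
               survival = exp(-(a[[s]] / b[[s]]) * (exp(b[[s]] * ages) - 1)))
  })
  as_lifetable(do.call(rbind, rows))
}

#' Inject QC artifacts into a genotype matrix
#'
#' Degrades a clean genotype matrix the way raw sequencing data is
#' degraded: random genotype missingness, low-coverage / low-quality
#' variants, capture gaps (variants with call rate forced under the
#' threshold), and Mendelian errors created by corrupting the child
#' genotype of randomly chosen trios.
#'
#' @param geno clean `famvar_genotypes`.
#' @param ped pedigree (for choosing trios).
#' @param missing_rate per-genotype missingness probability.
#' @param n_error_variants number of variants receiving injected Mendel
#'   errors.
#' @param families_per_error number of distinct families corrupted per
#'   error variant.
#' @param low_coverage_frac,low_quality_frac,capture_gap_frac fractions of
#'   variants forced to fail the coverage / quality / call-rate filters.
#' @return `famvar_genotypes` with attribute `truth`: the injected error
#'   trios per variant and which variants were degraded by which artifact.
#' @export
inject_artifacts <- function(geno, ped, missing_rate = 0.02,
                             n_error_variants = 5L, families_per_error = 1L,
                             low_coverage_frac = 0.05,
                             low_quality_frac = 0.05,
                             capture_gap_frac = 0.03) {
  dos <- geno$dosage
  v <- geno$variants
  m <- ncol(dos)
  truth <- list(error_trios = list(), low_coverage = character(),
                low_quality = character(), capture_gap = character())

  trios <- ped[!is.na(ped$father) & !is.na(ped$mother), ]
  trios <- trios[trios$id %in% rownames(dos) &
                 trios$father %in% rownames(dos) &
                 trios$mother %in% rownames(dos), ]
  if (n_error_variants > 0 && nrow(trios)) {
    err_vars <- sample(m, min(n_error_variants, m))
    for (j in err_vars) {
      fams <- sample(unique(trios$family),
                     min(families_per_error, length(unique(trios$family))))
      hit <- character()
      for (f in fams) {
        tr <- trios[trios$family == f, ][1, ]
        pf <- dos[tr$father, j]; pm <- dos[tr$mother, j]
        if (is.na(pf) || is.na(pm)) next
        # het x het parents admit any child; force the father homozygous
        if (pf == 1 && pm == 1) { dos[tr$father, j] <- 0; pf <- 0 }
        # impossible child: hom-ref under a hom-alt parent, else hom-alt
        dos[tr$id, j] <- if (pf == 2 || pm == 2) 0 else 2
        hit <- c(hit, tr$id)
      }
      if (length(hit)) {
        truth$error_trios[[v$variant[j]]] <- hit
      }
    }
  }

  if (missing_rate > 0) {
    drop_mask <- matrix(stats::runif(length(dos)) < missing_rate, nrow(dos))
    dos[drop_mask] <- NA
  }
  pool <- seq_len(m)
  pick <- function(frac) {
    k <- round(frac * m)
    if (!k) return(integer())
    s <- sample(pool, min(k, length(pool)))
    pool <<- setdiff(pool, s)
    s
  }
  lc <- pick(low_coverage_frac)
  v$mean_coverage[lc] <- stats::runif(length(lc), 1, 4.9)
  truth$low_coverage <- v$variant[lc]
  lq <- pick(low_quality_frac)
  v$quality[lq] <- stats::runif(length(lq), 10, 44)
  truth$low_quality <- v$variant[lq]
  cg <- pick(capture_gap_frac)
  for (j in cg) {
    gap <- sample(nrow(dos), ceiling(0.55 * nrow(dos)))
    dos[gap, j] <- NA
  }
  truth$capture_gap <- v$variant[cg]

  out <- genotype_matrix(dos, v)
  attr(out, "truth") <- truth
  out
}

#' Simulate a complete study dataset
#'
#' Chains the generators into the full stated world: pedigree, clean
#' gene-dropped genotypes, QC artifacts, phenotypes with one spiked causal
#' gene, a Gompertz life table, and the gene grouping map.
#'
#' @param n_families,n_genes cohort and panel size.
#' @param causal_gene gene receiving causal variants (default the first).
#' @param effect_size,h2 see [sim_phenotypes()].
#' @param seed RNG seed (mandatory for reproducibility).
#' @param artifacts inject QC artifacts into the genotypes.
#' @param ... passed to [sim_genotypes()].
#' @return list: `ped`, `geno` (degraded), `geno_clean`, `phen` (from
#'   [sim_phenotypes()]), `lifetable`, `genes` (gene -> variant ids),
#'   `seed`.
#' @export
sim_dataset <- function(n_families = 50, n_genes = 100,
                        causal_gene = "GENE001", effect_size = 2,
                        h2 = 0.3, seed = 1L, artifacts = TRUE, ...) {
  ws <- withr_seed(seed)
  on.exit(ws(), add = TRUE)
  ped <- sim_pedigree(n_families = n_families)
  geno_clean <- sim_genotypes(ped, n_genes = n_genes, ...)
  phen <- sim_phenotypes(ped, geno_clean, causal_gene = causal_gene,
                         effect_size = effect_size, h2 = h2)
  geno <- if (artifacts) inject_artifacts(geno_clean, ped) else geno_clean
  genes <- split(geno$variants$variant, geno$variants$gene)
  list(ped = ped, geno = geno, geno_clean = geno_clean, phen = phen,
       lifetable = sim_lifetable(), genes = genes, seed = seed)
}
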