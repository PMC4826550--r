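test_that("simulated pedigrees have the three-generation study structure", {
  set.seed(41)
  ped <- sim_pedigree(n_families = 10)
  expect_s3_class(ped, "famvar_pedigree")   # construction implies invariants
  sizes <- table(ped$family)
  expect_true(all(sizes >= 3))
  phi <- kinship(ped)
  f1 <- ped[ped$family == "F001", ]
  sibs <- f1$id[!f1$founder & f1$generation == 1]
  # married-in spouses: founders who are not parents of the sibship
  married_in <- f1$id[f1$founder &
                        !(f1$id %in% c(ped$father[ped$generation == 1],
                                       ped$mother[ped$generation == 1]))]
  for (sp in married_in) expect_true(all(phi[sp, sibs] == 0))
  # grandparents (parents of the sibship) are recorded but not genotyped
  gt <- attr(ped, "genotyped")
  gps <- unique(c(ped$father[ped$generation == 1],
                  ped$mother[ped$generation == 1]))
  expect_false(any(gps %in% gt))
  expect_true(all(sibs %in% gt))
  expect_true(all(married_in %in% gt))
})

test_that("gene dropping transmits parental alleles fairly", {
  set.seed(42)
  ped <- sim_pedigree(n_families = 30)
  geno <- sim_genotypes(ped, n_genes = 40, p_private = 0, p_common = 1)
  dos <- geno$dosage
  # children of het father x hom-ref mother: transmitted dose Bernoulli(1/2)
  trios <- ped[!is.na(ped$father) & !is.na(ped$mother), ]
  trios <- trios[trios$id %in% rownames(dos) & trios$father %in% rownames(dos) &
                   trios$mother %in% rownames(dos), ]
  Fd <- dos[trios$father, , drop = FALSE]
  Md <- dos[trios$mother, , drop = FALSE]
  Cd <- dos[trios$id, , drop = FALSE]
  sel <- Fd == 1 & Md == 0
  transmitted <- Cd[sel]
  expect_true(all(transmitted %in% c(0, 1)))
  n <- length(transmitted)
  expect_gt(n, 500)
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(transmitted) - 0.5), 4 * se)
})

test_that("pedigree-private variants have a single founder carrier", {
  set.seed(43)
  ped <- sim_pedigree(n_families = 12, genotype_parents = TRUE)
  geno <- sim_genotypes(ped, n_genes = 20, p_private = 1, p_common = 0)
  fams <- attr(2 * kinship(ped), "family")[rownames(geno$dosage)]
  for (j in seq_len(ncol(geno$dosage))) {
    carriers <- rownames(geno$dosage)[geno$dosage[, j] > 0]
    if (length(carriers)) {
      expect_equal(length(unique(fams[carriers])), 1)  # family-private
    }
  }
})

test_that("polygenic variance follows the kinship structure", {
  set.seed(44)
  ped <- sim_pedigree(n_families = 150)
  K <- 2 * kinship(ped)
  geno <- sim_genotypes(ped, n_genes = 2)
  # h2 = 0: no polygenic component at all
  ph0 <- sim_phenotypes(ped, geno, h2 = 0, K = K)
  expect_true(all(ph0$truth$polygenic == 0))
  # Haseman-Elston-style moment check: regress centered cross-products on K
  ph <- sim_phenotypes(ped, geno, causal_gene = NULL, h2 = 0.5,
                       total_var = 1, K = K)
  ids <- names(ph$y)
  yc <- ph$y - mean(ph$y)
  Ks <- K[ids, ids]
  fams <- attr(K, "family")[ids]
  xs <- c(); ys <- c()
  for (f in unique(fams)) {
    i <- which(fams == f)
    if (length(i) < 2) next
    pair <- which(upper.tri(Ks[i, i]), arr.ind = TRUE)
    xs <- c(xs, Ks[i, i][pair])
    ys <- c(ys, (yc[i][pair[, 1]] * yc[i][pair[, 2]]))
  }
  s2g_hat <- coef(lm(ys ~ xs))[2]
  expect_lt(abs(s2g_hat - 0.5), 0.2 * 0.5 + 0.1)
})

test_that("Gompertz life tables behave analytically", {
  lt <- sim_lifetable()
  s_m <- lt[lt$sex == "male", ]
  expect_equal(s_m$survival[s_m$age == 0], 1)
  expect_true(all(diff(s_m$survival) <= 0))
  # b -> 0 limit is exponential survival
  lt0 <- sim_lifetable(a = c(male = 0.01, female = 0.01),
                       b = c(male = 1e-8, female = 1e-8))
  s0 <- lt0[lt0$sex == "male", ]
  expect_lt(max(abs(s0$survival - exp(-0.01 * s0$age))), 1e-6)
  # hazard doubling time ln2/b recovered by finite differences
  b <- 0.09
  h <- -diff(log(s_m$survival[s_m$age %in% 60:80])) # hazard per year at 60..79
  slope <- coef(lm(log(h) ~ seq_along(h)))[2]
  expect_equal(unname(slope), b, tolerance = 0.02)
})

test_that("artifact injection is controlled and truthful", {
  set.seed(45)
  ped <- sim_pedigree(n_families = 10)
  geno <- sim_genotypes(ped, n_genes = 10)
  clean <- inject_artifacts(geno, ped, missing_rate = 0,
                            n_error_variants = 0, low_coverage_frac = 0,
                            low_quality_frac = 0, capture_gap_frac = 0)
  expect_equal(clean$dosage, geno$dosage)
  expect_equal(clean$variants, geno$variants)

  half <- inject_artifacts(geno, ped, missing_rate = 0.5,
                           n_error_variants = 0, low_coverage_frac = 0,
                           low_quality_frac = 0, capture_gap_frac = 0)
  cr <- colMeans(!is.na(half$dosage))
  expect_lt(abs(mean(cr) - 0.5), 0.03)

  bad <- inject_artifacts(geno, ped, n_error_variants = 3,
                          families_per_error = 2)
  truth <- attr(bad, "truth")
  counts <- mendel_family_counts(find_mendel_errors(bad, ped))
  for (v in names(truth$error_trios)) {
    # missingness can hide an injected trio, never invent one
    expect_lte(counts[[v]], 2)
  }
})

test_that("the default dataset reproduces the qualitative variant spectrum", {
  set.seed(46)
  ped <- sim_pedigree(n_families = 50)
  geno <- variant_qc_annotate(sim_genotypes(ped, n_genes = 100))
  seen <- geno$variants$mac > 0
  cf <- class_fractions(geno$variants[seen, ])
  expect_gt(cf$rare, 0.75)                  # most variants rare
  expect_gt(cf$singleton_among_rare, 0.1)   # singletons present
  expect_gt(cf$coding, 0.25)
  expect_gt(cf$utr, 0.35)
  # majority of observed variants are private to a single family
  fams <- ped$family[match(rownames(geno$dosage), ped$id)]
  n_fam <- vapply(which(seen), function(j) {
    length(unique(fams[geno$dosage[, j] > 0 & !is.na(geno$dosage[, j])]))
  }, integer(1))
  expect_gt(mean(n_fam == 1), 0.5)
})

test_that("simulation is deterministic given the seed", {
  d1 <- sim_dataset(n_families = 5, n_genes = 5, seed = 123)
  d2 <- sim_dataset(n_families = 5, n_genes = 5, seed = 123)
  expect_identical(d1$geno$dosage, d2$geno$dosage)
  expect_identical(d1$phen$y, d2$phen$y)
  expect_identical(d1$phen$raw, d2$phen$raw)
  d3 <- sim_dataset(n_families = 5, n_genes = 5, seed = 124)
  expect_false(identical(d1$phen$y, d3$phen$y))
})
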