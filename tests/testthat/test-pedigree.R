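test_that("kinship reproduces textbook coefficients", {
  phi <- kinship(ped_cousins())
  expect_equal(phi["gp", "gp"], 0.5)          # non-inbred founder diagonal
  expect_equal(phi["gp", "gm"], 0)            # unrelated founders
  expect_equal(phi["a", "ca"], 0.25)          # parent-offspring
  expect_equal(phi["a", "b"], 0.25)           # full sibs
  expect_equal(phi["ca", "cb"], 0.0625)       # first cousins
  expect_equal(kinship(ped_half_sibs())["h1", "h2"], 0.125)

  inb <- kinship(ped_inbred())
  expect_equal(inb["z", "z"], 0.5 * (1 + 0.0625))  # child of first cousins
})

test_that("kinship is zero across families and for married-in spouses", {
  ped <- ped_three_gen()
  phi <- kinship(ped)
  blood <- c("gp", "gm", "s1", "s2", "s3")
  expect_true(all(phi["w1", blood] == 0))
  expect_true(all(phi["w2", blood] == 0))
  expect_equal(phi["w1", "g1"], 0.25)  # spouse is still parent of offspring

  # adding an unrelated married-in spouse leaves existing entries unchanged
  df <- as.data.frame(ped)[, c("family", "id", "father", "mother", "sex")]
  df2 <- rbind(df, data.frame(family = "F1", id = "w3", father = NA,
                              mother = NA, sex = "female"))
  phi2 <- kinship(as_pedigree(df2))
  expect_equal(phi2[rownames(phi), colnames(phi)], phi, ignore_attr = TRUE)
  expect_true(all(phi2["w3", rownames(phi)] == 0))

  set.seed(11)
  two_fam <- sim_pedigree(n_families = 2)
  k2 <- kinship(two_fam)
  f1 <- two_fam$id[two_fam$family == "F001"]
  f2 <- two_fam$id[two_fam$family == "F002"]
  expect_true(all(k2[f1, f2] == 0))
})

test_that("2*phi of simulated pedigrees is positive semidefinite", {
  set.seed(42)
  for (rep in 1:3) {
    ped <- sim_pedigree(n_families = 5)
    ev <- eigen(2 * kinship(ped), symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
})

test_that("kinship agrees with gene-dropping Monte Carlo IBD on small pedigrees", {
  set.seed(7)
  for (ped in canonical_pedigrees()[c("cousins", "inbred")]) {
    exact <- kinship(ped)
    mc <- gene_drop_kinship(ped, n_drops = 3e4)
    tol <- pmax(3 * mc$se, 1e-12)
    expect_true(all(abs(exact - mc$phi) <= tol))
  }
})

test_that("pedigree validation catches structural errors", {
  expect_error(as_pedigree(data.frame(
    family = "F1", id = c("a", "b"), father = c("b", "a"),
    mother = c(NA, NA), sex = c(1, 1))), "cycle")
  expect_error(as_pedigree(data.frame(
    family = "F1", id = "a", father = "ghost", mother = NA, sex = 1)),
    "unknown father")
  expect_error(as_pedigree(data.frame(
    family = "F1", id = c("a", "a"), father = NA, mother = NA,
    sex = c(1, 1))), "duplicate")
  expect_error(as_pedigree(data.frame(
    family = c("F1", "F2", "F2"), id = c("p", "q", "c"),
    father = c(NA, NA, "p"), mother = c(NA, NA, "q"),
    sex = c(1, 2, 1))), "crosses families")
})

test_that("generation numbering and founder flags derive correctly", {
  ped <- ped_three_gen()
  expect_equal(ped$generation[ped$id == "gp"], 0L)
  expect_equal(ped$generation[ped$id == "s1"], 1L)
  expect_equal(ped$generation[ped$id == "w1"], 0L)   # married-in founder
  expect_equal(ped$generation[ped$id == "g1"], 2L)
  expect_true(all(ped$founder == (is.na(ped$father) & is.na(ped$mother))))
})

test_that("Mendel errors are flagged exactly per the trio rules", {
  ped <- as_pedigree(data.frame(
    family = "F1", id = c("f", "m", "c"),
    father = c(NA, NA, "f"), mother = c(NA, NA, "m"), sex = c(1, 2, 1)))
  make <- function(f, m, c) {
    dos <- matrix(c(f, m, c), 3, 1, dimnames = list(c("f", "m", "c"), "v1"))
    v <- data.frame(variant = "v1")
    nrow(find_mendel_errors(genotype_matrix(dos, v), ped))
  }
  expect_equal(make(0, 0, 1), 1)   # impossible transmission
  expect_equal(make(0, 2, 1), 0)   # forced heterozygote
  expect_equal(make(0, NA, 2), 0)  # missing member: skipped
  expect_equal(make(2, 2, 1), 1)
  expect_equal(make(2, 1, 0), 1)
  expect_equal(make(1, 1, 2), 0)   # het x het admits anything
})

test_that("unknown genotyped individuals are rejected", {
  ped <- ped_nuclear()
  dos <- matrix(0, 2, 1, dimnames = list(c("c1", "stranger"), "v1"))
  g <- genotype_matrix(dos, data.frame(variant = "v1"))
  expect_error(find_mendel_errors(g, ped), "absent from pedigree")
})

test_that("family counts are distinct per variant and zero when clean", {
  rep <- structure(
    data.frame(variant = c("v1", "v1", "v1"),
               child = c("c1", "c2", "c3"),
               father = "f", mother = "m",
               family = c("F1", "F1", "F3")),
    variants = c("v1", "v2"), class = c("famvar_mendel_report", "data.frame"))
  counts <- mendel_family_counts(rep)
  expect_equal(unname(counts["v1"]), 2L)
  expect_equal(unname(counts["v2"]), 0L)
})

test_that("gene-dropped genotypes are Mendel-clean until errors are injected", {
  set.seed(101)
  ped <- sim_pedigree(n_families = 8)
  geno <- sim_genotypes(ped, n_genes = 10)
  expect_equal(nrow(find_mendel_errors(geno, ped)), 0)

  bad <- inject_artifacts(geno, ped, missing_rate = 0,
                          n_error_variants = 4, families_per_error = 2,
                          low_coverage_frac = 0, low_quality_frac = 0,
                          capture_gap_frac = 0)
  truth <- attr(bad, "truth")$error_trios
  rep <- find_mendel_errors(bad, ped)
  counts <- mendel_family_counts(rep)
  for (v in names(truth)) {
    expect_gte(counts[[v]], length(truth[[v]]))
    expect_true(all(truth[[v]] %in% rep$child[rep$variant == v]))
  }
})

test_that("PED and kinship files round-trip", {
  ped <- ped_three_gen()
  f <- withr::local_tempfile(fileext = ".ped")
  write_ped(ped, f)
  back <- read_ped(f)
  expect_equal(as.data.frame(back), as.data.frame(ped))

  phi <- kinship(ped)
  k <- withr::local_tempfile(fileext = ".tsv")
  write_kinship(phi, k)
  phi2 <- read_kinship(k)
  expect_equal(phi2, phi, ignore_attr = TRUE)
})
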