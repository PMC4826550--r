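identityK <- function(n) {
  K <- diag(n)
  dimnames(K) <- list(paste0("i", 1:n), paste0("i", 1:n))
  attr(K, "family") <- stats::setNames(paste0("i", 1:n), paste0("i", 1:n))
  K
}

test_that("UWSS is the per-individual allele count with MAF imputation", {
  G <- rbind(c(0, 1, 2, 0), c(0, 0, 0, 0))
  expect_equal(unname(uwss(G)), c(3, 0))
  Gm <- rbind(c(0, NA, 1))
  expect_equal(unname(uwss(Gm, maf = c(0.1, 0.005, 0.2))), 1 + 2 * 0.005)
})

test_that("WSS weights follow the control-frequency formula", {
  G <- matrix(c(0, 1, 2), 3, 1)
  s <- wss(G, q = 0.5, n_controls = 100)
  expect_equal(attr(s, "weights"), 1 / sqrt(25))       # = 0.2
  expect_equal(as.numeric(s), c(0, 0.2, 0.4))
  # weights strictly decreasing in q on (0, 0.5)
  qs <- seq(0.01, 0.49, by = 0.01)
  ws <- 1 / sqrt(100 * qs * (1 - qs))
  expect_true(all(diff(ws) < 0))
  # zero genotypes give zero scores regardless of weights
  expect_equal(as.numeric(wss(matrix(0, 4, 2), q = c(0.1, 0.2),
                              n_controls = 50)), rep(0, 4))
  expect_error(wss(G, control_G = G[0, , drop = FALSE]), "use_all")
  # control-frequency smoothing: m alt alleles among n controls
  ctrl <- matrix(c(0, 1, 0, 0), 4, 1)
  s2 <- wss(G, control_G = ctrl)
  q_expect <- (1 + 1) / (2 * 4 + 2)
  expect_equal(attr(s2, "weights"), 1 / sqrt(4 * q_expect * (1 - q_expect)))
})

test_that("UWSS equals WSS under unit weights", {
  set.seed(31)
  G <- matrix(rbinom(60, 2, 0.1), 20, 3)
  manual <- drop(G %*% rep(1, 3))
  expect_equal(unname(uwss(G)), manual)
})

test_that("burden score in the LMM matches OLS for unrelated individuals", {
  set.seed(32)
  n <- 150
  G <- matrix(rbinom(n * 4, 2, 0.05), n, 4)
  s <- uwss(G)
  y <- 0.3 * s + rnorm(n)
  fit <- burden_lm(s, y, K = identityK(n))
  ols <- summary(lm(y ~ s))$coefficients
  expect_lt(abs(fit$beta - ols["s", 1]) / abs(ols["s", 1]), 1e-6)
  # ML variance scaling: OLS standard error rescaled by sqrt((n - p) / n)
  expect_lt(abs(fit$se - ols["s", 2] * sqrt((n - 2) / n)) / ols["s", 2], 1e-6)
  expect_error(burden_lm(rep(2, n), y, K = identityK(n)), "monomorphic")
})

test_that("chi-square mixture tail probabilities are exact", {
  # single eigenvalue: matches pchisq exactly
  expect_equal(pchisqsum(3.84, 1)$p, pchisq(3.84, 1, lower.tail = FALSE),
               tolerance = 1e-8)
  expect_equal(pchisqsum(7, 3.5)$p, pchisq(2, 1, lower.tail = FALSE),
               tolerance = 1e-8)
  # equal eigenvalues: sum of k chi2_1 = chi2_k
  expect_equal(pchisqsum(10, rep(1, 4))$p,
               pchisq(10, 4, lower.tail = FALSE), tolerance = 1e-8)
  # Monte Carlo cross-check for unequal weights
  set.seed(33)
  lam <- c(3, 1.5, 0.5, 0.1)
  draws <- colSums(lam * matrix(rchisq(4 * 2e5, 1), 4))
  q <- quantile(draws, 0.95)
  expect_equal(pchisqsum(q, lam)$p, 0.05, tolerance = 0.01)
  # far tail falls back without returning nonsense
  pt <- pchisqsum(500, lam)
  expect_gt(pt$p, 0)
  expect_lt(pt$p, 1e-20)
})

test_that("famSKAT equals a from-scratch SKAT oracle under independence", {
  set.seed(34)
  n <- 120
  for (rep in 1:5) {
    G <- matrix(rbinom(n * 6, 2, runif(6, 0.02, 0.1)), n, 6, byrow = TRUE)
    G <- G[, apply(G, 2, var) > 0, drop = FALSE]
    x1 <- rnorm(n)
    y <- 0.2 * x1 + rnorm(n)
    X <- cbind(1, x1)
    maf <- colMeans(G) / 2
    w <- dbeta(pmin(maf, 1 - maf), 1, 25)
    fam <- famskat(y, X, G, K = identityK(n), weights = "beta")
    ora <- skat_oracle(y, X, G, w)
    expect_equal(fam$p, ora$p, tolerance = 1e-6)
  }
})

test_that("famSKAT is invariant to variant order and null when r is orthogonal", {
  set.seed(35)
  n <- 100
  G <- matrix(rbinom(n * 5, 2, 0.08), n, 5)
  y <- rnorm(n)
  p1 <- famskat(y, NULL, G, K = identityK(n))$p
  p2 <- famskat(y, NULL, G[, 5:1], K = identityK(n))$p
  expect_equal(p2, p1, tolerance = 1e-10)

  # make every column orthogonal to the null residuals
  r <- y - mean(y)
  Go <- apply(G, 2, function(col) col - r * sum(r * col) / sum(r^2))
  fs <- famskat(y, NULL, Go, K = identityK(n))
  expect_lt(fs$statistic, 1e-12)
  expect_equal(fs$p, 1)
})

test_that("single-variant famSKAT with flat weights matches the score test", {
  set.seed(36)
  ped <- sim_pedigree(n_families = 20)
  K <- 2 * kinship(ped)
  n <- nrow(K)
  g <- matrix(rbinom(n, 2, 0.1), n, 1)
  y <- drop(0.4 * g) + draw_polygenic(polygenic_chols(K), n, 0.4) +
    rnorm(n, 0, sqrt(0.6))
  null <- fit_lmm(y, NULL, g = NULL, K = K)
  fs <- famskat(y, NULL, g, null_fit = null, weights = "flat")
  # score test of the same quadratic form
  v <- null$sigma2 * null$weights
  gt <- kinship_transform(null$decomp, as.vector(g))
  rt <- drop(null$yt - null$Xt %*% null$coefficients)
  U <- sum(gt * rt / v)
  Xt <- null$Xt
  XtViX_inv <- solve(crossprod(Xt, Xt / v))
  bx <- crossprod(Xt / v, gt)
  varU <- sum(gt^2 / v) - drop(t(bx) %*% XtViX_inv %*% bx)
  p_score <- pchisq(U^2 / varU, 1, lower.tail = FALSE)
  expect_equal(fs$p, p_score, tolerance = 1e-6)
})

test_that("famSKAT detects a burden of causal rare variants", {
  set.seed(37)
  ped <- sim_pedigree(n_families = 40)
  K <- 2 * kinship(ped)
  geno <- sim_genotypes(ped, n_genes = 2, p_private = 0.3, p_common = 0)
  ids <- rownames(geno$dosage)
  Ks <- K[ids, ids]; attr(Ks, "family") <- attr(K, "family")[ids]
  G <- geno$dosage[, geno$variants$gene == "GENE001", drop = FALSE]
  G <- G[, apply(G, 2, var) > 0, drop = FALSE]
  y <- drop(G %*% rep(1, ncol(G))) +
    draw_polygenic(polygenic_chols(Ks, ids), length(ids), 0.3) +
    rnorm(length(ids), 0, sqrt(0.7))
  expect_lt(famskat(y, NULL, G, K = Ks)$p, 0.01)
})

test_that("PWST is seed-reproducible, bounded below, and powered", {
  set.seed(38)
  ped <- sim_pedigree(n_families = 25)
  K <- 2 * kinship(ped)
  geno <- sim_genotypes(ped, n_genes = 1, p_private = 0.3, p_common = 0)
  ids <- rownames(geno$dosage)
  Ks <- K[ids, ids]; attr(Ks, "family") <- attr(K, "family")[ids]
  G <- geno$dosage
  G <- G[, apply(G, 2, var) > 0, drop = FALSE]
  n <- length(ids)
  y_null <- draw_polygenic(polygenic_chols(Ks, ids), n, 0.3) + rnorm(n)
  r1 <- pwst(y_null, NULL, G, K = Ks, n_perm = 150, seed = 99)
  r2 <- pwst(y_null, NULL, G, K = Ks, n_perm = 150, seed = 99)
  expect_identical(r1$p, r2$p)
  expect_identical(r1$statistic, r2$statistic)
  expect_gte(r1$p, 1 / 151)
  expect_error(pwst(y_null, NULL, G, K = Ks, n_perm = 50), "100")

  y_causal <- drop(G %*% rep(1.2, ncol(G))) + y_null
  expect_lt(pwst(y_causal, NULL, G, K = Ks, n_perm = 200, seed = 7)$p,
            pwst(y_null, NULL, G, K = Ks, n_perm = 200, seed = 7)$p)
})

test_that("gene scan tiers results and skips thin genes", {
  set.seed(39)
  ped <- sim_pedigree(n_families = 20)
  K <- 2 * kinship(ped)
  geno <- sim_genotypes(ped, n_genes = 6)
  geno <- variant_qc_annotate(geno, ped)
  ids <- rownames(geno$dosage)
  Ks <- K[ids, ids]; attr(Ks, "family") <- attr(K, "family")[ids]
  y <- stats::setNames(rnorm(length(ids)), ids)
  genes <- split(geno$variants$variant, geno$variants$gene)
  genes[["THIN"]] <- genes[[1]][1]
  res <- gene_scan(genes, geno, y, K = Ks,
                   tests = c("famskat", "uwss", "wss"),
                   control_ids = ids[1:20])
  expect_true(res$skipped[res$gene == "THIN"])
  expect_true(is.na(res$p_famskat[res$gene == "THIN"]))
  expect_equal(attr(res, "significant"), 0.05 / nrow(res))
  done <- !res$skipped
  expect_true(all(res$p_famskat[done] > 0 & res$p_famskat[done] <= 1))
  expect_true(all(res$p_uwss[done] > 0 & res$p_uwss[done] <= 1, na.rm = TRUE))
})
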