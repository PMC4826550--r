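# Shared fixtures and independent oracles used across test files.

# -- canonical pedigrees (all <= 20 members) ---------------------------------

ped_nuclear <- function() {
  as_pedigree(data.frame(
    family = "F1",
    id = c("f", "m", "c1", "c2"),
    father = c(NA, NA, "f", "f"),
    mother = c(NA, NA, "m", "m"),
    sex = c(1, 2, 1, 2)))
}

ped_half_sibs <- function() {
  as_pedigree(data.frame(
    family = "F1",
    id = c("f", "m1", "m2", "h1", "h2"),
    father = c(NA, NA, NA, "f", "f"),
    mother = c(NA, NA, NA, "m1", "m2"),
    sex = c(1, 2, 2, 1, 1)))
}

ped_cousins <- function() {
  as_pedigree(data.frame(
    family = "F1",
    id = c("gp", "gm", "a", "b", "sa", "sb", "ca", "cb"),
    father = c(NA, NA, "gp", "gp", NA, NA, "a", "b"),
    mother = c(NA, NA, "gm", "gm", NA, NA, "sa", "sb"),
    sex = c(1, 2, 1, 1, 2, 2, 1, 1)))
}

ped_three_gen <- function() {
  # grandparents, three sibs, two spouses, three grandchildren
  as_pedigree(data.frame(
    family = "F1",
    id = c("gp", "gm", "s1", "s2", "s3", "w1", "w2", "g1", "g2", "g3"),
    father = c(NA, NA, "gp", "gp", "gp", NA, NA, "s1", "s1", "s2"),
    mother = c(NA, NA, "gm", "gm", "gm", NA, NA, "w1", "w1", "w2"),
    sex = c(1, 2, 1, 1, 2, 2, 2, 1, 2, 1)))
}

ped_inbred <- function() {
  # offspring of first cousins: inbreeding f = 1/16, self-kinship 0.5 + f/2
  as_pedigree(data.frame(
    family = "F1",
    id = c("gp", "gm", "a", "b", "sa", "sb", "ca", "cb", "z"),
    father = c(NA, NA, "gp", "gp", NA, NA, "a", "b", "ca"),
    mother = c(NA, NA, "gm", "gm", NA, NA, "sa", "sb", "cb"),
    sex = c(1, 2, 1, 1, 2, 2, 1, 2, 1)))
}

canonical_pedigrees <- function() {
  list(nuclear = ped_nuclear(), half_sibs = ped_half_sibs(),
       cousins = ped_cousins(), three_gen = ped_three_gen(),
       inbred = ped_inbred())
}

# -- gene-dropping Monte Carlo kinship oracle --------------------------------
# Drops a single locus with globally unique founder alleles n_drops times;
# the kinship of (i, j) is the frequency, over drops and the four allele
# pairings, that a random allele from i is identical by descent to one from
# j. Returns the estimate matrix and its per-pair standard errors.
gene_drop_kinship <- function(ped, n_drops = 1e5) {
  n <- nrow(ped)
  ord <- order(ped$generation)
  idx <- stats::setNames(seq_len(n), ped$id)
  fa <- ifelse(is.na(ped$father), NA_integer_, idx[ped$father])
  mo <- ifelse(is.na(ped$mother), NA_integer_, idx[ped$mother])
  A1 <- matrix(0L, n_drops, n); A2 <- matrix(0L, n_drops, n)
  next_allele <- 0L
  for (i in ord) {
    if (is.na(fa[i]) && is.na(mo[i])) {
      A1[, i] <- next_allele + 1L
      A2[, i] <- next_allele + 2L
      next_allele <- next_allele + 2L
    } else {
      # a missing single parent is an unrelated founder with fresh alleles
      fal1 <- if (is.na(fa[i])) rep(next_allele + 1L, n_drops) else A1[, fa[i]]
      fal2 <- if (is.na(fa[i])) rep(next_allele + 2L, n_drops) else A2[, fa[i]]
      if (is.na(fa[i])) next_allele <- next_allele + 2L
      mal1 <- if (is.na(mo[i])) rep(next_allele + 1L, n_drops) else A1[, mo[i]]
      mal2 <- if (is.na(mo[i])) rep(next_allele + 2L, n_drops) else A2[, mo[i]]
      if (is.na(mo[i])) next_allele <- next_allele + 2L
      p1 <- stats::runif(n_drops) < 0.5
      p2 <- stats::runif(n_drops) < 0.5
      A1[, i] <- ifelse(p1, fal1, fal2)
      A2[, i] <- ifelse(p2, mal1, mal2)
    }
  }
  est <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  se <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      share <- ((A1[, i] == A1[, j]) + (A1[, i] == A2[, j]) +
                  (A2[, i] == A1[, j]) + (A2[, i] == A2[, j])) / 4
      est[i, j] <- est[j, i] <- mean(share)
      se[i, j] <- se[j, i] <- stats::sd(share) / sqrt(n_drops)
    }
  }
  list(phi = est, se = se)
}

# -- from-scratch SKAT oracle for unrelated individuals ----------------------
# Standard (non-family) SKAT: OLS null model, Q = r' G W^2 G' r, null
# distribution sigma2 * eigenvalues of W G' (I - H) G W, with the tail
# probability from Imhof's inversion formula integrated on a transformed
# finite interval. Independent of the package's famskat()/pchisqsum() code.
skat_oracle <- function(y, X, G, weights) {
  fit <- stats::lm.fit(X, y)
  r <- fit$residuals
  p <- ncol(X)
  sigma2 <- sum(r^2) / (length(y) - p)
  GW <- sweep(G, 2, weights, `*`)
  Q <- sum((crossprod(GW, r))^2)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  A <- crossprod(GW, (diag(length(y)) - H) %*% GW)
  lam <- eigen(A, symmetric = TRUE, only.values = TRUE)$values * sigma2
  lam <- lam[lam > 1e-10 * max(lam)]
  list(Q = Q, p = imhof_oracle(Q, lam))
}

# Imhof tail probability on t in (0,1) via u = t/(1-t)
imhof_oracle <- function(q, lam) {
  s <- max(lam)
  lam <- lam / s
  q <- q / s
  if (length(lam) == 1L) return(stats::pchisq(q / lam, 1, lower.tail = FALSE))
  f <- function(t) {
    u <- t / (1 - t)
    theta <- vapply(u, function(ui) 0.5 * sum(atan(lam * ui)), numeric(1)) -
      0.5 * q * u
    rho <- vapply(u, function(ui) prod((1 + lam^2 * ui^2)^0.25), numeric(1))
    (sin(theta) / (u * rho)) / (1 - t)^2
  }
  val <- stats::integrate(f, 0, 1, rel.tol = 1e-10, abs.tol = 1e-12,
                          subdivisions = 10000L, stop.on.error = FALSE)$value
  min(max(0.5 + val / pi, 0), 1)
}

# per-family Cholesky factors of 2*phi for fast repeated polygenic draws
polygenic_chols <- function(K, ids = rownames(K)) {
  fam <- attr(K, "family")[ids]
  lapply(split(seq_along(ids), fam), function(i) {
    list(idx = i, L = chol(K[ids[i], ids[i], drop = FALSE] +
                             diag(1e-10, length(i))))
  })
}

draw_polygenic <- function(chols, n, s2g) {
  u <- numeric(n)
  for (b in chols) {
    u[b$idx] <- drop(crossprod(b$L, stats::rnorm(length(b$idx)))) * sqrt(s2g)
  }
  u
}
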