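#' Unweighted sum score (UWSS)
#'
#' Per-individual total number of rare variant alleles carried across a
#' gene's variant set; missing dosages are imputed to twice the variant's
#' minor allele frequency.
#'
#' @param G individuals x variants dosage matrix (rare, functional,
#'   post-QC).
#' @param maf per-variant minor allele frequencies used for imputation
#'   (default: computed from `G`).
#' @return numeric per-individual score vector.
#' @examples
#' uwss(rbind(c(0, 1, 2, 0)))  # 3
#' @export
uwss <- function(G, maf = NULL) {
  if (is.null(maf)) maf <- colMeans(G, na.rm = TRUE) / 2
  G <- impute_mean(G, maf)
  rowSums(G)
}

impute_mean <- function(G, maf) {
  if (anyNA(G)) {
    fill <- matrix(rep(2 * maf, each = nrow(G)), nrow(G))
    G[is.na(G)] <- fill[is.na(G)]
  }
  G
}

#' Frequency-weighted sum score (WSS)
#'
#' Madsen–Browning-style weighted sum of minor alleles: weights derive
#' from the allele frequency among controls with add-one smoothing,
#' q_j = (m_j + 1) / (2 n_controls + 2), w_j = 1 / sqrt(n_controls *
#' q_j * (1 - q_j)); rarer-in-controls variants get larger weights.
#'
#' @param G individuals x variants dosage matrix.
#' @param control_G dosage matrix of the control individuals (typically
#'   married-in spouses) at the same variants; ignored when `q` given.
#' @param q per-variant control allele frequencies (already smoothed).
#' @param n_controls number of control individuals (required with `q`).
#' @param use_all with no controls available, set TRUE to compute
#'   frequencies from all of `G` instead.
#' @return per-individual score vector with the weights in
#'   `attr(, "weights")`.
#' @export
wss <- function(G, control_G = NULL, q = NULL, n_controls = NULL,
                use_all = FALSE) {
  if (is.null(q)) {
    if (is.null(control_G) || !nrow(control_G)) {
      if (!use_all) {
        stop("no controls: supply control_G, or set use_all = TRUE ",
             "to fall back to all-sample allele frequencies")
      }
      control_G <- G
    }
    n_controls <- nrow(control_G)
    m <- colSums(control_G, na.rm = TRUE)
    q <- (m + 1) / (2 * n_controls + 2)
  }
  stopifnot(!is.null(n_controls), all(q > 0), all(q < 1))
  w <- 1 / sqrt(n_controls * q * (1 - q))
  Gi <- impute_mean(G, colMeans(G, na.rm = TRUE) / 2)
  score <- drop(Gi %*% w)
  attr(score, "weights") <- w
  score
}

#' Burden test of a collapsed score in the kinship LMM
#'
#' Treats the per-individual UWSS/WSS score as a single fixed predictor in
#' the kinship linear mixed model, with variance components estimated by
#' maximum likelihood and the effect tested by the Wald test.
#'
#' @param score per-individual burden score.
#' @param y phenotype vector.
#' @param X covariate design (NULL = intercept).
#' @param K additive relationship matrix (or use `decomp`).
#' @param decomp pre-computed [kinship_eigen()].
#' @param method variance-component estimation (ML per the collapsed-test
#'   convention).
#' @return `famvar_lmm` fit; `beta`/`se`/`p` describe the score effect.
#' @export
burden_lm <- function(score, y, X = NULL, K = NULL, decomp = NULL,
                      method = "ML") {
  fit_lmm(y, X, g = score, K = K, decomp = decomp, method = method)
}

#' Tail probability of a positive linear combination of chi-squares
#'
#' P(sum_i lambda_i chi2_1 > q), computed by numerical integration of
#' Imhof's inversion formula (the Davies-type exact method), falling back
#' to the Kuonen saddlepoint approximation and, as a last resort, a
#' Satterthwaite moment-matched scaled chi-square.
#'
#' @param q observed statistic.
#' @param lambda positive mixture weights (eigenvalues).
#' @param acc target accuracy of the integration.
#' @return list with `p` (clamped to (0, 1]) and `method` used.
#' @export
pchisqsum <- function(q, lambda, acc = 1e-9) {
  lambda <- lambda[lambda > max(lambda) * 1e-12]
  if (!length(lambda)) return(list(p = 1, method = "degenerate"))
  if (q <= 0) return(list(p = 1, method = "degenerate"))
  # rescale for numerical stability; p is invariant
  s <- max(lambda)
  lambda <- lambda / s
  q <- q / s
  if (length(lambda) == 1L) {
    return(list(p = stats::pchisq(q / lambda, 1, lower.tail = FALSE),
                method = "exact"))
  }
  p <- imhof_p(q, lambda, acc)
  method <- "integration"
  if (is.na(p) || p < 1e-9 || p > 1 - 1e-9) {
    # the quadrature's absolute error floor (~acc) swamps extreme tails;
    # the saddlepoint is relatively accurate there
    ps <- saddlepoint_p(q, lambda)
    if (!is.na(ps)) {
      p <- ps
      method <- "saddlepoint"
    }
  }
  if (is.na(p) || p <= 0 || p > 1) {
    a <- sum(lambda^2) / sum(lambda)
    df <- sum(lambda)^2 / sum(lambda^2)
    p <- stats::pchisq(q / a, df, lower.tail = FALSE)
    method <- "satterthwaite"
  }
  list(p = min(max(p, .Machine$double.xmin), 1), method = method)
}

# 7-point Gauss-Legendre nodes/weights on [-1, 1]
.gl7 <- list(
  x = c(-0.9491079123427585, -0.7415311855993945, -0.4058451513773972, 0,
        0.4058451513773972, 0.7415311855993945, 0.9491079123427585),
  w = c(0.1294849661688697, 0.2797053914892766, 0.3818300505051189,
        0.4179591836734694, 0.3818300505051189, 0.2797053914892766,
        0.1294849661688697))

# Imhof inversion integral by panelized Gauss-Legendre quadrature in u.
# The integrand sin(theta(u)) / (u rho(u)) oscillates no faster than
# (sum(lambda) + q) / 2; panels of an eighth of that period make each panel
# smooth, and the alternating tail beyond the cutoff U is bounded by the
# envelope 1/(u rho(u)) times half a period.
imhof_p <- function(q, lambda, acc = 1e-9) {
  period <- 4 * pi / (sum(lambda) + q)
  envelope <- function(u) {
    1 / (u * exp(0.25 * colSums(log1p(outer(lambda^2, u^2)))))
  }
  u_probe <- period * 2^(0:40)
  bound <- envelope(u_probe) * period / 2
  hit <- which(bound < acc)
  if (!length(hit)) return(NA_real_)
  U <- u_probe[hit[1]]
  n_panel <- ceiling(U / (period / 8))
  if (n_panel > 4e5) return(NA_real_)
  h <- U / n_panel
  centers <- (seq_len(n_panel) - 0.5) * h
  us <- as.vector(outer(.gl7$x * (h / 2), centers, `+`))
  ws <- rep(.gl7$w * (h / 2), n_panel)
  total <- 0
  for (start in seq(1, length(us), by = 2e5)) {
    idx <- start:min(start + 2e5 - 1, length(us))
    u <- us[idx]
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    total <- total + sum(ws[idx] * sin(theta) / (u * rho))
  }
  0.5 + total / pi
}

saddlepoint_p <- function(q, lambda) {
  mu <- sum(lambda)
  if (abs(q - mu) < 1e-8 * mu) return(0.5)
  kprime <- function(z) sum(lambda / (1 - 2 * z * lambda))
  upper <- 1 / (2 * max(lambda))
  f <- function(z) kprime(z) - q
  lo <- if (q > mu) 0 else -1e3
  hi <- if (q > mu) upper * (1 - 1e-10) else 0
  root <- tryCatch(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root,
                   error = function(e) NA_real_)
  if (is.na(root)) return(NA_real_)
  K <- -0.5 * sum(log1p(-2 * root * lambda))
  K2 <- 2 * sum(lambda^2 / (1 - 2 * root * lambda)^2)
  w <- sign(root) * sqrt(max(2 * (root * q - K), 0))
  v <- root * sqrt(K2)
  if (abs(w) < 1e-8) return(0.5)
  stats::pnorm(w + log(v / w) / w, lower.tail = FALSE)
}

#' Family-based sequence kernel association test (famSKAT-style)
#'
#' Variance-component score test of a gene's rare-variant set with a
#' polygenic null model: the null LMM gives Vhat = 2*phi*sigma2_g +
#' I*sigma2_e and residuals r; the statistic is Q = r' Vinv G W^2 G' Vinv
#' r with diagonal per-variant weights W, and its null distribution is the
#' mixture of chi-squares with the eigenvalues of W G' P G W, where P =
#' Vinv - Vinv X (X' Vinv X)^-1 X' Vinv. With identity relatedness this
#' reduces to standard SKAT.
#'
#' @param y phenotype vector.
#' @param X covariate design (NULL = intercept).
#' @param G individuals x variants dosage matrix (missing imputed to
#'   2*maf).
#' @param K additive relationship matrix (or `null_fit`).
#' @param weights `"beta"` for Beta(maf; 1, 25) density weights, `"flat"`
#'   for 1, or a numeric per-variant vector.
#' @param method null-model variance estimation.
#' @param null_fit optional pre-fitted covariate-only [fit_lmm()] (reused
#'   across genes for one phenotype).
#' @return list of class `famvar_burden_result`: `statistic`, `p`,
#'   `p_method`, `n_variants`, `n_carriers`.
#' @export
famskat <- function(y, X = NULL, G, K = NULL, weights = "beta",
                    method = "REML", null_fit = NULL) {
  G <- as.matrix(G)
  maf <- colMeans(G, na.rm = TRUE) / 2
  G <- impute_mean(G, maf)
  w <- if (is.character(weights)) {
    switch(match.arg(weights, c("beta", "flat")),
           beta = stats::dbeta(pmin(maf, 1 - maf), 1, 25),
           flat = rep(1, ncol(G)))
  } else weights
  if (all(w == 0)) stop("all variant weights are zero")
  if (is.null(null_fit)) {
    null_fit <- fit_lmm(y, X, g = NULL, K = K, method = method)
  }
  decomp <- null_fit$decomp
  # everything in the rotated basis where Vhat is diagonal: v = sigma2 * wts
  v <- null_fit$sigma2 * null_fit$weights
  Gt <- kinship_transform(decomp, G)
  Xt <- null_fit$Xt
  rt <- null_fit$yt - Xt %*% null_fit$coefficients
  GW <- sweep(Gt, 2, w, `*`)
  s <- drop(crossprod(GW, rt / v))          # W G' Vinv r
  Q <- sum(s^2)
  # A = W G' P G W, P = Vinv - Vinv X (X'Vinv X)^-1 X'Vinv
  XtVi <- Xt / v
  XtViX_inv <- solve(crossprod(Xt, XtVi))
  B <- crossprod(GW, XtVi)                  # W G' Vinv X
  A <- crossprod(GW, GW / v) - B %*% XtViX_inv %*% t(B)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > max(ev, 0) * 1e-10]
  pres <- if (Q <= 0 || !length(ev)) {
    list(p = 1, method = "degenerate")
  } else {
    pchisqsum(Q, ev)
  }
  structure(list(test = "famSKAT", statistic = Q, p = pres$p,
                 p_method = pres$method, n_variants = ncol(G),
                 n_carriers = sum(rowSums(G > 0.5) > 0),
                 h2 = null_fit$h2),
            class = "famvar_burden_result")
}

#' Adaptive permutation-weighted sum test (PWST-style)
#'
#' Weights each variant by its signed evidence under the null kinship LMM
#' (a_j = sign(score_j) * -log10 p_j from per-variant score tests), tests
#' the a-weighted burden score by a Wald statistic, and calibrates it by
#' permutation adapted to family data: residuals are decorrelated through
#' the Cholesky factor of Vhat, permuted, re-correlated, and the adaptive
#' weights are re-estimated in every permutation so the overfitting of the
#' data-derived weights is reproduced under the null.
#'
#' @param y phenotype vector.
#' @param X covariate design (NULL = intercept).
#' @param G individuals x variants dosage matrix.
#' @param K additive relationship matrix (or `null_fit`).
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed (recorded in the result; required for
#'   reproducibility).
#' @param decorrelate permute decorrelated residuals (default) rather
#'   than raw residuals.
#' @param method null-model variance estimation.
#' @param null_fit optional pre-fitted covariate-only model.
#' @return `famvar_burden_result` with `statistic` (observed Wald z^2),
#'   `p` = (1 + #\{perm >= obs\}) / (n_perm + 1), `n_perm`, `seed`.
#' @export
pwst <- function(y, X = NULL, G, K = NULL, n_perm = 1000L, seed = 1L,
                 decorrelate = TRUE, method = "REML", null_fit = NULL) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  G <- as.matrix(G)
  G <- impute_mean(G, colMeans(G, na.rm = TRUE) / 2)
  if (is.null(null_fit)) {
    null_fit <- fit_lmm(y, X, g = NULL, K = K, method = method)
  }
  decomp <- null_fit$decomp
  v <- null_fit$sigma2 * null_fit$weights   # diagonal of rotated Vhat
  Xt <- null_fit$Xt
  Gt <- kinship_transform(decomp, G)
  rt <- drop(null_fit$yt - Xt %*% null_fit$coefficients)

  XtVi <- Xt / v
  XtViX_inv <- solve(crossprod(Xt, XtVi))
  # per-variant score statistics: U_j = g' Vinv r, var from projection
  GtVi <- Gt / v
  BX <- crossprod(Gt, XtVi)                         # G' Vinv X
  var_u <- colSums(Gt * GtVi) - rowSums((BX %*% XtViX_inv) * BX)

  stat_for <- function(rt_use) {
    U <- drop(crossprod(GtVi, rt_use))
    z <- U / sqrt(pmax(var_u, 1e-300))
    pj <- 2 * stats::pnorm(-abs(z))
    a <- sign(U) * (-log10(pmax(pj, 1e-300)))
    bt <- drop(Gt %*% a)                            # rotated burden score
    # Wald z^2 of the weighted burden in the GLS with Vhat fixed
    M <- cbind(Xt, bt)
    MtVi <- M / v
    MtViM <- crossprod(M, MtVi)
    ch <- tryCatch(chol(MtViM), error = function(e) NULL)
    if (is.null(ch)) return(NA_real_)
    yt_use <- drop(Xt %*% null_fit$coefficients) + rt_use
    bhat <- backsolve(ch, forwardsolve(t(ch), crossprod(MtVi, yt_use)))
    covm <- chol2inv(ch)
    k <- ncol(M)
    (bhat[k]^2) / covm[k, k]
  }

  obs <- stat_for(rt)
  ws <- withr_seed(seed)
  on.exit(ws(), add = TRUE)
  L <- sqrt(v)                                      # chol of rotated Vhat
  r_dec <- if (decorrelate) rt / L else rt
  perm_stats <- vapply(seq_len(n_perm), function(i) {
    rp <- sample(r_dec)
    stat_for(if (decorrelate) rp * L else rp)
  }, numeric(1))
  bad <- mean(!is.finite(perm_stats))
  if (bad > 0.05) warning("non-finite statistic in ", round(100 * bad),
                          "% of permutations")
  p <- (1 + sum(perm_stats >= obs, na.rm = TRUE)) / (n_perm + 1)
  structure(list(test = "PWST", statistic = obs, p = p,
                 n_perm = n_perm, seed = seed,
                 n_variants = ncol(G),
                 n_carriers = sum(rowSums(G > 0.5) > 0),
                 prop_nonfinite = bad),
            class = "famvar_burden_result")
}

# save/restore RNG state so a fixed test seed does not leak
withr_seed <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.famvar_burden_result <- function(x, ...) {
  cat("famvar ", x$test, ": statistic = ", signif(x$statistic, 4),
      ", p = ", signif(x$p, 3), " (", x$n_variants, " variants)\n", sep = "")
  invisible(x)
}

#' Gene-level rare-variant scan
#'
#' Runs the requested collapsed/kernel tests gene by gene on burden-mode
#' filtered genotypes, reusing one null model per phenotype, and tiers
#' the results by the Bonferroni gene-count threshold (significant) and
#' the fixed suggestive level 1e-3. Genes with fewer than two post-filter
#' variants are reported with `skipped = TRUE`.
#'
#' @param genes named list mapping gene symbol to variant ids.
#' @param geno `famvar_genotypes` (burden-mode retained set).
#' @param y named phenotype vector.
#' @param X covariate design or NULL.
#' @param K additive relationship matrix.
#' @param tests subset of `c("uwss", "wss", "pwst", "famskat")`.
#' @param control_ids ids of control individuals for WSS weights (NULL:
#'   all-sample fallback).
#' @param n_perm,seed PWST permutation settings.
#' @param suggestive fixed suggestive p threshold.
#' @return data frame: gene, n_variants, n_carriers, skipped, p_<test>
#'   columns, significance tier per test; thresholds in attributes
#'   `significant` / `suggestive`.
#' @export
gene_scan <- function(genes, geno, y, X = NULL, K,
                      tests = c("famskat", "pwst"),
                      control_ids = NULL, n_perm = 1000L, seed = 1L,
                      suggestive = 1e-3) {
  tests <- match.arg(tests, c("uwss", "wss", "pwst", "famskat"),
                     several.ok = TRUE)
  ids <- names(y)
  dos <- geno$dosage[ids, , drop = FALSE]
  null_reml <- fit_lmm(y, X, g = NULL, K = K, method = "REML")
  null_ml <- if (any(tests %in% c("uwss", "wss"))) {
    fit_lmm(y, X, g = NULL, K = K, method = "ML")
  }
  rows <- lapply(names(genes), function(gn) {
    vids <- intersect(genes[[gn]], colnames(dos))
    row <- data.frame(gene = gn, n_variants = length(vids),
                      n_carriers = NA_integer_, skipped = FALSE)
    for (t in tests) row[[paste0("p_", t)]] <- NA_real_
    if (length(vids) < 2) {
      row$skipped <- TRUE
      return(row)
    }
    G <- dos[, vids, drop = FALSE]
    poly <- apply(G, 2, function(x) stats::var(x, na.rm = TRUE) > 0)
    G <- G[, poly, drop = FALSE]
    if (ncol(G) < 2) {
      row$skipped <- TRUE
      return(row)
    }
    row$n_carriers <- sum(rowSums(G > 0.5, na.rm = TRUE) > 0)
    for (t in tests) {
      pt <- switch(t,
        famskat = famskat(y, X, G, null_fit = null_reml)$p,
        pwst = pwst(y, X, G, n_perm = n_perm,
                    seed = seed + match(gn, names(genes)),
                    null_fit = null_reml)$p,
        uwss = {
          s <- uwss(G)
          if (stats::var(s) == 0) NA_real_ else
            burden_lm(s, y, X, decomp = null_ml$decomp)$p
        },
        wss = {
          cg <- if (!is.null(control_ids)) {
            dos[intersect(control_ids, ids), vids[poly], drop = FALSE]
          }
          s <- wss(G, control_G = cg, use_all = is.null(cg))
          if (stats::var(s) == 0) NA_real_ else
            burden_lm(s, y, X, decomp = null_ml$decomp)$p
        })
      row[[paste0("p_", t)]] <- pt
    }
    row
  })
  out <- do.call(rbind, rows)
  sig <- bonferroni_threshold(nrow(out))
  for (t in tests) {
    p <- out[[paste0("p_", t)]]
    out[[paste0("tier_", t)]] <- ifelse(is.na(p), NA_character_,
      ifelse(p < sig, "significant",
             ifelse(p < suggestive, "suggestive", "ns")))
  }
  attr(out, "significant") <- sig
  attr(out, "suggestive") <- suggestive
  out
}
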