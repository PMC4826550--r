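#' Kinship-adjusted linear mixed model for single-variant association
#'
#' Fits y = X b + g beta + u + e with polygenic random effect
#' u ~ N(0, 2*phi*sigma2_g) and residual e ~ N(0, I*sigma2_e). The
#' variance structure is profiled over the heritability ratio
#' h2 = sigma2_g / (sigma2_g + sigma2_e) after a one-off eigendecomposition
#' of K = 2*phi (block-diagonal by family, reused across variants via
#' `decomp`). Fixed effects come from GLS at the optimum; the genotype
#' effect is tested by a two-sided Wald z statistic against the normal
#' reference.
#'
#' @param y numeric phenotype vector (no missing values).
#' @param X covariate design matrix including the intercept column; NULL
#'   for intercept only.
#' @param g additive genotype dosage vector (the tested predictor), or
#'   NULL to fit the null (covariate-only) model.
#' @param K additive relationship matrix `2 * kinship(ped)` (ignored when
#'   `decomp` is given).
#' @param decomp pre-computed [kinship_eigen()] of K.
#' @param method `"REML"` (default) or `"ML"` variance-component
#'   estimation.
#' @param h2 optionally fix the heritability ratio (e.g. 0 for an
#'   identity-covariance weighted least-squares fit).
#' @param grid_points number of coarse grid points over h2 in [0, 1)
#'   evaluated before local refinement of the profile likelihood.
#' @return list of class `famvar_lmm`: `beta`, `se`, `z`, `p` for the
#'   tested predictor (NA for a null fit), `coefficients` (all fixed
#'   effects), `cov_unscaled`, `sigma2_g`, `sigma2_e`, `h2`, `loglik`,
#'   `n`, `converged`, `method`, and `decomp`/`fitted`/`residuals` for
#'   downstream kernel and permutation tests.
#' @export
fit_lmm <- function(y, X = NULL, g = NULL, K = NULL, decomp = NULL,
                    method = c("REML", "ML"), h2 = NULL, grid_points = 21L) {
  method <- match.arg(method)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (anyNA(y) || anyNA(X)) stop("missing values in y or X")
  if (!is.null(g)) {
    if (anyNA(g)) stop("missing genotype dosages: drop those individuals first")
    if (stats::var(g) == 0) stop("monomorphic predictor: genotype is constant")
    X <- cbind(X, genotype = g)
  }
  if (is.null(decomp)) {
    if (is.null(K)) stop("supply K or decomp")
    decomp <- kinship_eigen(K)
  }
  stopifnot(decomp$n == n)
  lam <- decomp$values
  yt <- kinship_transform(decomp, y)
  Xt <- kinship_transform(decomp, X)
  p <- ncol(X)

  profile <- function(h) {
    w <- h * lam + (1 - h)
    if (any(w <= 0)) return(list(ll = -Inf))
    wi <- 1 / w
    XtWX <- crossprod(Xt * wi, Xt)
    XtWy <- crossprod(Xt * wi, yt)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(list(ll = -Inf))
    beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
    r <- yt - Xt %*% beta
    rss <- sum(r^2 * wi)
    if (method == "REML") {
      s2 <- rss / (n - p)
      ll <- -0.5 * ((n - p) * log(2 * pi * s2) + sum(log(w)) +
                      2 * sum(log(diag(ch))) + (n - p))
    } else {
      s2 <- rss / n
      ll <- -0.5 * (n * log(2 * pi * s2) + sum(log(w)) + n)
    }
    list(ll = ll, beta = drop(beta), s2 = s2, chol = ch, w = w)
  }

  converged <- TRUE
  if (is.null(h2)) {
    grid <- seq(0, 0.999, length.out = grid_points)
    lls <- vapply(grid, function(h) profile(h)$ll, numeric(1))
    best <- which.max(lls)
    lo <- grid[max(1L, best - 1L)]
    hi <- grid[min(length(grid), best + 1L)]
    opt <- stats::optimize(function(h) profile(h)$ll, c(lo, hi), maximum = TRUE)
    h2 <- if (opt$objective >= lls[best]) opt$maximum else grid[best]
    if (!is.finite(opt$objective)) converged <- FALSE
  }
  fit <- profile(h2)
  if (!is.finite(fit$ll)) {
    return(structure(list(beta = NA_real_, se = NA_real_, z = NA_real_,
                          p = NA_real_, converged = FALSE, n = n,
                          method = method),
                     class = "famvar_lmm"))
  }
  s2 <- fit$s2                      # total variance (REML-/ML-scaled)
  cov_unscaled <- chol2inv(fit$chol)
  dimnames(cov_unscaled) <- list(colnames(X), colnames(X))
  se_all <- sqrt(s2 * diag(cov_unscaled))
  coef <- stats::setNames(fit$beta, colnames(X))
  res <- list(
    coefficients = coef,
    cov_unscaled = cov_unscaled,
    sigma2 = s2,
    sigma2_g = h2 * s2,
    sigma2_e = (1 - h2) * s2,
    h2 = h2,
    loglik = fit$ll,
    n = n,
    converged = converged,
    method = method,
    decomp = decomp,
    lambda = lam,
    weights = fit$w,
    Xt = Xt, yt = yt,
    beta = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_
  )
  if (!is.null(g)) {
    res$beta <- unname(coef["genotype"])
    res$se <- unname(se_all[length(se_all)])
    res$z <- res$beta / res$se
    res$p <- 2 * stats::pnorm(-abs(res$z))
  }
  res$fitted <- drop(kinship_transform(decomp, Xt %*% fit$beta, inverse = TRUE))
  res$residuals <- y - res$fitted
  class(res) <- "famvar_lmm"
  res
}

#' @export
print.famvar_lmm <- function(x, ...) {
  cat("famvar kinship LMM (", x$method, "), n = ", x$n,
      ", h2 = ", signif(x$h2, 3), "\n", sep = "")
  if (!is.na(x$beta)) {
    cat("genotype effect: beta =", signif(x$beta, 4), "se =",
        signif(x$se, 4), "p =", signif(x$p, 3), "\n")
  }
  invisible(x)
}

#' Single-variant association scan
#'
#' Runs [fit_lmm()] for each variant column against one phenotype,
#' reusing one kinship eigendecomposition. Individuals with a missing
#' genotype are dropped per variant (complete-case), in which case the
#' kinship decomposition for the subset is recomputed.
#'
#' @param geno `famvar_genotypes` (post single-mode QC).
#' @param y named phenotype vector (names = individual ids).
#' @param X covariate matrix (rows aligned to y), or NULL.
#' @param K additive relationship matrix for the individuals in `y`.
#' @param method variance-component estimation method.
#' @param min_mac skip variants below this minor allele count.
#' @return data frame: variant, maf, mac, n, beta, se, p, converged.
#' @export
assoc_single <- function(geno, y, X = NULL, K, method = "REML", min_mac = 1L) {
  ids <- names(y)
  stopifnot(!is.null(ids), all(ids %in% rownames(geno$dosage)))
  dos <- geno$dosage[ids, , drop = FALSE]
  if (is.null(X)) X <- matrix(1, length(y), 1)
  full <- kinship_eigen(K)
  out <- lapply(seq_len(ncol(dos)), function(j) {
    gj <- dos[, j]
    keep <- !is.na(gj)
    if (!any(keep)) {
      return(data.frame(variant = colnames(dos)[j], maf = NA_real_,
                        mac = NA_integer_, n = 0L, beta = NA_real_,
                        se = NA_real_, p = NA_real_, converged = FALSE))
    }
    mm <- compute_maf(gj)
    row <- data.frame(variant = colnames(dos)[j], maf = mm$maf, mac = mm$mac,
                      n = sum(keep), beta = NA_real_, se = NA_real_,
                      p = NA_real_, converged = FALSE)
    if (mm$mac < min_mac || stats::var(gj[keep]) == 0) return(row)
    fit <- if (all(keep)) {
      fit_lmm(y, X, gj, decomp = full, method = method)
    } else {
      Ksub <- K[keep, keep, drop = FALSE]
      attr(Ksub, "family") <- attr(K, "family")[rownames(Ksub)]
      fit_lmm(y[keep], X[keep, , drop = FALSE], gj[keep], K = Ksub,
              method = method)
    }
    row$beta <- fit$beta; row$se <- fit$se; row$p <- fit$p
    row$converged <- fit$converged
    row
  })
  do.call(rbind, out)
}

#' Genomic control lambda
#'
#' Median observed p-value divided by the expected median (0.5) of
#' uniform null p-values.
#'
#' @param pvalues vector of p-values (NA dropped).
#' @return lambda.
#' @export
genomic_control <- function(pvalues) {
  p <- pvalues[!is.na(pvalues)]
  if (!length(p)) stop("no valid p-values")
  stats::median(p) / 0.5
}

#' Bonferroni significance threshold
#'
#' 0.05 divided by the number of tests (phenotype multiplicity not
#' counted).
#'
#' @param n_tests number of variants (or genes) tested.
#' @return alpha threshold.
#' @export
bonferroni_threshold <- function(n_tests) {
  stopifnot(n_tests >= 1)
  0.05 / n_tests
}

#' Partition association results by minor allele count stability
#'
#' The kinship LMM Wald test is unstable below 10 minor allele copies;
#' results are split into a stable (mac >= 10) and an unstable (mac < 10)
#' set.
#'
#' @param results data frame with a `mac` column.
#' @return list with `stable` and `unstable` data frames.
#' @export
mac_partition <- function(results) {
  list(stable = results[results$mac >= 10, , drop = FALSE],
       unstable = results[results$mac < 10, , drop = FALSE])
}

#' Q-Q plot coordinates for association p-values
#'
#' Sorted observed -log10 p against the uniform expectation i/(n+1).
#'
#' @param pvalues vector of p-values.
#' @return data frame with `expected` and `observed` (-log10 scale).
#' @export
qq_plot_data <- function(pvalues) {
  p <- sort(pvalues[!is.na(pvalues)])
  n <- length(p)
  data.frame(expected = -log10(seq_len(n) / (n + 1)),
             observed = -log10(p))
}
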