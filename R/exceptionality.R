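#' Life table container
#'
#' Sex- and birth-cohort-specific survival curves. Validates that each
#' (sex, cohort) stratum has S(0) = 1 (when age 0 is present), S monotone
#' non-increasing, and values in [0, 1].
#'
#' @param df data frame with columns `sex`, `birth_year_cohort`, `age`,
#'   `survival`.
#' @return `famvar_lifetable` data frame.
#' @export
as_lifetable <- function(df) {
  need <- c("sex", "birth_year_cohort", "age", "survival")
  stopifnot(all(need %in% names(df)))
  if (any(df$survival < 0 | df$survival > 1)) stop("survival outside [0, 1]")
  for (key in split(df, list(df$sex, df$birth_year_cohort), drop = TRUE)) {
    s <- key$survival[order(key$age)]
    if (any(diff(s) > 1e-12)) {
      stop("survival not monotone non-increasing for sex=", key$sex[1],
           " cohort=", key$birth_year_cohort[1])
    }
  }
  class(df) <- c("famvar_lifetable", "data.frame")
  df
}

#' Read a life table TSV
#'
#' Tab-delimited with header `sex`, `birth_year_cohort`, `age`,
#' `survival`; validated by [as_lifetable()].
#'
#' @param path file path.
#' @export
read_lifetable <- function(path) {
  as_lifetable(utils::read.delim(path, na.strings = "NA"))
}

#' @param lt life table to write.
#' @rdname read_lifetable
#' @export
write_lifetable <- function(lt, path) {
  utils::write.table(lt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

lifetable_survival <- function(lt, sex, cohort, age) {
  rows <- lt[lt$sex == sex & lt$birth_year_cohort == cohort, , drop = FALSE]
  if (!nrow(rows)) {
    stop("no life table for sex=", sex, " cohort=", cohort)
  }
  stats::approx(rows$age, rows$survival, xout = age, rule = 2)$y
}

#' Survival exceptionality score
#'
#' Negative logarithm of the probability of surviving beyond the age at
#' last contact, conditional on survival to age 40, under the sex- and
#' birth-cohort-matched life table: score = -log_b(S(age)/S(40)), with S
#' linearly interpolated on the table's age grid.
#'
#' @param age_last age at last contact (>= 40).
#' @param sex,birth_year_cohort stratum keys matching the life table.
#' @param lifetable a `famvar_lifetable`.
#' @param log_base logarithm base (default natural).
#' @return non-negative score (vectorized over individuals).
#' @examples
#' lt <- sim_lifetable()
#' survival_exceptionality(40, "male", lt$birth_year_cohort[1], lt)  # 0
#' @export
survival_exceptionality <- function(age_last, sex, birth_year_cohort,
                                    lifetable, log_base = exp(1)) {
  if (any(age_last < 40)) {
    stop("age at last contact below 40: scores are conditional on survival to 40")
  }
  n <- length(age_last)
  sex <- rep_len(sex, n)
  cohort <- rep_len(birth_year_cohort, n)
  vapply(seq_len(n), function(i) {
    s40 <- lifetable_survival(lifetable, sex[i], cohort[i], 40)
    if (s40 <= 0) stop("S(40) = 0 in matched life table")
    sa <- lifetable_survival(lifetable, sex[i], cohort[i], age_last[i])
    p <- min(sa / s40, 1)
    -log(p, base = log_base)
  }, numeric(1))
}

tail_probability <- function(value, ref_values = NULL, ref_mean = NULL,
                             ref_sd = NULL, beneficial = c("lower", "higher"),
                             two_sided = FALSE) {
  beneficial <- match.arg(beneficial)
  if (!is.null(ref_values)) {
    n <- length(ref_values)
    k <- if (beneficial == "lower") sum(ref_values <= value) else sum(ref_values >= value)
    p <- max(k / n, 1 / (n + 1))
  } else {
    z <- (value - ref_mean) / ref_sd
    p <- if (beneficial == "lower") stats::pnorm(z) else stats::pnorm(z, lower.tail = FALSE)
    p <- max(p, .Machine$double.xmin)
  }
  if (two_sided) p <- min(2 * min(p, 1 - p), 1)
  p
}

#' Quantitative trait exceptionality score
#'
#' Negative logarithm of the one-sided probability, in the matched
#' reference stratum, of a trait value at least as extreme as the
#' observation in the beneficial direction. Empirical references floor the
#' probability at 1/(n_ref + 1); parametric references use a normal tail.
#'
#' @param value observed trait value (scalar).
#' @param ref_values empirical reference sample for the matched stratum, or
#'   NULL to use `ref_mean`/`ref_sd`.
#' @param ref_mean,ref_sd parametric normal reference.
#' @param beneficial which direction is healthier (`"lower"` or
#'   `"higher"`).
#' @param two_sided use a two-sided probability (off by default).
#' @param log_base logarithm base.
#' @return list with `score`, `p`.
#' @export
trait_exceptionality <- function(value, ref_values = NULL, ref_mean = NULL,
                                 ref_sd = NULL,
                                 beneficial = c("lower", "higher"),
                                 two_sided = FALSE, log_base = exp(1)) {
  p <- tail_probability(value, ref_values, ref_mean, ref_sd,
                        beneficial, two_sided)
  list(score = -log(p, base = log_base), p = p)
}

#' Disease onset-age exceptionality score
#'
#' For affected individuals only: negative logarithm of the reference
#' probability of disease onset at the observed age or later (later onset
#' is more exceptional). Unaffected individuals get NA, not 0.
#'
#' @param onset_age observed onset age, NA for unaffected.
#' @param ref_onsets reference onset-age sample.
#' @param log_base logarithm base.
#' @return list with `score`, `p` (both NA when unaffected).
#' @examples
#' onset_exceptionality(75, c(60, 70, 80))$p  # 1/3
#' @export
onset_exceptionality <- function(onset_age, ref_onsets, log_base = exp(1)) {
  if (is.na(onset_age)) return(list(score = NA_real_, p = NA_real_))
  n <- length(ref_onsets)
  p <- max(sum(ref_onsets >= onset_age) / n, 1 / (n + 1))
  list(score = -log(p, base = log_base), p = p)
}

#' Residualize exceptionality scores on covariates
#'
#' Final analysis phenotype: scores adjusted for study covariates (field
#' center, principal components, ...) by full least-squares
#' residualization (see [adjust_covariates()]).
#'
#' @param scores numeric score vector.
#' @param covariates data frame of covariates.
#' @param standardize standardize residuals to unit variance.
#' @return residual vector.
#' @export
residualize_scores <- function(scores, covariates = NULL, standardize = TRUE) {
  adjust_covariates(scores, covariates, mode = "full",
                    standardize = standardize)
}
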