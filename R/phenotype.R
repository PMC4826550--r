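#' Mortality weights for the Healthy Aging Index components
#'
#' Cox proportional-hazards regression coefficients for the effect of each
#' component on survival, used to weight the per-trait tertile scores.
#'
#' @return named numeric vector (sbp, fvc, mmse, creatinine, glucose).
#' @export
hai_mortality_weights <- function() {
  c(sbp = 0.17085, fvc = 0.38386, mmse = 0.42873,
    creatinine = 0.13397, glucose = 0.23880)
}

# which direction is unhealthy for each HAI component
hai_directions <- function() {
  c(sbp = "higher", fvc = "lower", mmse = "lower",
    creatinine = "higher", glucose = "higher")
}

#' Tertile cutpoints for HAI scoring
#'
#' Computes per-trait tertile boundaries, by default on residuals from a
#' linear age adjustment within sex ("approximate age-adjusted tertiles");
#' raw-value tertiles are available with `age_adjust = FALSE`.
#'
#' @param components data frame with columns `sbp`, `fvc`, `mmse`,
#'   `creatinine`, `glucose` (one row per individual).
#' @param age,sex vectors used for the age adjustment (required when
#'   `age_adjust = TRUE`).
#' @param age_adjust adjust each component for age within sex before
#'   taking tertiles.
#' @return list of class `famvar_hai_cutpoints`: per trait, the two
#'   boundaries, the unhealthy direction, and (when age-adjusted) the
#'   per-sex linear fits needed to place new values.
#' @export
hai_cutpoints <- function(components, age = NULL, sex = NULL,
                          age_adjust = TRUE) {
  traits <- names(hai_directions())
  stopifnot(all(traits %in% names(components)))
  out <- list(age_adjust = age_adjust, traits = list())
  for (tr in traits) {
    x <- components[[tr]]
    fits <- NULL
    if (age_adjust) {
      stopifnot(!is.null(age), !is.null(sex))
      fits <- lapply(split(seq_along(x), sex), function(i) {
        f <- stats::lm(x[i] ~ age[i])
        c(intercept = unname(stats::coef(f)[1]), slope = unname(stats::coef(f)[2]))
      })
      x <- hai_residual(x, age, sex, fits)
    }
    q <- stats::quantile(x, c(1 / 3, 2 / 3), na.rm = TRUE, names = FALSE)
    out$traits[[tr]] <- list(boundaries = q,
                             direction = hai_directions()[[tr]],
                             fits = fits)
  }
  class(out) <- "famvar_hai_cutpoints"
  out
}

hai_residual <- function(x, age, sex, fits) {
  r <- rep(NA_real_, length(x))
  for (s in names(fits)) {
    i <- which(sex == s)
    r[i] <- x[i] - (fits[[s]]["intercept"] + fits[[s]]["slope"] * age[i])
  }
  r
}

#' Healthy Aging Index
#'
#' Scores each of five physiological components 0 (healthiest tertile), 1
#' or 2 (unhealthiest) and sums them to an index from 0 (healthy) to 10
#' (unhealthy). Values on a tertile boundary take the lower (healthier)
#' score. Any missing component gives a missing HAI — no partial sums.
#'
#' @param components data frame of component values (see [hai_cutpoints()]).
#' @param cutpoints a `famvar_hai_cutpoints`.
#' @param age,sex needed when the cutpoints are age-adjusted.
#' @return list with `scores` (individuals x traits matrix of 0/1/2) and
#'   `hai` (row sums, NA if any component missing).
#' @export
hai_score <- function(components, cutpoints, age = NULL, sex = NULL) {
  traits <- names(cutpoints$traits)
  scores <- matrix(NA_real_, nrow(components), length(traits),
                   dimnames = list(rownames(components), traits))
  for (tr in traits) {
    cp <- cutpoints$traits[[tr]]
    x <- components[[tr]]
    if (cutpoints$age_adjust) {
      stopifnot(!is.null(age), !is.null(sex))
      x <- hai_residual(x, age, sex, cp$fits)
    }
    q <- cp$boundaries
    if (cp$direction == "higher") {        # higher value = unhealthier
      s <- ifelse(x <= q[1], 0, ifelse(x <= q[2], 1, 2))
    } else {                               # lower value = unhealthier
      s <- ifelse(x >= q[2], 0, ifelse(x >= q[1], 1, 2))
    }
    scores[, tr] <- s
  }
  list(scores = scores, hai = rowSums(scores))
}

#' Mortality-weighted Healthy Aging Index
#'
#' Weighted sum of the five per-trait 0/1/2 scores using the Cox-derived
#' mortality weights.
#'
#' @param scores individuals x traits matrix from [hai_score()].
#' @param weights named weights (default [hai_mortality_weights()]).
#' @return numeric vector of weighted sums (NA when any score missing).
#' @export
mortality_weighted_hai <- function(scores, weights = hai_mortality_weights()) {
  stopifnot(all(colnames(scores) %in% names(weights)))
  drop(scores %*% weights[colnames(scores)])
}

#' Leukocyte telomere length from the T/S ratio
#'
#' Linear calibration of qPCR telomere/single-copy-gene ratio to base
#' pairs: bp = 1585 * T/S + 3582.
#'
#' @param ts_ratio non-negative T/S ratio.
#' @return telomere length in base pairs.
#' @export
telomere_bp <- function(ts_ratio) {
  stopifnot(all(ts_ratio >= 0, na.rm = TRUE))
  1585 * ts_ratio + 3582
}

#' Friedewald LDL cholesterol
#'
#' LDL = total cholesterol - HDL - triglycerides/5, valid only when
#' triglycerides < 400 mg/dL (NA otherwise).
#'
#' @param total_chol,hdl,trig mg/dL.
#' @return LDL cholesterol in mg/dL, NA where triglycerides >= 400.
#' @export
friedewald_ldl <- function(total_chol, hdl, trig) {
  ldl <- total_chol - hdl - trig / 5
  ldl[!is.na(trig) & trig >= 400] <- NA_real_
  ldl
}

#' Simple derived measurements
#'
#' Pulse pressure (systolic minus diastolic, mmHg), body mass index
#' (kg/m^2) and type-2-diabetes status (diabetes medication use or
#' fasting glucose >= 126 mg/dL).
#'
#' @param sbp,dbp blood pressures in mmHg.
#' @return `pulse_pressure`: mmHg.
#' @export
pulse_pressure <- function(sbp, dbp) sbp - dbp

#' @param weight_kg,height_m weight and height.
#' @rdname pulse_pressure
#' @export
bmi <- function(weight_kg, height_m) weight_kg / height_m^2

#' @param meds logical, on diabetes medication.
#' @param fasting_glucose mg/dL.
#' @rdname pulse_pressure
#' @export
t2d_status <- function(meds, fasting_glucose) {
  meds | (!is.na(fasting_glucose) & fasting_glucose >= 126)
}

#' Rank-based inverse normal transform
#'
#' Maps values to standard-normal quantiles by rank using the Blom offset:
#' ranks r -> qnorm((r - 3/8) / (n + 1/4)). Ties share the average rank;
#' missing values stay missing and do not enter n.
#'
#' @param values numeric vector (>= 2 non-missing).
#' @return transformed vector, same length and order.
#' @export
inverse_normal <- function(values) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 2) stop("need at least 2 non-missing values")
  r <- rank(values[ok], ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

#' Residualize a trait on covariates
#'
#' Least-squares covariate adjustment; `"full"` mode regresses on every
#' covariate, `"stepwise"` mode forward-selects covariates at p < 0.05
#' (Wald/F test of the added term) before residualizing. Residuals are
#' standardized to unit variance.
#'
#' @param trait numeric response.
#' @param covariates data frame (numeric or factor columns); factors are
#'   one-hot expanded by the model formula.
#' @param mode `"full"` or `"stepwise"`.
#' @param alpha stepwise entry threshold.
#' @param standardize divide residuals by their standard deviation.
#' @return numeric residual vector aligned to the input rows (NA where the
#'   trait or a used covariate is missing).
#' @export
adjust_covariates <- function(trait, covariates = NULL,
                              mode = c("full", "stepwise"),
                              alpha = 0.05, standardize = TRUE) {
  mode <- match.arg(mode)
  n <- length(trait)
  if (is.null(covariates) || !length(covariates)) {
    covariates <- data.frame(row.names = seq_len(n))
  }
  stopifnot(nrow(covariates) == n)
  dat <- data.frame(.y = trait, covariates, check.names = TRUE)
  vars <- setdiff(names(dat), ".y")

  if (mode == "stepwise" && length(vars)) {
    selected <- character()
    repeat {
      cand <- setdiff(vars, selected)
      if (!length(cand)) break
      pvals <- vapply(cand, function(v) {
        base_f <- stats::reformulate(c("1", selected), response = ".y")
        new_f <- stats::reformulate(c("1", selected, v), response = ".y")
        a <- stats::anova(stats::lm(base_f, data = dat),
                          stats::lm(new_f, data = dat))
        a[["Pr(>F)"]][2]
      }, numeric(1))
      best <- which.min(pvals)
      if (is.na(pvals[best]) || pvals[best] >= alpha) break
      selected <- c(selected, cand[best])
    }
    vars <- selected
  }

  f <- stats::reformulate(c("1", vars), response = ".y")
  fit <- stats::lm(f, data = dat, na.action = stats::na.exclude)
  if (length(vars)) {
    alias <- stats::alias(fit)$Complete
    if (!is.null(alias)) {
      stop("collinear covariate column(s): ",
           paste(rownames(alias), collapse = ", "))
    }
  }
  r <- stats::residuals(fit)
  if (standardize) {
    s <- stats::sd(r, na.rm = TRUE)
    if (is.finite(s) && s > 0) r <- r / s
  }
  as.numeric(r)
}
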