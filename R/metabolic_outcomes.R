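# Metabolic risk indices, age/sex residualization, and the composite score.

# pmol/L of insulin per mU/L (conventional <-> SI conversion).
INSULIN_PMOL_PER_MU <- 6.945

#' Derive metabolic risk indices from a raw panel
#'
#' Computes BMI, waist:height ratio, TC:HDL ratio, Friedewald LDL and HOMA
#' insulin resistance for each subject.
#'
#' HOMA is glucose (mmol/L) x insulin (mU/L) / 22.5. Insulin assayed in
#' pmol/L is first converted to mU/L (divide by 6.945); set
#' `literal_homa = TRUE` to skip the conversion and divide the pmol/L value
#' by 22.5 directly (a dimensionally inconsistent but sometimes-printed form).
#'
#' Friedewald LDL = TC - HDL - TG/2.2 (all mmol/L); it is invalid above a
#' triglyceride bound (default 4.5 mmol/L) and is returned as `NA` there.
#'
#' @param panel Data frame with columns `subject_id`, `body_mass` (kg),
#'   `height` (cm), `waist` (cm), `tc`, `hdl`, `tg`, `glucose` (mmol/L),
#'   `insulin` (pmol/L unless `insulin_unit = "mU_per_l"`).
#' @param insulin_unit Unit of the insulin column.
#' @param literal_homa Use the literal pmol/L formula without conversion.
#' @param friedewald_tg_max Triglyceride validity bound for LDL (mmol/L).
#' @return Data frame: `subject_id`, `bmi`, `wc_height`, `tc_hdl`, `ldl`,
#'   `homa`.
#' @export
derive_indices <- function(panel,
                           insulin_unit = c("pmol_per_l", "mU_per_l"),
                           literal_homa = FALSE,
                           friedewald_tg_max = 4.5) {
  insulin_unit <- match.arg(insulin_unit)
  need <- c("body_mass", "height", "waist", "tc", "hdl", "tg",
            "glucose", "insulin")
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("panel missing columns: ", paste(miss, collapse = ", "))
  pos <- c("body_mass", "height", "waist", "tc", "hdl", "tg", "glucose",
           "insulin")
  for (v in pos)
    if (any(panel[[v]] <= 0 | !is.finite(panel[[v]])))
      stop("non-positive or non-finite values in `", v, "`")
  if (any(panel$hdl >= panel$tc))
    stop("HDL must be below total cholesterol")

  insulin_mU <- if (insulin_unit == "pmol_per_l" && !literal_homa)
    panel$insulin / INSULIN_PMOL_PER_MU else panel$insulin
  ldl <- panel$tc - panel$hdl - panel$tg / 2.2
  ldl[panel$tg > friedewald_tg_max] <- NA_real_
  data.frame(
    subject_id = panel$subject_id,
    bmi = panel$body_mass / (panel$height / 100)^2,
    wc_height = panel$waist / panel$height,
    tc_hdl = panel$tc / panel$hdl,
    ldl = ldl,
    homa = panel$glucose * insulin_mU / 22.5)
}

#' Residualize an outcome on age and sex
#'
#' Ordinary least squares of `outcome` on an intercept, age and a binary sex
#' indicator; returns the residuals. Residuals have mean zero and are
#' orthogonal to both covariates; the sex coding (0/1 vs 1/2) cannot affect
#' them.
#'
#' @param outcome Numeric vector, no missing values.
#' @param age Numeric vector of ages.
#' @param sex Binary vector (any two-level coding).
#' @return Residual vector of the same length.
#' @export
residualize <- function(outcome, age, sex) {
  n <- length(outcome)
  stopifnot(length(age) == n, length(sex) == n)
  if (anyNA(outcome) || anyNA(age) || anyNA(sex))
    stop("missing values not allowed; use complete cases")
  if (n <= 3) stop("need n > 3 observations")
  sex_num <- as.numeric(factor(sex))
  X <- cbind(1, age, sex_num)
  qx <- qr(X)
  if (qx$rank < ncol(X) &&
      length(unique(age)) > 1 && length(unique(sex_num)) > 1)
    stop("rank-deficient design (age/sex collinear)")
  qr.resid(qx, outcome)
}

#' Residualize a set of outcomes on age and sex
#'
#' @param outcomes Data frame or matrix of outcome columns.
#' @param age,sex Covariates as in [residualize()].
#' @return Matrix of residuals with the same column names.
#' @export
adjust_outcomes <- function(outcomes, age, sex) {
  m <- as.matrix(outcomes)
  res <- apply(m, 2, residualize, age = age, sex = sex)
  colnames(res) <- colnames(m)
  res
}

#' Composite metabolic-health score
#'
#' Standardizes each age/sex-adjusted risk factor to mean 0 / SD 1, reverses
#' the aerobic-fitness component (so that higher always means worse health),
#' averages the six z-scores, and rescales the average to unit SD over the
#' sample. The resulting score has sample mean 0 and SD 1 by construction.
#'
#' @param adjusted Matrix or data frame of adjusted outcome residuals; six
#'   columns expected by the standard protocol (SBP, TG, TC:HDL, HOMA,
#'   WC:height, fitness).
#' @param reverse Column names whose sign is flipped (default `"andersen"`).
#' @param rescale Rescale the averaged score to SD 1 (default TRUE).
#' @return Numeric composite vector (higher = worse metabolic health).
#' @export
composite_score <- function(adjusted, reverse = "andersen", rescale = TRUE) {
  m <- as.matrix(adjusted)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance component(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  z <- scale(m)
  rev_idx <- which(colnames(m) %in% reverse)
  z[, rev_idx] <- -z[, rev_idx]
  comp <- rowMeans(z)
  if (rescale) comp <- comp / stats::sd(comp)
  as.numeric(comp)
}

#' Read a metabolic panel CSV
#'
#' Required columns: `subject_id`, `sex`, `age`, `body_mass`, `height`,
#' `waist`, `sbp`, `dbp`, `tc`, `hdl`, `tg`, `glucose`, `insulin`,
#' `andersen_distance`.
#'
#' @param path CSV file path.
#' @return Data frame of the panel.
#' @export
read_panel_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sex", "age", "body_mass", "height", "waist",
            "sbp", "dbp", "tc", "hdl", "tg", "glucose", "insulin",
            "andersen_distance")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("panel CSV missing columns: ",
                         paste(miss, collapse = ", "))
  df
}

#' Build the adjusted outcome set used by the multivariate models
#'
#' Derives indices from the raw panel, residualizes the six model outcomes
#' (SBP, TG, TC:HDL, HOMA, WC:height, Andersen distance) on age and sex, and
#' appends the composite score.
#'
#' @param panel Raw panel data frame (see [read_panel_csv()]).
#' @param ... Passed to [derive_indices()].
#' @return A list with `adjusted` (n x 6 residual matrix), `composite`
#'   (numeric vector), `derived` (indices data frame).
#' @export
build_outcomes <- function(panel, ...) {
  derived <- derive_indices(panel, ...)
  raw <- cbind(sbp = panel$sbp, tg = panel$tg, tc_hdl = derived$tc_hdl,
               homa = derived$homa, wc_height = derived$wc_height,
               andersen = panel$andersen_distance)
  adjusted <- adjust_outcomes(raw, panel$age, panel$sex)
  list(adjusted = adjusted,
       composite = composite_score(adjusted),
       derived = derived)
}
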