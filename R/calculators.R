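# Deterministic clinical classifiers applied automatically during screening.
# Band convention (documented in clinical_thresholds.yaml): lower bound
# inclusive, upper bound exclusive; abdominal obesity alone is a strict '>'
# per the ATP-III wording.

#' Laboratory unit conversion helpers
#'
#' Convert between mg/dL and mmol/L for the analytes the calculators use.
#' Conversion factors (mg/dL per mmol/L): glucose 18.016, cholesterol (total,
#' HDL, LDL) 38.67, triglycerides 88.57.
#'
#' @param x Numeric value(s).
#' @param analyte One of "glucose", "cholesterol", "triglycerides".
#' @return Converted numeric value(s).
#' @export
mgdl_to_mmol <- function(x, analyte = c("glucose", "cholesterol",
                                        "triglycerides")) {
  x / unit_factor(match.arg(analyte))
}

#' @rdname mgdl_to_mmol
#' @export
mmol_to_mgdl <- function(x, analyte = c("glucose", "cholesterol",
                                        "triglycerides")) {
  x * unit_factor(match.arg(analyte))
}

unit_factor <- function(analyte) {
  c(glucose = 18.016, cholesterol = 38.67, triglycerides = 88.57)[[analyte]]
}

#' Body mass index with category
#'
#' @param weight Weight in kg (> 0).
#' @param height Height in cm (> 0).
#' @return List with `value` (kg/m^2) and `category` in
#'   underweight / normal / overweight / obese (cuts 18.5, 25, 30;
#'   lower-inclusive, so a BMI of exactly 25 is overweight).
#' @examples
#' compute_bmi(70, 175)  # 22.86, normal
#' @export
compute_bmi <- function(weight, height) {
  if (!isTRUE(weight > 0) || !isTRUE(height > 0)) {
    stop_domain("weight and height must be > 0")
  }
  th <- clinical_thresholds()$bmi
  value <- weight / (height / 100)^2
  category <- if (value < th$underweight_below) "underweight"
  else if (value < th$overweight_from) "normal"
  else if (value < th$obese_from) "overweight"
  else "obese"
  list(value = value, category = category)
}

#' Blood-pressure severity category (JNC-7 bands)
#'
#' The label is the worse of the systolic and diastolic component categories:
#' normal <120 and <80; high_normal 120-139 or 80-89; stage1 140-159 or
#' 90-99; stage2 >= 160 or >= 100. ("high_normal" is the 120-139/80-89 band,
#' i.e. JNC-7 prehypertension.)
#'
#' @param systolic,diastolic mmHg, with systolic > diastolic > 0.
#' @return List with `label`, `systolic`, `diastolic`.
#' @export
categorize_bp <- function(systolic, diastolic) {
  if (!isTRUE(systolic > diastolic) || !isTRUE(diastolic > 0)) {
    stop_domain("requires systolic > diastolic > 0")
  }
  th <- clinical_thresholds()$blood_pressure
  level <- function(value, which) {
    if (value >= th$stage2[[which]]) 4L
    else if (value >= th$stage1[[which]]) 3L
    else if (value >= th$high_normal[[which]]) 2L
    else 1L
  }
  worst <- max(level(systolic, "systolic_from"), level(diastolic, "diastolic_from"))
  list(label = c("normal", "high_normal", "stage1", "stage2")[worst],
       systolic = systolic, diastolic = diastolic)
}

#' Abdominal obesity by waist circumference
#'
#' ATP-III waist-circumference criterion: strictly greater than 102 cm (men)
#' or 88 cm (women).
#'
#' @param waist Waist circumference in cm (> 0).
#' @param sex "male" or "female".
#' @return Logical.
#' @export
detect_abdominal_obesity <- function(waist, sex) {
  if (!isTRUE(waist > 0)) stop_domain("waist must be > 0")
  sex <- match.arg(sex, c("male", "female"))
  waist > clinical_thresholds()$abdominal_obesity$waist_over[[sex]]
}

#' Fasting plasma glucose category
#'
#' @param fpg Fasting plasma glucose in mg/dL (> 0).
#' @return List with `fpg` and `category`: normal (<100),
#'   impaired_fasting_glucose (100-125), diabetic_range (>= 126).
#' @export
categorize_fpg <- function(fpg) {
  if (!isTRUE(fpg > 0)) stop_domain("fpg must be > 0")
  th <- clinical_thresholds()$fasting_glucose
  category <- if (fpg < th$impaired_from) "normal"
  else if (fpg < th$diabetic_from) "impaired_fasting_glucose"
  else "diabetic_range"
  list(fpg = fpg, category = category)
}

#' Lipid panel per-component categories (ATP-III bands)
#'
#' Total cholesterol: desirable <200, borderline 200-239, high >= 240.
#' LDL: <130 / 130-159 / >= 160. Triglycerides: <150 / 150-199 / >= 200.
#' HDL is flagged low below 40 mg/dL (men) or 50 mg/dL (women).
#'
#' @param panel Named list/vector with `total_cholesterol`, `hdl`, `ldl`,
#'   `triglycerides` in mg/dL (all >= 0, hdl <= total_cholesterol).
#' @param sex "male" or "female" (sets the low-HDL cut).
#' @return List of component categories plus `low_hdl` logical and
#'   `any_borderline_or_high` convenience flag.
#' @export
categorize_lipids <- function(panel, sex) {
  sex <- match.arg(sex, c("male", "female"))
  vals <- vapply(c("total_cholesterol", "hdl", "ldl", "triglycerides"),
                 function(k) as.numeric(panel[[k]] %||% NA_real_), 0)
  if (any(!is.na(vals) & vals < 0)) stop_domain("lipid values must be >= 0")
  if (!is.na(vals["hdl"]) && !is.na(vals["total_cholesterol"]) &&
      vals["hdl"] > vals["total_cholesterol"]) {
    stop_domain("hdl cannot exceed total cholesterol")
  }
  th <- clinical_thresholds()$lipids
  band <- function(x, cuts) {
    if (is.na(x)) return(NA_character_)
    if (x < cuts$borderline_from) "desirable"
    else if (x < cuts$high_from) "borderline"
    else "high"
  }
  out <- list(
    total_cholesterol = band(vals["total_cholesterol"], th$total_cholesterol),
    ldl = band(vals["ldl"], th$ldl),
    triglycerides = band(vals["triglycerides"], th$triglycerides),
    low_hdl = if (is.na(vals["hdl"])) NA else vals["hdl"] < th$low_hdl_below[[sex]]
  )
  cats <- unlist(out[1:3])
  out$any_borderline_or_high <-
    any(cats %in% c("borderline", "high"), na.rm = TRUE) || isTRUE(out$low_hdl)
  out
}

#' ATP-III metabolic syndrome detection
#'
#' Five criteria: waist > 102/88 cm by sex; triglycerides >= 150 mg/dL;
#' HDL < 40/50 mg/dL by sex; blood pressure >= 130/85 mmHg (either component)
#' or on antihypertensive treatment; fasting glucose >= 100 mg/dL. Positive
#' when at least three are met. A missing component evaluates its criterion
#' as not met and is recorded in `not_evaluable`.
#'
#' @param exam A [physical_exam()] (or NULL) supplying waist and blood
#'   pressure.
#' @param panel Lipid panel as in [categorize_lipids()] (or NULL).
#' @param fpg Fasting plasma glucose, mg/dL (or NA).
#' @param sex "male" or "female".
#' @param treated_bp Logical, on antihypertensive treatment.
#' @return List with `criteria_met` (character subset of the five names),
#'   `positive`, and `not_evaluable` (criteria lacking data).
#' @export
detect_metabolic_syndrome <- function(exam, panel, fpg, sex,
                                      treated_bp = FALSE) {
  sex <- match.arg(sex, c("male", "female"))
  th <- clinical_thresholds()$metabolic_syndrome
  met <- character(0)
  missing <- character(0)
  judge <- function(name, available, hit) {
    if (!available) missing <<- c(missing, name)
    else if (hit) met <<- c(met, name)
  }
  judge("abdominal_obesity", !is.null(exam) && isTRUE(exam$waist > 0),
        !is.null(exam) && isTRUE(detect_abdominal_obesity(exam$waist, sex)))
  tg <- if (is.null(panel)) NA_real_ else as.numeric(panel$triglycerides %||% NA_real_)
  judge("high_triglycerides", !is.na(tg), isTRUE(tg >= th$triglycerides_from))
  hdl <- if (is.null(panel)) NA_real_ else as.numeric(panel$hdl %||% NA_real_)
  judge("low_hdl", !is.na(hdl), isTRUE(hdl < th$low_hdl_below[[sex]]))
  bp_known <- !is.null(exam) && isTRUE(exam$systolic > 0)
  judge("elevated_bp", bp_known || isTRUE(treated_bp),
        isTRUE(treated_bp) ||
          (bp_known && (exam$systolic >= th$bp_from$systolic ||
                        exam$diastolic >= th$bp_from$diastolic)))
  judge("elevated_fpg", !is.na(fpg), isTRUE(fpg >= th$fpg_from))
  list(criteria_met = met,
       positive = length(met) >= th$min_criteria,
       not_evaluable = missing)
}
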