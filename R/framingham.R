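# Framingham 10-year hard-CHD risk, ATP-III point-table version.
# The sex-specific tables are shipped as data (inst/extdata/framingham_atp3.yaml)
# so every cell is auditable and swappable without touching code.

band_index <- function(x, cuts) {
  # cuts c1 < c2 < ...: index 1 for x < c1, 2 for c1 <= x < c2, ...
  sum(x >= unlist(cuts)) + 1L
}

in_band <- function(age, bands) {
  which(vapply(bands, function(b) age >= b[[1]] && age <= b[[2]], TRUE))
}

#' Framingham 10-year hard-CHD risk (ATP-III point tables)
#'
#' Sums the sex-specific ATP-III points for age band, age-group-adjusted total
#' cholesterol and smoking, HDL, and treated/untreated systolic pressure, then
#' maps total points to the published 10-year hard coronary heart disease risk
#' percent. The lookup's open "<1\%" band is reported as 0.5 and the open top
#' band as 30. Risk category: low (<10\%), intermediate (10 to <20\%),
#' high (>= 20\%).
#'
#' @param age Age in completed years, 20-79.
#' @param sex "male" or "female".
#' @param total_cholesterol Total cholesterol, mg/dL.
#' @param hdl HDL cholesterol, mg/dL.
#' @param systolic Systolic blood pressure, mmHg.
#' @param treated_bp Logical, on antihypertensive treatment.
#' @param smoker Logical, current smoker.
#' @return List with `points` (integer), `ten_year_risk` (percent) and
#'   `category`.
#' @examples
#' framingham_risk(55, "male", 220, 45, 135, treated_bp = FALSE, smoker = TRUE)
#' @export
framingham_risk <- function(age, sex, total_cholesterol, hdl, systolic,
                            treated_bp = FALSE, smoker = FALSE) {
  sex <- match.arg(sex, c("male", "female"))
  if (!isTRUE(age >= 20 && age <= 79)) {
    stop_domain("age must be within the tabulated range 20-79, got ", age)
  }
  if (!isTRUE(total_cholesterol > 0) || !isTRUE(hdl > 0) || !isTRUE(systolic > 0)) {
    stop_domain("cholesterol, hdl and systolic must be positive")
  }
  tab <- framingham_tables()
  sx <- tab[[sex]]
  pts <- sx$age_points[[in_band(age, tab$age_bands)]]
  decade <- in_band(age, tab$decades)
  chol_band <- band_index(total_cholesterol, tab$total_cholesterol_cuts)
  pts <- pts + sx$chol_points[[chol_band]][[decade]]
  if (isTRUE(smoker)) pts <- pts + sx$smoker_points[[decade]]
  hp <- tab$hdl_points
  pts <- pts + if (hdl >= 60) hp$ge60 else if (hdl >= 50) hp$`50_59`
  else if (hdl >= 40) hp$`40_49` else hp$lt40
  sbp_band <- band_index(systolic, tab$sbp_cuts)
  pts <- pts + if (isTRUE(treated_bp)) sx$sbp_points_treated[[sbp_band]]
  else sx$sbp_points_untreated[[sbp_band]]

  rk <- sx$risk
  risk <- if (pts < rk$floor_below) rk$below_value
  else if (pts >= rk$top_from) rk$top_value
  else rk$table[[as.character(pts)]]
  cuts <- clinical_thresholds()$framingham_categories
  category <- if (risk < cuts$intermediate_from) "low"
  else if (risk < cuts$high_from) "intermediate"
  else "high"
  list(points = as.integer(pts), ten_year_risk = as.numeric(risk),
       category = category)
}
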