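# Access to the versioned clinical-constants files shipped with the package.

.smartscreen_cache <- new.env(parent = emptyenv())

#' Screening test codes known to the package
#'
#' The fixed vocabulary of screening test identifiers used in records,
#' rulesets and audit tallies.
#'
#' @return Character vector of test codes.
#' @export
test_codes <- function() {
  c("FPG", "LIPID_PROFILE", "FOBT", "SIGMOIDOSCOPY_COLONOSCOPY",
    "PAP_SMEAR", "MAMMOGRAPHY", "PSA", "SKIN_EXAM")
}

#' Clinical threshold constants
#'
#' Loads (and caches) the versioned cut-point file used by the clinical
#' calculators: BMI classes, JNC-7 blood-pressure bands, ATP-III lipid,
#' fasting-glucose, abdominal-obesity and metabolic-syndrome thresholds, and
#' the Framingham risk-category cuts. Band convention throughout: lower bound
#' inclusive, upper bound exclusive.
#'
#' @param path Optional path to an alternative thresholds YAML file; the
#'   default is the file shipped with the package.
#' @return Nested list mirroring the YAML structure.
#' @export
clinical_thresholds <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.smartscreen_cache$thresholds)) {
      return(.smartscreen_cache$thresholds)
    }
    path <- system.file("extdata", "clinical_thresholds.yaml",
                        package = "smartscreen")
    th <- yaml::read_yaml(path)
    .smartscreen_cache$thresholds <- th
    return(th)
  }
  yaml::read_yaml(path)
}

# Cached ATP-III Framingham point tables.
#' @keywords internal
framingham_tables <- function() {
  if (is.null(.smartscreen_cache$framingham)) {
    path <- system.file("extdata", "framingham_atp3.yaml",
                        package = "smartscreen")
    .smartscreen_cache$framingham <- yaml::read_yaml(path)
  }
  .smartscreen_cache$framingham
}
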