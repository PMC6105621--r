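# Worked-example stroke cohort.

#' Example chronic-stroke cohort
#'
#' Clinical and imaging characteristics of eight patients in the early chronic
#' phase after a first ischemic stroke, transcribed from a published cohort
#' table: lesion volume (mm^3), corticospinal-tract lesion load (mm^3),
#' months since stroke, NIHSS (0 = no deficit) and the four Chedoke-McMaster
#' limb-segment stages (7 = normal; one foot score is missing because that
#' patient could not complete clinical testing). Used throughout the worked
#' examples for the cohort statistics.
#'
#' Numeric columns in the source print run together without delimiters, so the
#' values here were reconstructed by enumerating digit splits and validating
#' the lesion-size column against the source's own correlation table (which it
#' reproduces to within 0.01); the tract lesion-load column does not reproduce
#' the source's functional correlations under any reading and appears to be a
#' different (unweighted) quantity — see the package vignette.
#'
#' @return A tibble with columns `id`, `sex`, `age`, `side`, `location`,
#'   `lesion_volume`, `wcst_ll`, `months_post`, `nihss`, `chedoke_arm`,
#'   `chedoke_hand`, `chedoke_leg`, `chedoke_foot`.
#' @export
example_stroke_cohort <- function() {
  path <- system.file("extdata", "stroke_cohort_example.tsv",
                      package = "hemiconn", mustWork = TRUE)
  read_cohort(path)
}
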