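# Synthetic clinical cohorts with known marker -> score coefficients, for
# regression-recovery experiments.

#' Cohort generator specification
#'
#' Each outcome is generated as
#' `intercept + b_lesion * lesion_volume + b_li * li_s1 + N(0, sd)`, with
#' Chedoke components clipped to \[1, 7\] and NIHSS floored at 0 after noise.
#' Default coefficients keep the scores well inside their ranges so clipping is
#' essentially inactive and the analytic variance decomposition holds.
#'
#' @param n_patients,n_controls Group sizes (>= 3 patients for any regression).
#' @param betas Named list of `c(intercept, b_lesion, b_li, sd)` per outcome
#'   (`nihss`, `chedoke_arm`, `chedoke_hand`, `chedoke_leg`, `chedoke_foot`).
#' @param lesion_range Uniform sampling range of lesion volume, mm^3.
#' @param li_range Uniform sampling range of the S1 laterality index.
#' @param missing Optional data frame with columns `row`, `col` marking cells
#'   to blank (patient row index, column name).
#' @param seed RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 8L, n_controls = 8L,
                        betas = list(
                          nihss        = c(intercept = 4,   b_lesion =  2.5e-5, b_li =  3.0, sd = 1.5),
                          chedoke_arm  = c(intercept = 6.5, b_lesion = -1.2e-5, b_li = -1.5, sd = 0.5),
                          chedoke_hand = c(intercept = 6.5, b_lesion = -1.0e-5, b_li = -1.8, sd = 0.5),
                          chedoke_leg  = c(intercept = 6.0, b_lesion = -0.6e-5, b_li = -0.5, sd = 0.5),
                          chedoke_foot = c(intercept = 6.0, b_lesion = -0.9e-5, b_li = -0.8, sd = 0.5)),
                        lesion_range = c(300, 350000),
                        li_range = c(-0.2, 1),
                        missing = NULL,
                        seed = 1L) {
  if (n_patients < 3L) stop("need at least 3 patients", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 betas = betas, lesion_range = lesion_range, li_range = li_range,
                 missing = missing, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a clinical cohort table
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `id`, `group`, `lesion_volume`, `wcst_ll`,
#'   `li_s1`, `li_m1`, `nihss`, `chedoke_arm`, `chedoke_hand`, `chedoke_leg`,
#'   `chedoke_foot`. Control rows carry `NA` lesion markers and ceiling scores.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  np <- spec$n_patients; nc <- spec$n_controls
  withr::with_seed(spec$seed, {
    lesion <- runif(np, spec$lesion_range[1], spec$lesion_range[2])
    li_s1 <- runif(np, spec$li_range[1], spec$li_range[2])
    li_m1 <- pmin(1, pmax(-1, li_s1 * 0.8 + rnorm(np, 0, 0.15)))
    wcst <- lesion * runif(np, 0.01, 0.35)
    eps <- lapply(spec$betas, function(b) rnorm(np, 0, b[["sd"]]))
  })
  outcome <- function(nm) {
    b <- spec$betas[[nm]]
    y <- b[["intercept"]] + b[["b_lesion"]] * lesion + b[["b_li"]] * li_s1 + eps[[nm]]
    if (nm == "nihss") pmax(0, y) else pmin(7, pmax(1, y))
  }
  pat <- tibble::tibble(
    id = sprintf("P%02d", seq_len(np)), group = "patient",
    lesion_volume = lesion, wcst_ll = wcst, li_s1 = li_s1, li_m1 = li_m1,
    nihss = outcome("nihss"),
    chedoke_arm = outcome("chedoke_arm"), chedoke_hand = outcome("chedoke_hand"),
    chedoke_leg = outcome("chedoke_leg"), chedoke_foot = outcome("chedoke_foot"))
  if (!is.null(spec$missing)) {
    for (i in seq_len(nrow(spec$missing))) {
      pat[spec$missing$row[i], spec$missing$col[i]] <- NA
    }
  }
  if (nc > 0) {
    ctl <- tibble::tibble(
      id = sprintf("C%02d", seq_len(nc)), group = "control",
      lesion_volume = NA_real_, wcst_ll = NA_real_,
      li_s1 = NA_real_, li_m1 = NA_real_,
      nihss = 0, chedoke_arm = 7, chedoke_hand = 7, chedoke_leg = 7,
      chedoke_foot = 7)
    dplyr::bind_rows(pat, ctl)
  } else {
    pat
  }
}

#' Analytic variance decomposition of a simulated cohort outcome
#'
#' Population R-squared of the lesion-only and lesion + LI models under the
#' generative model of [simulate_cohort()] (uniform, independent predictors),
#' used as the oracle in regression-recovery experiments.
#'
#' @param spec A [cohort_spec()].
#' @param outcome Outcome name, e.g. `"nihss"`.
#' @return A list with `r2_block1`, `r2_block2` and `delta_r2`.
#' @export
cohort_population_r2 <- function(spec, outcome = "nihss") {
  b <- spec$betas[[outcome]]
  v_les <- diff(spec$lesion_range)^2 / 12
  v_li <- diff(spec$li_range)^2 / 12
  v1 <- b[["b_lesion"]]^2 * v_les
  v2 <- b[["b_li"]]^2 * v_li
  tot <- v1 + v2 + b[["sd"]]^2
  list(r2_block1 = v1 / tot, r2_block2 = (v1 + v2) / tot, delta_r2 = v2 / tot)
}
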