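#' Assay cost/time configuration
#'
#' Unit costs for a clinical biomarker panel: routine assays (AFP,
#' CA 19-9, CA 125, CEA, Prolactin, CA 15-3) average $2 per test, other
#' biomarker assays $5.5, and each biomarker takes about 2.5 h of clinical
#' test time.
#'
#' @param routine_cost USD per routine biomarker test.
#' @param other_cost USD per non-routine biomarker test.
#' @param hours_per_biomarker clinical hours per biomarker assay.
#' @return A list of class `"cost_config"`.
#' @export
cost_config <- function(routine_cost = 2, other_cost = 5.5,
                        hours_per_biomarker = 2.5) {
  if (routine_cost <= 0 || other_cost <= 0 || hours_per_biomarker <= 0) {
    stop("config error: cost parameters must be positive", call. = FALSE)
  }
  structure(list(routine_cost = routine_cost, other_cost = other_cost,
                 hours_per_biomarker = hours_per_biomarker),
            class = "cost_config")
}

#' Clinical cost and turnaround time of a feature panel
#'
#' Only biomarker features are charged; the omega score and clinical
#' covariates (age, sex, race) add no assay cost or time. Cost is
#' `routine_cost * #routine + other_cost * #other` biomarkers; time is
#' `hours_per_biomarker * #biomarkers`.
#'
#' @param features a [feature_meta()] frame (e.g. the selected panel).
#' @param config a [cost_config()].
#' @return A list with `cost` (USD), `time` (hours), `n_routine`,
#'   `n_other`.
#' @export
panel_cost <- function(features, config = cost_config()) {
  stopifnot(inherits(config, "cost_config"))
  bio <- features$kind == "biomarker"
  n_routine <- sum(bio & features$routine)
  n_other <- sum(bio & !features$routine)
  list(cost = config$routine_cost * n_routine + config$other_cost * n_other,
       time = config$hours_per_biomarker * (n_routine + n_other),
       n_routine = n_routine, n_other = n_other)
}
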