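#' The berberine nanocarrier study: factors
#'
#' The three formulation factors of the bundled berberine nanostructured
#' lipid carrier study: glycerol monostearate amount (100-200 mg),
#' poloxamer 407 concentration (1-2 % w/w) and oleic acid amount
#' (15-30 mg).
#'
#' @return List of three [factor_def()]s.
#' @export
berberine_factors <- function() {
  list(
    factor_def("GMS", 100, 200, "mg"),
    factor_def("poloxamer407", 1, 2, "% w/w"),
    factor_def("oleic_acid", 15, 30, "mg")
  )
}

#' The berberine nanocarrier study: responses
#'
#' Particle size (sqrt transform, minimized, linear model), entrapment
#' efficiency (inverse transform, maximized, reduced quadratic), zeta
#' potential (stored as a signed negative value; its factors show no
#' significant effect, so it is excluded from optimization) and
#' 24-hour cumulative drug release (untransformed, maximized, linear
#' model).
#'
#' @return List of four [response_def()]s.
#' @export
berberine_responses <- function() {
  list(
    response_def("PS", transform = "sqrt", goal = "minimize",
                 terms = "linear", min_valid = 1e-9, units = "nm"),
    response_def("EE", transform = "inverse", goal = "maximize",
                 terms = "quadratic", reduce = TRUE,
                 min_valid = 0, max_valid = 100, units = "%"),
    response_def("ZP", transform = "identity", goal = "none",
                 terms = "linear", units = "mV"),
    response_def("CDR", transform = "identity", goal = "maximize",
                 terms = "linear", min_valid = 0, max_valid = 100,
                 units = "%")
  )
}

#' The berberine nanocarrier study: full configuration
#'
#' Protocol constants of the bundled study: AUC horizon 480 min,
#' three-point terminal window, brain/blood ratio read at 30 min,
#' permeation cell of 2.5 cm^2 with 50 mL receptor and 1 mL replaced
#' samples, release cell of 5 cm^2, 3 mg donor dose, and a donor
#' concentration of 1000 ug/mL (implied by the study's flux/permeability
#' pairing).
#'
#' @return A [study_config()].
#' @export
berberine_config <- function() {
  study_config(
    factors = berberine_factors(),
    responses = berberine_responses(),
    ke_points = 3, auc_t_end = 480, ratio_time = 30,
    search = list(grid_n = 41, reltol = 1e-6),
    permeation = list(area_cm2 = 2.5, donor_dose_ug = 3000,
                      donor_volume_ml = 3,
                      donor_concentration_ug_ml = 1000,
                      receptor_volume_ml = 50, sample_volume_ml = 1),
    release = list(area_cm2 = 5, donor_dose_ug = 3000,
                   donor_volume_ml = 3,
                   donor_concentration_ug_ml = 1000,
                   receptor_volume_ml = 50, sample_volume_ml = 1)
  )
}

#' The berberine nanocarrier study: 17-run design table
#'
#' The bundled 17-run Box-Behnken formulation table: factor settings in
#' laboratory units and the measured mean responses (particle size nm,
#' entrapment %, zeta potential mV as a signed value, 24-h cumulative
#' release %).
#'
#' @return Data frame with columns `run`, `GMS`, `poloxamer407`,
#'   `oleic_acid`, `PS`, `EE`, `ZP`, `CDR`.
#' @export
berberine_runs <- function() {
  read_design_table(
    system.file("extdata", "nlc_formulation_runs.csv",
                package = "nose2brain", mustWork = TRUE),
    berberine_config()
  )
}

#' The berberine nanocarrier study: reported pharmacokinetic parameters
#'
#' Non-compartmental parameters of the in vivo arms (intravenous
#' solution, intranasal solution, intranasal coated carrier; brain and
#' blood): Tmax, Cmax, Ke, half-life, AUC0-t, the 30-min brain/blood
#' concentration ratio and the AUC_brain/AUC_blood quotient.
#'
#' @return Data frame, one row per (group, tissue, route).
#' @export
pk_reference <- function() {
  utils::read.csv(
    system.file("extdata", "pk_reference_parameters.csv",
                package = "nose2brain", mustWork = TRUE),
    stringsAsFactors = FALSE
  )
}

#' The berberine nanocarrier study: reported permeation parameters
#'
#' Ex vivo nasal-mucosa permeation parameters of the coated carrier and
#' the plain solution: steady-state flux, 12-h cumulative amount per
#' area, apparent permeability and percent permeated.
#'
#' @return Data frame, one row per preparation.
#' @export
permeation_reference <- function() {
  utils::read.csv(
    system.file("extdata", "permeation_reference.csv",
                package = "nose2brain", mustWork = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Fit the study's standard response-surface models
#'
#' Fits every response of a configuration to a design table using its
#' declared transform and term set, backward-eliminating where the
#' response asks for it.
#'
#' @param runs Design table (see [read_design_table()]).
#' @param config A [study_config()].
#' @return Named list of `rsm_fit` objects.
#' @examples
#' fits <- fit_study_models(berberine_runs(), berberine_config())
#' coef(fits$PS)
#' @export
fit_study_models <- function(runs, config) {
  design <- as_bbd_design(runs, config$factors)
  fits <- lapply(config$responses, function(r) {
    fit <- fit_rsm(design, runs[[r$name]], terms = r$terms,
                   transform = r$transform, response_name = r$name)
    if (r$reduce) fit <- reduce_model(fit, alpha = 0.05) else fit
  })
  names(fits) <- names(config$responses)
  fits
}

#' Desirability goals declared by a configuration
#'
#' @param config A [study_config()].
#' @param runs Optional design table whose observed response ranges
#'   become the anchors (otherwise anchors default at optimization
#'   time).
#' @return Named list of [desirability_goal()]s for the responses with
#'   a `minimize`/`maximize` goal.
#' @export
study_goals <- function(config, runs = NULL) {
  keep <- Filter(function(r) r$goal != "none", config$responses)
  goals <- lapply(keep, function(r) {
    desirability_goal(
      r$goal,
      lower = if (!is.null(runs)) min(runs[[r$name]]),
      upper = if (!is.null(runs)) max(runs[[r$name]])
    )
  })
  names(goals) <- vapply(keep, `[[`, character(1), "name")
  goals
}
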