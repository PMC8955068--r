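#' Define a response variable
#'
#' @param name Response name (column header in design tables).
#' @param transform Modelling transform, see [apply_transform()].
#' @param goal `"minimize"`, `"maximize"`, or `"none"` (excluded from
#'   optimization, e.g. a response whose factors show no significant
#'   effect).
#' @param terms Default term set for this response, see [rsm_terms()].
#' @param reduce Backward-eliminate the model at `alpha = 0.05` after
#'   fitting.
#' @param min_valid,max_valid Validation bounds applied when reading a
#'   design table (`NA` = unbounded).
#' @param units Units label.
#' @return List of class `response_def`.
#' @export
response_def <- function(name, transform = "identity",
                         goal = c("maximize", "minimize", "none"),
                         terms = "linear", reduce = FALSE,
                         min_valid = NA_real_, max_valid = NA_real_,
                         units = "") {
  goal <- match.arg(goal)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  transform <- match.arg(transform, c("identity", "sqrt", "inverse"))
  structure(
    list(name = name, transform = transform, goal = goal,
         terms = rsm_terms(terms), reduce = isTRUE(reduce),
         min_valid = min_valid, max_valid = max_valid, units = units),
    class = "response_def"
  )
}

#' Assemble a study configuration
#'
#' Gathers everything the pipeline needs beyond the raw tables: factor
#' and response definitions, the terminal-phase window and AUC horizon
#' for pharmacokinetics, desirability search settings, and the
#' diffusion-cell geometry for release and permeation runs. All volumes,
#' areas and doses must be strictly positive — the cell geometry is
#' never assumed.
#'
#' @param factors List of three [factor_def()]s.
#' @param responses List of [response_def()]s.
#' @param ke_points Terminal-phase point count for Ke estimation.
#' @param auc_t_end AUC horizon (min, > 0).
#' @param ratio_time Time of the brain/blood concentration ratio (min).
#' @param search List: `grid_n` (grid density per axis) and `reltol`
#'   (polish tolerance) for the desirability search.
#' @param permeation List: `area_cm2`, `donor_dose_ug`,
#'   `donor_volume_ml`, `donor_concentration_ug_ml`,
#'   `receptor_volume_ml`, `sample_volume_ml` for the permeation cell.
#' @param release Same fields for the release cell.
#' @return List of class `study_config`.
#' @seealso [berberine_config()] for the bundled study's configuration.
#' @export
study_config <- function(factors, responses,
                         ke_points = 3, auc_t_end = 480, ratio_time = 30,
                         search = list(grid_n = 41, reltol = 1e-6),
                         permeation = list(area_cm2 = 2.5,
                                           donor_dose_ug = 3000,
                                           donor_volume_ml = 3,
                                           donor_concentration_ug_ml = 1000,
                                           receptor_volume_ml = 50,
                                           sample_volume_ml = 1),
                         release = list(area_cm2 = 5,
                                        donor_dose_ug = 3000,
                                        donor_volume_ml = 3,
                                        donor_concentration_ug_ml = 1000,
                                        receptor_volume_ml = 50,
                                        sample_volume_ml = 1)) {
  stopifnot(is.list(factors),
            all(vapply(factors, inherits, logical(1), "factor_def")),
            is.list(responses),
            all(vapply(responses, inherits, logical(1), "response_def")))
  stopifnot(auc_t_end > 0, ke_points >= 2, ratio_time >= 0,
            search$grid_n >= 2, search$reltol > 0)
  for (geom in list(permeation = permeation, release = release)) {
    vals <- unlist(geom)
    if (any(!is.finite(vals)) || any(vals <= 0)) {
      stop("all cell areas, doses and volumes must be strictly positive",
           call. = FALSE)
    }
  }
  names(factors) <- vapply(factors, `[[`, character(1), "name")
  names(responses) <- vapply(responses, `[[`, character(1), "name")
  structure(
    list(factors = factors, responses = responses,
         ke_points = ke_points, auc_t_end = auc_t_end,
         ratio_time = ratio_time, search = search,
         permeation = permeation, release = release),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat("study configuration:\n  factors:",
      paste(names(x$factors), collapse = ", "),
      "\n  responses:", paste(names(x$responses), collapse = ", "),
      sprintf("\n  AUC horizon %g min, Ke window %d points\n",
              x$auc_t_end, x$ke_points))
  invisible(x)
}

#' Read / write a study configuration as YAML
#'
#' @param path File path.
#' @return `read_study_config()` returns a [study_config()];
#'   `write_study_config()` returns `path` invisibly.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  factors <- lapply(y$factors, function(f) {
    factor_def(f$name, f$low, f$high, f$units %||% "")
  })
  responses <- lapply(y$responses, function(r) {
    response_def(r$name, r$transform %||% "identity",
                 r$goal %||% "none", r$terms %||% "linear",
                 r$reduce %||% FALSE,
                 r$min_valid %||% NA_real_, r$max_valid %||% NA_real_,
                 r$units %||% "")
  })
  study_config(factors, responses,
               ke_points = y$ke_points %||% 3,
               auc_t_end = y$auc_t_end %||% 480,
               ratio_time = y$ratio_time %||% 30,
               search = utils::modifyList(list(grid_n = 41, reltol = 1e-6),
                                          y$search %||% list()),
               permeation = y$permeation %||%
                 eval(formals(study_config)$permeation),
               release = y$release %||% eval(formals(study_config)$release))
}

#' @rdname read_study_config
#' @param config A [study_config()].
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  y <- list(
    factors = lapply(unname(config$factors), function(f) {
      list(name = f$name, low = f$low, high = f$high, units = f$units)
    }),
    responses = lapply(unname(config$responses), function(r) {
      list(name = r$name, transform = r$transform, goal = r$goal,
           terms = as.list(r$terms), reduce = r$reduce,
           min_valid = r$min_valid, max_valid = r$max_valid,
           units = r$units)
    }),
    ke_points = config$ke_points, auc_t_end = config$auc_t_end,
    ratio_time = config$ratio_time, search = config$search,
    permeation = config$permeation, release = config$release
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
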