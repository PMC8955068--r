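#' Entrapment efficiency
#'
#' Indirect entrapment estimate: the fraction of the added dose that is
#' not recovered free in the filtrate,
#' `EE% = 100 * (dose - free) / dose`.
#'
#' @param dose_mg Drug added to the formulation (mg, > 0).
#' @param free_mg Unentrapped drug measured in the filtrate (mg).
#' @return Entrapment efficiency in percent.
#' @examples
#' entrapment_efficiency(10, 1.97) # 80.3
#' @export
entrapment_efficiency <- function(dose_mg, free_mg) {
  stopifnot(all(dose_mg > 0))
  if (any(free_mg < 0) || any(free_mg > dose_mg)) {
    stop("free drug must lie between 0 and the dose", call. = FALSE)
  }
  100 * (dose_mg - free_mg) / dose_mg
}

#' Describe a Franz diffusion-cell run
#'
#' Raw sampling record of an in vitro release or ex vivo permeation
#' experiment: receptor-chamber concentrations measured at increasing
#' times, with the cell geometry needed to convert them into cumulative
#' amounts. When `replacement = TRUE` each sample of `sample_volume_ml`
#' is replaced with fresh medium and the removed drug mass is added back
#' in the cumulative bookkeeping.
#'
#' @param times_h Strictly increasing sampling times (hours).
#' @param concentrations_ug_ml Sampled receptor concentrations (ug/mL).
#' @param donor_dose_ug Drug loaded in the donor chamber (ug).
#' @param area_cm2 Diffusion surface area (cm^2).
#' @param receptor_volume_ml Receptor chamber volume (mL).
#' @param sample_volume_ml Volume withdrawn per sample (mL).
#' @param replacement Whether withdrawn medium is replaced.
#' @return An object of class `diffusion_run`.
#' @export
diffusion_run <- function(times_h, concentrations_ug_ml, donor_dose_ug,
                          area_cm2, receptor_volume_ml,
                          sample_volume_ml = 0, replacement = sample_volume_ml > 0) {
  times_h <- as.numeric(times_h)
  concentrations_ug_ml <- as.numeric(concentrations_ug_ml)
  stopifnot(length(times_h) == length(concentrations_ug_ml))
  if (length(times_h) && any(diff(times_h) <= 0)) {
    stop("sampling times must be strictly increasing", call. = FALSE)
  }
  if (any(concentrations_ug_ml < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  stopifnot(donor_dose_ug > 0, area_cm2 > 0, receptor_volume_ml > 0,
            sample_volume_ml >= 0)
  if (sample_volume_ml >= receptor_volume_ml) {
    stop("sample volume must be smaller than the receptor volume",
         call. = FALSE)
  }
  structure(
    list(times_h = times_h, concentrations_ug_ml = concentrations_ug_ml,
         donor_dose_ug = donor_dose_ug, area_cm2 = area_cm2,
         receptor_volume_ml = receptor_volume_ml,
         sample_volume_ml = sample_volume_ml, replacement = replacement),
    class = "diffusion_run"
  )
}

#' Cumulative amount transferred per unit area
#'
#' Converts sampled receptor concentrations into the cumulative drug
#' amount per membrane area. With sampling replacement,
#' `Q(t_n) = (C_n V_receptor + sum_{i<n} C_i V_sample) / area`,
#' crediting the drug mass removed by earlier samples; without
#' replacement simply `Q(t_n) = C_n V_receptor / area`.
#'
#' @param run A [diffusion_run()].
#' @return Numeric vector `Q` (ug/cm^2), one value per sampling time.
#' @examples
#' r <- diffusion_run(12, 23.64, donor_dose_ug = 3000, area_cm2 = 2.5,
#'                    receptor_volume_ml = 50)
#' cumulative_per_area(r) # 472.8
#' @export
cumulative_per_area <- function(run) {
  stopifnot(inherits(run, "diffusion_run"))
  conc <- run$concentrations_ug_ml
  if (run$replacement && run$sample_volume_ml > 0) {
    removed <- c(0, cumsum(conc * run$sample_volume_ml))[seq_along(conc)]
    (conc * run$receptor_volume_ml + removed) / run$area_cm2
  } else {
    conc * run$receptor_volume_ml / run$area_cm2
  }
}

#' Percent of the applied dose transferred
#'
#' @param q_end Cumulative amount per area at the end time (ug/cm^2).
#' @param dose_per_area Applied dose per area (ug/cm^2, > 0).
#' @return Percent transferred.
#' @examples
#' percent_transferred(472.8, 600) # 78.8
#' @export
percent_transferred <- function(q_end, dose_per_area) {
  stopifnot(all(dose_per_area > 0))
  100 * q_end / dose_per_area
}

#' Steady-state flux from a cumulative-permeation series
#'
#' Least-squares slope of `Q` versus time over the chosen window. The
#' default window drops only the first point, treating everything after
#' it as the steady-state portion; pass an index vector or a `c(t0, t1)`
#' time range to restrict further.
#'
#' @param times_h Sampling times (hours).
#' @param q Cumulative amounts per area (ug/cm^2), same length.
#' @param window `NULL` (default), integer indices, or a numeric time
#'   range `c(t0, t1)` selecting the points used.
#' @return Flux Jss (ug cm^-2 h^-1).
#' @examples
#' t <- 1:12
#' steady_state_flux(t, 10.63 * t) # 10.63
#' @export
steady_state_flux <- function(times_h, q, window = NULL) {
  stopifnot(length(times_h) == length(q))
  idx <- if (is.null(window)) {
    seq_along(times_h)[-1]
  } else if (is.double(window) && length(window) == 2L) {
    which(times_h >= window[1] & times_h <= window[2])
  } else {
    as.integer(window)
  }
  if (length(idx) < 2L) {
    stop("steady-state flux needs at least 2 points in the window",
         call. = FALSE)
  }
  t <- times_h[idx]
  y <- q[idx]
  unname(stats::cov(t, y) / stats::var(t))
}

#' Apparent permeability coefficient
#'
#' `Papp = Jss / C0` with `C0` the donor concentration, so that
#' `Papp * C0` recovers the steady-state flux exactly.
#'
#' @param jss Steady-state flux (ug cm^-2 h^-1).
#' @param donor_concentration_ug_ml Donor concentration C0 (ug/mL, > 0).
#' @return Papp in cm/h.
#' @examples
#' apparent_permeability(10.63, 1000) # 0.01063
#' @export
apparent_permeability <- function(jss, donor_concentration_ug_ml) {
  stopifnot(all(donor_concentration_ug_ml > 0))
  jss / donor_concentration_ug_ml
}

#' Summarize a diffusion run into permeation parameters
#'
#' Convenience wrapper computing the cumulative series, endpoint amount,
#' percent of dose transferred, steady-state flux and apparent
#' permeability in one pass.
#'
#' @param run A [diffusion_run()].
#' @param donor_concentration_ug_ml Donor concentration C0 (ug/mL).
#' @param window Flux window, see [steady_state_flux()].
#' @return List of class `permeation_params`: `jss`, `papp`, `q_end`,
#'   `percent`, and the full `q` series.
#' @export
permeation_parameters <- function(run, donor_concentration_ug_ml,
                                  window = NULL) {
  q <- cumulative_per_area(run)
  jss <- steady_state_flux(run$times_h, q, window)
  structure(
    list(
      jss = jss,
      papp = apparent_permeability(jss, donor_concentration_ug_ml),
      q_end = q[length(q)],
      percent = percent_transferred(q[length(q)],
                                    run$donor_dose_ug / run$area_cm2),
      q = q,
      times_h = run$times_h
    ),
    class = "permeation_params"
  )
}

#' @export
print.permeation_params <- function(x, ...) {
  cat(sprintf(
    "Jss %.4g ug/cm^2/h  Papp %.4g cm/h  Q(end) %.4g ug/cm^2 (%.3g%% of dose)\n",
    x$jss, x$papp, x$q_end, x$percent))
  invisible(x)
}
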