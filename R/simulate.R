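# mean-one multiplicative log-normal noise factors
lognormal_factors <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Ground-truth response surface for simulation
#'
#' @param transform `"identity"`, `"sqrt"` or `"inverse"` — the scale on
#'   which the polynomial and the Gaussian noise live.
#' @param coefficients Named numeric vector: `"(Intercept)"` plus term
#'   labels accepted by [rsm_terms()].
#' @param noise_sd Gaussian noise SD on the transformed scale (>= 0).
#' @return Object of class `true_surface`.
#' @export
true_surface <- function(transform = c("identity", "sqrt", "inverse"),
                         coefficients, noise_sd = 0) {
  transform <- match.arg(transform)
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            noise_sd >= 0)
  if (!"(Intercept)" %in% names(coefficients)) {
    stop("coefficients must include an '(Intercept)' entry", call. = FALSE)
  }
  terms <- rsm_terms(setdiff(names(coefficients), "(Intercept)"))
  structure(
    list(transform = transform,
         coefficients = coefficients[c("(Intercept)", terms)],
         terms = terms, noise_sd = noise_sd),
    class = "true_surface"
  )
}

#' Simulate a Box-Behnken formulation study
#'
#' Builds the design, evaluates each true polynomial at every run on its
#' transformed scale, adds Gaussian noise of the stated SD, and
#' back-transforms to the original response scale. Noise draws that push
#' a `sqrt`/`inverse` response out of the transform's domain are redrawn
#' (with a warning), up to `max_retries` times per response.
#'
#' @param factors List of three [factor_def()]s.
#' @param center_replicates Centre-point replicates.
#' @param truth Named list of [true_surface()]s, one per response.
#' @param seed Integer seed (reproducibility).
#' @param max_retries Redraw cap for domain violations.
#' @return List with `design` (a `bbd_design`) and `runs` (data frame of
#'   actual-unit factor settings and simulated responses, one row per
#'   run, with a leading `run` label column).
#' @examples
#' ts <- true_surface("sqrt", c("(Intercept)" = 12.8, x1 = 1.87,
#'                              x2 = -0.58, x3 = -0.14), noise_sd = 0)
#' sim <- simulate_bbd_study(berberine_factors(), 5, list(PS = ts), seed = 1)
#' @export
simulate_bbd_study <- function(factors, center_replicates, truth, seed,
                               max_retries = 100) {
  stopifnot(is.list(truth), length(truth) >= 1L, !is.null(names(truth)),
            all(vapply(truth, inherits, logical(1), "true_surface")))
  set.seed(as.integer(seed))
  design <- bbd_design(factors, center_replicates)
  n <- nrow(design$coded)
  runs <- cbind(run = seq_len(n), design$actual)
  for (nm in names(truth)) {
    ts <- truth[[nm]]
    eta <- drop(term_matrix(design$coded, ts$terms) %*% ts$coefficients)
    y_t <- eta + stats::rnorm(n, sd = ts$noise_sd)
    if (ts$transform != "identity") {
      tries <- 0
      while (any(y_t <= 0) && tries < max_retries) {
        bad <- y_t <= 0
        y_t[bad] <- eta[bad] + stats::rnorm(sum(bad), sd = ts$noise_sd)
        tries <- tries + 1
      }
      if (any(y_t <= 0)) {
        stop("response '", nm, "': could not draw in-domain transformed ",
             "values after ", max_retries, " retries", call. = FALSE)
      }
      if (tries > 0) {
        warning("response '", nm, "': redrew out-of-domain noise (",
                tries, " retry pass(es))", call. = FALSE)
      }
    }
    runs[[nm]] <- inverse_transform(y_t, ts$transform)
  }
  list(design = design, runs = runs)
}

#' Parameters of the two-compartment nasal/intravenous PK simulator
#'
#' The simulator treats blood as a one-compartment system (bolus input
#' for the intravenous route, first-order absorption of the systemic
#' depot fraction for the intranasal route) and the brain as a linear
#' uptake/efflux compartment fed by blood, plus — for the intranasal
#' route — a first-order direct nose-to-brain input of the `f_direct`
#' depot fraction. All solutions are closed-form, so zero-noise
#' simulations are exact.
#'
#' @param dose_ug Administered dose (ug).
#' @param v_blood_ml Apparent blood distribution volume (mL).
#' @param v_brain_ml Apparent volume scaling the direct brain input (mL).
#' @param k Blood elimination rate (min^-1).
#' @param ka Nasal absorption rate into blood (min^-1, IN only).
#' @param kin Brain uptake rate from blood (min^-1).
#' @param kout Brain efflux rate (min^-1).
#' @param f_direct Fraction of the nasal dose taking the direct
#'   nose-to-brain pathway, in `[0, 1]`.
#' @param kd Direct-input rate (min^-1).
#' @param times Sampling grid (min).
#' @param noise_cv Multiplicative log-normal noise CV (0 = noiseless).
#' @param seed Integer seed.
#' @return Validated parameter list of class `pk_sim_params`.
#' @export
pk_sim_params <- function(dose_ug = 1125, v_blood_ml = 176,
                          v_brain_ml = 176, k = 0.0218, ka = 0.012,
                          kin = 0.004, kout = 0.01, f_direct = 0.5,
                          kd = 0.02,
                          times = c(10, 30, 60, 120, 240, 480),
                          noise_cv = 0, seed = 1L) {
  p <- list(dose_ug = dose_ug, v_blood_ml = v_blood_ml,
            v_brain_ml = v_brain_ml, k = k, ka = ka, kin = kin,
            kout = kout, f_direct = f_direct, kd = kd,
            times = as.numeric(times), noise_cv = noise_cv,
            seed = as.integer(seed))
  with(p, {
    stopifnot(dose_ug > 0, v_blood_ml > 0, v_brain_ml > 0,
              k > 0, ka > 0, kin > 0, kout > 0, kd > 0,
              f_direct >= 0, f_direct <= 1, noise_cv >= 0,
              length(times) >= 2, all(times >= 0), all(diff(times) > 0))
  })
  rates <- c(k = p$k, ka = p$ka, kout = p$kout, kd = p$kd)
  if (min(abs(diff(sort(rates)))) < 1e-10) {
    stop("rate constants k, ka, kout, kd must be pairwise distinct ",
         "(the closed-form solution degenerates)", call. = FALSE)
  }
  structure(p, class = "pk_sim_params")
}

# closed-form concentration curves (ng/mL); internal
pk_curves <- function(p) {
  c0 <- 1000 * p$dose_ug / p$v_blood_ml          # ng/mL
  a_in <- 1000 * p$dose_ug * (1 - p$f_direct) * p$ka /
    (p$v_blood_ml * (p$ka - p$k))
  bump <- function(k1, k2) function(t) (exp(-k1 * t) - exp(-k2 * t)) / (k2 - k1)
  list(
    blood_iv = function(t) c0 * exp(-p$k * t),
    brain_iv = function(t) c0 * p$kin * bump(p$k, p$kout)(t),
    blood_in = function(t) a_in * (exp(-p$k * t) - exp(-p$ka * t)),
    brain_in = function(t) {
      indirect <- p$kin * a_in *
        (bump(p$k, p$kout)(t) - bump(p$ka, p$kout)(t))
      direct <- 1000 * p$f_direct * p$dose_ug * p$kd / p$v_brain_ml *
        bump(p$kd, p$kout)(t)
      indirect + direct
    }
  )
}

# exact zero-to-infinity AUCs of the closed-form curves (ng/mL * min)
pk_true_auc <- function(p) {
  c0 <- 1000 * p$dose_ug / p$v_blood_ml
  blood_iv <- c0 / p$k
  brain_iv <- p$kin * c0 / (p$k * p$kout)
  blood_in <- c0 * (1 - p$f_direct) / p$k
  brain_in_indirect <- p$kin * blood_in / p$kout
  brain_in_direct <- 1000 * p$f_direct * p$dose_ug / (p$v_brain_ml * p$kout)
  list(blood_iv = blood_iv, brain_iv = brain_iv, blood_in = blood_in,
       brain_in = brain_in_indirect + brain_in_direct,
       brain_in_direct = brain_in_direct,
       brain_in_indirect = brain_in_indirect)
}

#' Simulate an intravenous/intranasal brain-targeting PK study
#'
#' Generates the four concentration-time profiles (brain and blood after
#' intravenous and intranasal dosing) from the closed-form model of
#' [pk_sim_params()], with optional multiplicative log-normal noise.
#' Because the curves are analytic, the returned `truth` element also
#' carries the exact zero-to-infinity AUCs and the targeting metrics
#' they imply — the ground truth a downstream estimator should recover.
#'
#' @param params A [pk_sim_params()] object.
#' @return Object of class `pk_simulation`: list with `profiles` (named
#'   list of four [concentration_profile()]s: `blood_iv`, `brain_iv`,
#'   `blood_in`, `brain_in`), and `truth` (exact AUCs, implied `dte` and
#'   `dtp`, and the generating `params`).
#' @examples
#' sim <- simulate_pk_study(pk_sim_params(f_direct = 0, noise_cv = 0))
#' sim$truth$dte # exactly 100: no direct pathway
#' @export
simulate_pk_study <- function(params) {
  stopifnot(inherits(params, "pk_sim_params"))
  set.seed(params$seed)
  curves <- pk_curves(params)
  t <- params$times
  meta <- list(blood_iv = c("blood", "IV"), brain_iv = c("brain", "IV"),
               blood_in = c("blood", "IN"), brain_in = c("brain", "IN"))
  profiles <- lapply(names(curves), function(nm) {
    conc <- curves[[nm]](t) * lognormal_factors(length(t), params$noise_cv)
    concentration_profile(t, conc, tissue = meta[[nm]][1],
                          route = meta[[nm]][2], group = "simulated")
  })
  names(profiles) <- names(curves)
  auc <- pk_true_auc(params)
  truth <- list(
    auc_inf = auc[c("blood_iv", "brain_iv", "blood_in", "brain_in")],
    dte = dte(auc$brain_in, auc$blood_in, auc$brain_iv, auc$blood_iv),
    dtp = 100 * auc$brain_in_direct / auc$brain_in,
    params = params
  )
  structure(list(profiles = profiles, truth = truth),
            class = "pk_simulation")
}

#' @export
print.pk_simulation <- function(x, ...) {
  cat("simulated PK study:", length(x$profiles), "profiles at",
      length(x$truth$params$times), "times\n")
  cat(sprintf("truth: DTE %.4g%%, DTP %.4g%% (f_direct = %g)\n",
              x$truth$dte, x$truth$dtp, x$truth$params$f_direct))
  invisible(x)
}

#' Simulate a diffusion-cell permeation run
#'
#' Generates sampled receptor concentrations consistent with a
#' cumulative-permeation line `Q(t) = max(0, flux * (t - lag))`,
#' honouring the sampling-replacement bookkeeping that
#' [cumulative_per_area()] inverts, with optional multiplicative noise
#' on the concentrations.
#'
#' @param true_flux Steady-state flux (ug cm^-2 h^-1, >= 0).
#' @param lag_h Lag time before permeation starts (h).
#' @param times_h Sampling times (h).
#' @param donor_dose_ug,area_cm2,receptor_volume_ml,sample_volume_ml,replacement
#'   Cell geometry, see [diffusion_run()].
#' @param noise_cv Multiplicative log-normal noise CV on concentrations.
#' @param seed Integer seed (used when `noise_cv > 0`).
#' @return A [diffusion_run()].
#' @examples
#' run <- simulate_permeation(10.63, times_h = 1:12)
#' steady_state_flux(run$times_h, cumulative_per_area(run)) # 10.63
#' @export
simulate_permeation <- function(true_flux, lag_h = 0, times_h = 1:12,
                                donor_dose_ug = 3000, area_cm2 = 2.5,
                                receptor_volume_ml = 50,
                                sample_volume_ml = 1, replacement = TRUE,
                                noise_cv = 0, seed = 1L) {
  stopifnot(true_flux >= 0, lag_h >= 0)
  set.seed(as.integer(seed))
  q <- pmax(0, true_flux * (as.numeric(times_h) - lag_h))
  conc <- numeric(length(q))
  removed <- 0
  for (i in seq_along(q)) {
    conc[i] <- if (replacement && sample_volume_ml > 0) {
      (q[i] * area_cm2 - removed) / receptor_volume_ml
    } else {
      q[i] * area_cm2 / receptor_volume_ml
    }
    removed <- removed + conc[i] * sample_volume_ml
  }
  conc <- pmax(0, conc * lognormal_factors(length(conc), noise_cv))
  diffusion_run(times_h, conc, donor_dose_ug, area_cm2,
                receptor_volume_ml, sample_volume_ml, replacement)
}
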