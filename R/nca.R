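#' Tissue concentration-time profile
#'
#' Ordered drug concentrations for one tissue, administration route and
#' study group. Times are minutes, concentrations ng/mL.
#'
#' @param time Strictly increasing, non-negative times (min).
#' @param concentration Non-negative concentrations (ng/mL).
#' @param tissue `"brain"` or `"blood"`.
#' @param route `"IV"` or `"IN"`.
#' @param group Formulation/group label.
#' @return An object of class `concentration_profile`.
#' @export
concentration_profile <- function(time, concentration,
                                  tissue = c("brain", "blood"),
                                  route = c("IV", "IN"),
                                  group = "") {
  tissue <- match.arg(tissue)
  route <- match.arg(route)
  time <- as.numeric(time)
  concentration <- as.numeric(concentration)
  stopifnot(length(time) == length(concentration), length(time) >= 1L)
  if (any(time < 0)) stop("times must be non-negative", call. = FALSE)
  if (any(diff(time) == 0)) {
    stop("duplicate times within a profile", call. = FALSE)
  }
  if (any(diff(time) < 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(concentration < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  structure(
    list(time = time, concentration = concentration,
         tissue = tissue, route = route, group = group),
    class = "concentration_profile"
  )
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat(sprintf("%s / %s%s: %d points, t = %g..%g min\n",
              x$tissue, x$route,
              if (nzchar(x$group)) paste0(" (", x$group, ")") else "",
              length(x$time), min(x$time), max(x$time)))
  invisible(x)
}

#' Area under the concentration-time curve (linear trapezoid)
#'
#' Linear trapezoidal integration of the observed profile from its first
#' time up to `t_end`. No extrapolation: if `t_end` exceeds the last
#' observation, integration stops there; if `t_end` falls between
#' observations, the profile is linearly interpolated at `t_end` (the
#' trapezoid rule is exact for piecewise-linear curves, so this keeps
#' the integral additive over adjacent intervals).
#'
#' @param profile A [concentration_profile()] (>= 2 points).
#' @param t_end Upper integration limit (min); default = last observation.
#' @return AUC in ng/mL x min.
#' @examples
#' p <- concentration_profile(c(0, 60), c(0, 600), "blood", "IV")
#' auc_trapezoid(p) # 18000
#' @export
auc_trapezoid <- function(profile, t_end = NULL) {
  stopifnot(inherits(profile, "concentration_profile"))
  t <- profile$time
  c_ <- profile$concentration
  if (length(t) < 2L) {
    stop("AUC needs at least 2 observations", call. = FALSE)
  }
  if (is.null(t_end)) t_end <- t[length(t)]
  if (t_end < t[1]) {
    stop("t_end precedes the first observation", call. = FALSE)
  }
  t_end <- min(t_end, t[length(t)])
  keep <- t <= t_end
  tt <- t[keep]
  cc <- c_[keep]
  if (t_end > tt[length(tt)]) {
    cc <- c(cc, stats::approx(t, c_, xout = t_end)$y)
    tt <- c(tt, t_end)
  }
  if (length(tt) < 2L) return(0)
  sum(diff(tt) * (cc[-1] + cc[-length(cc)]) / 2)
}

#' Terminal elimination rate constant
#'
#' Log-linear regression over the last `n_points` observations:
#' `Ke = -slope` of `ln C` versus `t`, with half-life `t1/2 = ln 2 / Ke`.
#' Exact for noiseless mono-exponential decay at any sampling grid.
#'
#' @param profile A [concentration_profile()].
#' @param n_points Number of terminal points (default 3).
#' @return List with `ke` (min^-1), `t_half` (min), `n_points`.
#' @examples
#' t <- c(120, 240, 480)
#' p <- concentration_profile(t, 100 * exp(-0.017 * t), "blood", "IV")
#' terminal_ke(p)$ke # 0.017
#' @export
terminal_ke <- function(profile, n_points = 3) {
  stopifnot(inherits(profile, "concentration_profile"), n_points >= 2)
  n <- length(profile$time)
  if (n < n_points) {
    stop("profile has fewer than ", n_points, " observations", call. = FALSE)
  }
  idx <- seq.int(n - n_points + 1L, n)
  cc <- profile$concentration[idx]
  if (any(cc <= 0)) {
    stop("terminal window contains non-positive concentrations; ",
         "shorten n_points or trim the profile", call. = FALSE)
  }
  t <- profile$time[idx]
  slope <- stats::cov(t, log(cc)) / stats::var(t)
  if (slope >= 0) {
    stop("terminal slope is non-negative (no apparent elimination phase); ",
         sprintf("window t = %g..%g min", t[1], t[length(t)]), call. = FALSE)
  }
  ke <- -slope
  list(ke = ke, t_half = log(2) / ke, n_points = n_points)
}

#' Peak concentration and its time
#'
#' Maximum observed concentration and the earliest time attaining it
#' (plateaus resolve to their first time).
#'
#' @param profile A [concentration_profile()].
#' @return List with `cmax` (ng/mL) and `tmax` (min).
#' @export
cmax_tmax <- function(profile) {
  stopifnot(inherits(profile, "concentration_profile"))
  i <- which.max(profile$concentration)
  list(cmax = profile$concentration[i], tmax = profile$time[i])
}

#' Non-compartmental summary of a profile
#'
#' @param profile A [concentration_profile()].
#' @param t_end AUC horizon (min), see [auc_trapezoid()].
#' @param ke_points Terminal window size, see [terminal_ke()].
#' @return List of class `nca_result`: `cmax`, `tmax`, `ke`, `t_half`,
#'   `auc`, plus `tissue`/`route`/`group` labels.
#' @export
nca <- function(profile, t_end = NULL, ke_points = 3) {
  pk <- cmax_tmax(profile)
  ke <- terminal_ke(profile, ke_points)
  structure(
    list(tissue = profile$tissue, route = profile$route,
         group = profile$group,
         cmax = pk$cmax, tmax = pk$tmax,
         ke = ke$ke, t_half = ke$t_half,
         auc = auc_trapezoid(profile, t_end)),
    class = "nca_result"
  )
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf(
    "%s/%s%s: Cmax %.4g ng/mL at Tmax %g min, Ke %.4g /min (t1/2 %.4g min), AUC %.6g ng/mL*min\n",
    x$tissue, x$route,
    if (nzchar(x$group)) paste0(" (", x$group, ")") else "",
    x$cmax, x$tmax, x$ke, x$t_half, x$auc))
  invisible(x)
}

#' Brain-to-blood concentration ratio at a time point
#'
#' By default both profiles must contain an observation exactly at `t`.
#' With `interpolate = TRUE`, concentrations are log-linearly
#' interpolated between bracketing observations (falling back to linear
#' when a bracketing concentration is zero).
#'
#' @param brain,blood [concentration_profile()] objects.
#' @param t Time (min).
#' @param interpolate Allow interpolation between observations.
#' @return Scalar ratio `C_brain(t) / C_blood(t)`.
#' @export
brain_blood_ratio <- function(brain, blood, t, interpolate = FALSE) {
  conc_at <- function(p) {
    i <- which(p$time == t)
    if (length(i) == 1L) return(p$concentration[i])
    if (!interpolate) {
      stop(sprintf("no observation at t = %g min in the %s/%s profile",
                   t, p$tissue, p$route), call. = FALSE)
    }
    if (t < p$time[1] || t > p$time[length(p$time)]) {
      stop(sprintf("t = %g min outside the %s/%s profile", t, p$tissue,
                   p$route), call. = FALSE)
    }
    j <- findInterval(t, p$time)
    c1 <- p$concentration[j]; c2 <- p$concentration[j + 1]
    if (c1 > 0 && c2 > 0) {
      exp(stats::approx(p$time[j:(j + 1)], log(c(c1, c2)), xout = t)$y)
    } else {
      stats::approx(p$time[j:(j + 1)], c(c1, c2), xout = t)$y
    }
  }
  cb <- conc_at(brain)
  cp <- conc_at(blood)
  if (cp == 0) stop("blood concentration is zero at t = ", t, call. = FALSE)
  cb / cp
}

#' Drug targeting efficiency (DTE%)
#'
#' Ratio of the intranasal to the intravenous brain/blood AUC quotients,
#' times 100. A value of 100 means the nasal route confers no
#' preferential brain exposure beyond systemic redistribution.
#'
#' @param auc_brain_in,auc_blood_in Brain and blood AUC0-t after
#'   intranasal dosing (> 0).
#' @param auc_brain_iv,auc_blood_iv The same after intravenous dosing.
#' @return DTE in percent.
#' @examples
#' dte(469403, 385609, 74944, 313493) # 509.2
#' @export
dte <- function(auc_brain_in, auc_blood_in, auc_brain_iv, auc_blood_iv) {
  if (any(c(auc_brain_in, auc_blood_in, auc_brain_iv, auc_blood_iv) <= 0)) {
    stop("all four AUC values must be positive", call. = FALSE)
  }
  100 * (auc_brain_in / auc_blood_in) / (auc_brain_iv / auc_blood_iv)
}

#' Direct transport percentage (DTP%)
#'
#' Fraction of intranasal brain exposure not attributable to
#' redistribution from blood: with
#' `Bx = (AUC_brain_IV / AUC_blood_IV) * AUC_blood_IN`,
#' `DTP = 100 * (AUC_brain_IN - Bx) / AUC_brain_IN`. Algebraically
#' `DTP = 100 * (1 - 100/DTE)`.
#'
#' @inheritParams dte
#' @return DTP in percent (<= 100; negative when the nasal route
#'   under-delivers to brain).
#' @examples
#' dtp(469403, 385609, 74944, 313493) # 80.4
#' @export
dtp <- function(auc_brain_in, auc_blood_in, auc_brain_iv, auc_blood_iv) {
  if (auc_brain_in <= 0 || auc_blood_iv <= 0) {
    stop("AUC_brain(IN) and AUC_blood(IV) must be positive", call. = FALSE)
  }
  bx <- (auc_brain_iv / auc_blood_iv) * auc_blood_in
  100 * (auc_brain_in - bx) / auc_brain_in
}

#' Nose-to-brain targeting metrics for one intranasal group
#'
#' Full targeting panel from four concentration profiles: the intranasal
#' group's brain and blood profiles plus an intravenous reference pair.
#' Computes per-profile non-compartmental summaries, the brain/blood
#' concentration ratio at `t_ratio`, per-route AUC_brain/AUC_blood
#' quotients, and DTE/DTP with the intermediate `Bx`.
#'
#' @param brain_in,blood_in,brain_iv,blood_iv [concentration_profile()]s.
#' @param t_ratio Time for the concentration ratio (min, default 30).
#' @param t_end AUC horizon (min, default 480).
#' @param ke_points Terminal window size.
#' @param interpolate Passed to [brain_blood_ratio()].
#' @return List of class `targeting_metrics`: `nca` (list of four
#'   `nca_result`s), `conc_ratio_in`, `auc_ratio_in`, `auc_ratio_iv`,
#'   `bx`, `dte`, `dtp`.
#' @export
targeting_metrics <- function(brain_in, blood_in, brain_iv, blood_iv,
                              t_ratio = 30, t_end = 480, ke_points = 3,
                              interpolate = FALSE) {
  profs <- list(brain_in = brain_in, blood_in = blood_in,
                brain_iv = brain_iv, blood_iv = blood_iv)
  expected <- list(brain_in = c("brain", "IN"), blood_in = c("blood", "IN"),
                   brain_iv = c("brain", "IV"), blood_iv = c("blood", "IV"))
  for (nm in names(profs)) {
    p <- profs[[nm]]
    stopifnot(inherits(p, "concentration_profile"))
    if (p$tissue != expected[[nm]][1] || p$route != expected[[nm]][2]) {
      stop("profile '", nm, "' should be ", expected[[nm]][1], "/",
           expected[[nm]][2], " but is ", p$tissue, "/", p$route,
           call. = FALSE)
    }
  }
  res <- lapply(profs, nca, t_end = t_end, ke_points = ke_points)
  aucs <- vapply(res, `[[`, numeric(1), "auc")
  structure(
    list(
      nca = res,
      conc_ratio_in = brain_blood_ratio(brain_in, blood_in, t_ratio,
                                        interpolate = interpolate),
      auc_ratio_in = aucs[["brain_in"]] / aucs[["blood_in"]],
      auc_ratio_iv = aucs[["brain_iv"]] / aucs[["blood_iv"]],
      bx = (aucs[["brain_iv"]] / aucs[["blood_iv"]]) * aucs[["blood_in"]],
      dte = dte(aucs[["brain_in"]], aucs[["blood_in"]],
                aucs[["brain_iv"]], aucs[["blood_iv"]]),
      dtp = dtp(aucs[["brain_in"]], aucs[["blood_in"]],
                aucs[["brain_iv"]], aucs[["blood_iv"]]),
      t_ratio = t_ratio, t_end = t_end
    ),
    class = "targeting_metrics"
  )
}

#' @export
print.targeting_metrics <- function(x, ...) {
  for (r in x$nca) print(r)
  cat(sprintf("C_brain/C_blood at %g min (IN): %.3g\n", x$t_ratio,
              x$conc_ratio_in))
  cat(sprintf("AUC_brain/AUC_blood: IN %.3g, IV %.3g\n",
              x$auc_ratio_in, x$auc_ratio_iv))
  cat(sprintf("DTE %.4g%%  DTP %.4g%%\n", x$dte, x$dtp))
  invisible(x)
}
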