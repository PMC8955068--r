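#' Derringer desirability of a single response
#'
#' One-sided desirability on anchors `lower` < `upper`:
#' for `goal = "maximize"`, `d = ((y - lower)/(upper - lower))^weight`;
#' for `goal = "minimize"`, `d = ((upper - y)/(upper - lower))^weight`;
#' both clipped into `[0, 1]` so out-of-range predictions are handled
#' gracefully.
#'
#' @param value Numeric vector of response values (original scale).
#' @param goal `"minimize"` or `"maximize"`.
#' @param lower,upper Anchor values on the response scale (`lower < upper`).
#' @param weight Positive exponent (default 1, linear ramp).
#' @return Desirabilities in `[0, 1]`.
#' @examples
#' desirability(119.8, "minimize", 107.2, 230.8) # 0.898
#' @export
desirability <- function(value, goal = c("maximize", "minimize"),
                         lower, upper, weight = 1) {
  goal <- match.arg(goal)
  stopifnot(length(lower) == 1L, length(upper) == 1L, weight > 0)
  if (!(lower < upper)) {
    stop("desirability anchors require lower < upper", call. = FALSE)
  }
  frac <- switch(goal,
    maximize = (value - lower) / (upper - lower),
    minimize = (upper - value) / (upper - lower)
  )
  pmin(1, pmax(0, frac))^weight
}

#' Overall desirability
#'
#' Geometric mean of the individual desirabilities; zero whenever any
#' single desirability is zero.
#'
#' @param d Numeric vector of desirabilities in `[0, 1]`.
#' @return Scalar overall desirability `D` in `[0, 1]`.
#' @export
overall_desirability <- function(d) {
  d <- as.numeric(d)
  if (!length(d)) stop("no desirabilities supplied", call. = FALSE)
  if (any(d < 0 | d > 1)) {
    stop("individual desirabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(d == 0)) return(0)
  exp(mean(log(d)))
}

#' Per-response goal specification for multi-response optimization
#'
#' @param goal `"minimize"` or `"maximize"`.
#' @param lower,upper Optional anchors; when omitted they default at
#'   optimization time to the observed response range over the design.
#' @param weight Positive exponent (default 1).
#' @return A list of class `desirability_goal`.
#' @export
desirability_goal <- function(goal = c("maximize", "minimize"),
                              lower = NULL, upper = NULL, weight = 1) {
  goal <- match.arg(goal)
  stopifnot(weight > 0)
  if (!is.null(lower) && !is.null(upper) && !(lower < upper)) {
    stop("desirability anchors require lower < upper", call. = FALSE)
  }
  structure(list(goal = goal, lower = lower, upper = upper, weight = weight),
            class = "desirability_goal")
}

#' Multi-response desirability optimization over the coded cube
#'
#' Maximizes the overall desirability of several fitted response-surface
#' models over the coded factor cube `[-1, 1]^3` by a dense grid search
#' followed by a Nelder-Mead polish (coordinates clamped to the cube).
#' The procedure is fully deterministic. A model whose prediction leaves
#' its transform's domain at a candidate point contributes desirability
#' zero there. Grid ties are broken by the smallest prediction of the
#' first minimize-goal response, then by lexicographic coded coordinates.
#'
#' Anchors default to the observed minimum/maximum of each model's
#' response over the design, the conventional software default.
#'
#' @param models Named list of `rsm_fit` objects sharing one design.
#' @param goals Named list of [desirability_goal()]s, names matching
#'   `models`.
#' @param grid_n Grid points per axis for the initial search.
#' @param reltol Relative convergence tolerance of the polish step.
#' @return Object of class `desirability_optimum`: list with
#'   `coded` (optimal coded point), `actual` (factor settings in
#'   laboratory units), `predictions`, `desirabilities`, `overall`, and
#'   the `anchors` used.
#' @examples
#' runs <- berberine_runs()
#' des <- as_bbd_design(runs, berberine_factors())
#' mods <- list(
#'   PS  = fit_rsm(des, runs$PS, "linear", "sqrt", response_name = "PS"),
#'   CDR = fit_rsm(des, runs$CDR, "linear", "identity", response_name = "CDR")
#' )
#' goals <- list(PS = desirability_goal("minimize"),
#'               CDR = desirability_goal("maximize"))
#' optimize_desirability(mods, goals)
#' @export
optimize_desirability <- function(models, goals, grid_n = 41, reltol = 1e-6) {
  stopifnot(is.list(models), length(models) >= 1L,
            all(vapply(models, inherits, logical(1), "rsm_fit")))
  if (is.null(names(models)) || is.null(names(goals)) ||
      !setequal(names(models), names(goals))) {
    stop("'models' and 'goals' must be named lists over the same responses",
         call. = FALSE)
  }
  goals <- goals[names(models)]
  anchors <- lapply(names(models), function(nm) {
    g <- goals[[nm]]
    list(
      lower = if (is.null(g$lower)) min(models[[nm]]$response) else g$lower,
      upper = if (is.null(g$upper)) max(models[[nm]]$response) else g$upper
    )
  })
  names(anchors) <- names(models)

  # vectorized prediction: NA where the inverse transform's domain fails
  predict_points <- function(m, pts) {
    eta <- drop(term_matrix(pts, m$terms) %*% m$coefficients)
    if (m$transform == "identity") return(eta)
    out <- rep(NA_real_, length(eta))
    ok <- eta > 0
    out[ok] <- inverse_transform(eta[ok], m$transform)
    out
  }
  predict_all <- function(pt) {
    pt <- matrix(pt, nrow = 1, dimnames = list(NULL, c("x1", "x2", "x3")))
    vapply(models, predict_points, numeric(1), pts = pt)
  }
  d_cols <- function(pred_mat) {
    vapply(names(models), function(nm) {
      p <- pred_mat[, nm]
      d <- desirability(p, goals[[nm]]$goal, anchors[[nm]]$lower,
                        anchors[[nm]]$upper, goals[[nm]]$weight)
      d[is.na(p)] <- 0
      d
    }, numeric(nrow(pred_mat)))
  }
  D_of <- function(pt) {
    overall_desirability(drop(d_cols(t(as.matrix(predict_all(pt))))))
  }

  # dense grid, evaluated in one vectorized pass per model
  g <- seq(-1, 1, length.out = grid_n)
  grid <- as.matrix(expand.grid(x1 = g, x2 = g, x3 = g))
  preds <- vapply(models, predict_points, numeric(nrow(grid)), pts = grid)
  dmat <- d_cols(preds)
  zero <- rowSums(dmat == 0) > 0
  Dg <- numeric(nrow(dmat))
  Dg[!zero] <- exp(rowMeans(log(dmat[!zero, , drop = FALSE])))
  best <- max(Dg)
  cand <- which(Dg >= best - 1e-12)
  if (length(cand) > 1L) {
    min_goal <- names(models)[vapply(goals, function(g) g$goal, "") == "minimize"]
    key1 <- if (length(min_goal)) preds[cand, min_goal[1]] else rep(0, length(cand))
    ord <- order(key1, grid[cand, 1], grid[cand, 2], grid[cand, 3])
    cand <- cand[ord]
  }
  start <- grid[cand[1], ]

  clamp <- function(p) pmin(1, pmax(-1, p))
  opt <- stats::optim(start, function(p) -D_of(clamp(p)),
                      method = "Nelder-Mead",
                      control = list(reltol = reltol, maxit = 2000))
  polished <- clamp(opt$par)
  if (-opt$value < best) polished <- start  # polish may not improve a vertex
  preds <- predict_all(polished)
  dvals <- drop(d_cols(t(as.matrix(preds))))

  factors <- models[[1]]$design$factors
  actual <- vapply(seq_along(factors),
                   function(j) to_actual(factors[[j]], polished[j]), numeric(1))
  names(actual) <- names(factors)

  structure(
    list(coded = stats::setNames(as.numeric(polished), c("x1", "x2", "x3")),
         actual = actual,
         predictions = preds,
         desirabilities = dvals,
         overall = overall_desirability(dvals),
         anchors = anchors,
         grid_n = grid_n),
    class = "desirability_optimum"
  )
}

#' @export
print.desirability_optimum <- function(x, ...) {
  cat(sprintf("overall desirability D = %.3f at coded (%s)\n", x$overall,
              paste(sprintf("%.3f", x$coded), collapse = ", ")))
  for (nm in names(x$actual)) {
    cat(sprintf("  %-12s %.4g\n", nm, x$actual[[nm]]))
  }
  for (nm in names(x$predictions)) {
    cat(sprintf("  predicted %-8s %.4g (d = %.3f)\n", nm,
                x$predictions[[nm]], x$desirabilities[[nm]]))
  }
  invisible(x)
}

#' Percent prediction error of a model against experiment
#'
#' `100 * (experimental - predicted) / experimental`, the conventional
#' report for validating an optimized formulation against the model's
#' point prediction.
#'
#' @param experimental Measured value (non-zero).
#' @param predicted Model prediction on the same scale.
#' @return Signed percent error.
#' @examples
#' prediction_error(142.1, 119.8) # 15.7
#' @export
prediction_error <- function(experimental, predicted) {
  if (any(experimental == 0)) {
    stop("prediction error undefined for experimental value 0", call. = FALSE)
  }
  100 * (experimental - predicted) / experimental
}
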