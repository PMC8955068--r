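#' Define a design factor
#'
#' A factor is described by its name, its low and high levels in actual
#' (laboratory) units, and an optional units label. The mid level is the
#' arithmetic mean of low and high; coded units map low/mid/high onto
#' -1/0/+1.
#'
#' @param name Factor name, used as a column header in design tables.
#' @param low,high Low and high levels in actual units; `low < high`.
#' @param units Optional units label (e.g. `"mg"`).
#' @return An object of class `factor_def`.
#' @examples
#' gms <- factor_def("GMS", 100, 200, "mg")
#' to_coded(gms, 150) # 0
#' @export
factor_def <- function(name, low, high, units = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  low <- as.numeric(low)
  high <- as.numeric(high)
  if (!is.finite(low) || !is.finite(high) || low >= high) {
    stop("factor '", name, "': low level must be strictly below high level",
         call. = FALSE)
  }
  structure(
    list(name = name, low = low, high = high, units = units),
    class = "factor_def"
  )
}

#' @export
print.factor_def <- function(x, ...) {
  cat(sprintf("factor %s: %g / %g / %g %s (coded -1 / 0 / +1)\n",
              x$name, x$low, (x$low + x$high) / 2, x$high, x$units))
  invisible(x)
}

#' Map actual factor values to coded units
#'
#' Coded units place the low, mid and high levels at -1, 0 and +1:
#' `coded = (actual - centre) / half_range`. Values outside `[-1, 1]`
#' are allowed (extrapolation) and flagged with a warning.
#'
#' @param factor A [factor_def()].
#' @param actual Numeric vector in actual units.
#' @return Numeric vector of coded values.
#' @seealso [to_actual()] for the exact inverse.
#' @export
to_coded <- function(factor, actual) {
  stopifnot(inherits(factor, "factor_def"))
  centre <- (factor$low + factor$high) / 2
  half <- (factor$high - factor$low) / 2
  coded <- (as.numeric(actual) - centre) / half
  out <- abs(coded) > 1 + 1e-8
  if (any(out, na.rm = TRUE)) {
    warning("factor '", factor$name, "': ", sum(out),
            " value(s) outside the design range (|coded| > 1)", call. = FALSE)
  }
  coded
}

#' Map coded factor values back to actual units
#'
#' Exact functional inverse of [to_coded()]:
#' `actual = centre + coded * half_range`.
#'
#' @inheritParams to_coded
#' @param coded Numeric vector of coded values.
#' @return Numeric vector in actual units.
#' @export
to_actual <- function(factor, coded) {
  stopifnot(inherits(factor, "factor_def"))
  centre <- (factor$low + factor$high) / 2
  half <- (factor$high - factor$low) / 2
  centre + as.numeric(coded) * half
}

#' Construct a three-factor Box-Behnken design
#'
#' The three-factor Box-Behnken design places runs at the midpoints of the
#' twelve edges of the coded cube (all sign combinations of two factors at
#' +/-1 with the third at 0) plus replicated centre points. With five
#' centre replicates this gives the classical 17-run design.
#'
#' Rows are ordered canonically: edge blocks by the index of the factor
#' held at zero (x1 block first), signs in lexicographic order within a
#' block, and centre replicates last. Coded levels are stored exactly as
#' -1, 0, +1 so that orthogonality checks are free of floating-point
#' drift.
#'
#' @param factors List of exactly three [factor_def()] objects.
#' @param center_replicates Number of centre-point replicates (>= 0).
#' @return An object of class `bbd_design`: a list with elements
#'   `factors`, `coded` (n x 3 matrix, columns `x1`, `x2`, `x3`),
#'   `actual` (data frame in laboratory units) and `is_center`
#'   (logical vector).
#' @examples
#' des <- bbd_design(berberine_factors(), center_replicates = 5)
#' nrow(des$coded) # 17
#' @export
bbd_design <- function(factors, center_replicates = 5) {
  if (!is.list(factors) || length(factors) != 3L ||
      !all(vapply(factors, inherits, logical(1), "factor_def"))) {
    stop("unsupported design: exactly 3 factor_def objects are required",
         call. = FALSE)
  }
  stopifnot(length(center_replicates) == 1L, center_replicates >= 0)
  center_replicates <- as.integer(center_replicates)

  signs <- as.matrix(expand.grid(s2 = c(-1, 1), s1 = c(-1, 1)))[, c("s1", "s2")]
  signs <- signs[order(signs[, 1], signs[, 2]), , drop = FALSE]
  edge <- NULL
  for (zero_idx in 1:3) {
    block <- matrix(0, nrow = 4, ncol = 3)
    block[, setdiff(1:3, zero_idx)] <- signs
    edge <- rbind(edge, block)
  }
  coded <- rbind(edge, matrix(0, nrow = center_replicates, ncol = 3))
  colnames(coded) <- c("x1", "x2", "x3")
  rownames(coded) <- NULL

  new_bbd_design(factors, coded,
                 is_center = c(rep(FALSE, 12), rep(TRUE, center_replicates)))
}

new_bbd_design <- function(factors, coded, is_center) {
  names(factors) <- vapply(factors, `[[`, character(1), "name")
  actual <- as.data.frame(
    mapply(function(f, j) to_actual(f, coded[, j]),
           factors, seq_along(factors), SIMPLIFY = FALSE),
    optional = TRUE
  )
  names(actual) <- names(factors)
  structure(
    list(factors = factors, coded = coded, actual = actual,
         is_center = is_center),
    class = "bbd_design"
  )
}

#' Build a design object from observed factor settings
#'
#' Converts a table of runs in actual units into a `bbd_design` by coding
#' each factor column. Coded values numerically indistinguishable from
#' -1, 0 or +1 are snapped to those exact levels so that designs read
#' back from CSV retain exact orthogonality.
#'
#' @param runs Data frame with one column per factor (actual units).
#' @param factors List of three [factor_def()] objects whose names match
#'   columns of `runs`.
#' @param snap_tol Absolute tolerance for snapping to design levels.
#' @return A `bbd_design` (rows in the order of `runs`).
#' @export
as_bbd_design <- function(runs, factors, snap_tol = 1e-6) {
  if (!is.list(factors) || length(factors) != 3L ||
      !all(vapply(factors, inherits, logical(1), "factor_def"))) {
    stop("unsupported design: exactly 3 factor_def objects are required",
         call. = FALSE)
  }
  fnames <- vapply(factors, `[[`, character(1), "name")
  missing <- setdiff(fnames, names(runs))
  if (length(missing)) {
    stop("design table lacks factor column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  coded <- vapply(seq_along(factors), function(j) {
    v <- suppressWarnings(to_coded(factors[[j]], runs[[fnames[j]]]))
    for (lev in c(-1, 0, 1)) v[abs(v - lev) < snap_tol] <- lev
    v
  }, numeric(nrow(runs)))
  coded <- matrix(coded, ncol = 3, dimnames = list(NULL, c("x1", "x2", "x3")))
  new_bbd_design(factors, coded, is_center = rowSums(coded != 0) == 0)
}

#' @export
print.bbd_design <- function(x, ...) {
  cat(sprintf("Box-Behnken design: %d runs (%d edge, %d centre)\n",
              nrow(x$coded), sum(!x$is_center), sum(x$is_center)))
  cat("factors:", paste(names(x$factors), collapse = ", "), "\n")
  invisible(x)
}

#' Export a design as a data frame
#'
#' @param x A `bbd_design`.
#' @param row.names,optional Ignored; present for S3 compatibility.
#' @param ... Unused.
#' @return Data frame with actual-unit columns followed by parallel
#'   `coded_*` columns.
#' @export
as.data.frame.bbd_design <- function(x, row.names = NULL, optional = FALSE, ...) {
  coded <- as.data.frame(x$coded)
  names(coded) <- paste0("coded_", names(x$factors))
  cbind(x$actual, coded)
}
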