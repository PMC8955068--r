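#' Response transforms for surface modelling
#'
#' Models are fitted on a transformed response scale. Three transforms
#' are supported: `identity`, `sqrt` (requires strictly positive
#' responses) and `inverse` (1/y, requires non-zero responses).
#'
#' @param x Numeric vector of responses (original scale).
#' @param kind One of `"identity"`, `"sqrt"`, `"inverse"`.
#' @param labels Optional run labels used in domain-error messages.
#' @return Transformed numeric vector.
#' @seealso [inverse_transform()]
#' @examples
#' apply_transform(230.8, "sqrt")   # 15.1921...
#' apply_transform(54.1, "inverse") # 0.018484...
#' @export
apply_transform <- function(x, kind = c("identity", "sqrt", "inverse"),
                            labels = NULL) {
  kind <- match.arg(kind)
  x <- as.numeric(x)
  if (is.null(labels)) labels <- seq_along(x)
  bad <- switch(kind,
    identity = rep(FALSE, length(x)),
    sqrt = x <= 0,
    inverse = x == 0
  )
  if (any(bad, na.rm = TRUE)) {
    stop("transform '", kind, "' undefined for run(s) ",
         paste(labels[which(bad)], collapse = ", "), call. = FALSE)
  }
  switch(kind, identity = x, sqrt = sqrt(x), inverse = 1 / x)
}

#' Invert a response transform
#'
#' Exact functional inverse of [apply_transform()]: squaring for `sqrt`,
#' reciprocal for `inverse`. For `sqrt` and `inverse` the transformed
#' value must be strictly positive for the inverse to land back on the
#' original response scale.
#'
#' @param x Numeric vector on the transformed scale.
#' @inheritParams apply_transform
#' @return Numeric vector on the original response scale.
#' @export
inverse_transform <- function(x, kind = c("identity", "sqrt", "inverse"),
                              labels = NULL) {
  kind <- match.arg(kind)
  x <- as.numeric(x)
  if (is.null(labels)) labels <- seq_along(x)
  if (kind != "identity") {
    bad <- x <= 0
    if (any(bad, na.rm = TRUE)) {
      stop("inverse of transform '", kind,
           "' undefined for non-positive value(s) at ",
           paste(labels[which(bad)], collapse = ", "), call. = FALSE)
    }
  }
  switch(kind, identity = x, sqrt = x^2, inverse = 1 / x)
}
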