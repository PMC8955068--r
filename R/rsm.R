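#' @title Polynomial term sets for response-surface models
#'
#' @description Terms are labelled `x1`, `x2`, `x3` (linear), `x1:x2`,
#' `x1:x3`, `x2:x3` (two-way interactions) and `x1^2`, `x2^2`, `x3^2`
#' (pure quadratics). The intercept is always present and is not listed.
#' Term sets obey weak heredity: an interaction requires both parent
#' linear terms and a square term requires its linear parent.
#'
#' @param terms `"linear"`, `"quadratic"`, or a character vector of term
#'   labels.
#' @return Character vector of validated term labels.
#' @examples
#' rsm_terms("linear")
#' rsm_terms(c("x1", "x2", "x3", "x1:x3", "x1^2", "x2^2", "x3^2"))
#' @export
rsm_terms <- function(terms = "linear") {
  if (identical(terms, "linear")) terms <- c("x1", "x2", "x3")
  if (identical(terms, "quadratic")) {
    terms <- c("x1", "x2", "x3", "x1:x2", "x1:x3", "x2:x3",
               "x1^2", "x2^2", "x3^2")
  }
  all_terms <- c("x1", "x2", "x3", "x1:x2", "x1:x3", "x2:x3",
                 "x1^2", "x2^2", "x3^2")
  bad <- setdiff(terms, all_terms)
  if (length(bad)) {
    stop("unknown term(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  terms <- all_terms[all_terms %in% terms]
  for (t in terms) {
    need <- term_parents(t)
    if (!all(need %in% terms)) {
      stop("term '", t, "' requires parent term(s): ",
           paste(setdiff(need, terms), collapse = ", "), call. = FALSE)
    }
  }
  terms
}

term_parents <- function(term) {
  if (grepl(":", term, fixed = TRUE)) {
    strsplit(term, ":", fixed = TRUE)[[1]]
  } else if (grepl("^", term, fixed = TRUE)) {
    sub("\\^2$", "", term)
  } else {
    character(0)
  }
}

# model matrix (including intercept) for a coded matrix and term labels
term_matrix <- function(coded, terms) {
  cols <- lapply(terms, function(t) {
    if (grepl(":", t, fixed = TRUE)) {
      p <- strsplit(t, ":", fixed = TRUE)[[1]]
      coded[, p[1]] * coded[, p[2]]
    } else if (grepl("^", t, fixed = TRUE)) {
      coded[, sub("\\^2$", "", t)]^2
    } else {
      coded[, t]
    }
  })
  X <- cbind(rep(1, nrow(coded)), do.call(cbind, cols))
  colnames(X) <- c("(Intercept)", terms)
  X
}

#' Fit a transformed response-surface model on coded factors
#'
#' Ordinary least squares of the transformed response on the requested
#' polynomial terms of the coded factor settings. This is the model used
#' for three-level factorial nanoparticle formulation studies: responses
#' such as particle size or entrapment efficiency are first transformed
#' (square root, reciprocal or left untouched) and a low-order polynomial
#' in coded units is fitted.
#'
#' @param design A [bbd_design()] (rows aligned with `response`).
#' @param response Numeric vector of responses in original units.
#' @param terms Term set, see [rsm_terms()].
#' @param transform `"identity"`, `"sqrt"` or `"inverse"`.
#' @param response_name Label carried into reports.
#' @return Object of class `rsm_fit` with elements `coefficients`
#'   (named, transformed scale, coded units), `terms`, `transform`,
#'   `fitted` / `residuals` (transformed scale), `df_residual`,
#'   `response`, `response_name` and the originating `design`.
#' @examples
#' runs <- berberine_runs()
#' des <- as_bbd_design(runs, berberine_factors())
#' fit <- fit_rsm(des, runs$PS, terms = "linear", transform = "sqrt",
#'                response_name = "PS")
#' coef(fit) # intercept 12.7979, x1 1.87247, ...
#' @export
fit_rsm <- function(design, response, terms = "linear",
                    transform = c("identity", "sqrt", "inverse"),
                    response_name = deparse(substitute(response))) {
  stopifnot(inherits(design, "bbd_design"))
  transform <- match.arg(transform)
  terms <- rsm_terms(terms)
  n <- nrow(design$coded)
  response <- as.numeric(response)
  if (length(response) != n) {
    stop("response length (", length(response),
         ") does not match design rows (", n, ")", call. = FALSE)
  }
  p <- length(terms) + 1L
  if (n < p + 1L) {
    stop("too few runs (", n, ") for ", p, " model terms", call. = FALSE)
  }
  y <- apply_transform(response, transform)
  X <- term_matrix(design$coded, terms)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop("singular fit: model matrix is rank deficient (rank ", qx$rank,
         " < ", ncol(X), " terms)", call. = FALSE)
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  structure(
    list(
      coefficients = beta,
      terms = terms,
      transform = transform,
      response = response,
      response_transformed = y,
      fitted = fitted,
      residuals = res,
      df_residual = n - p,
      hat = rowSums(qr.Q(qx)^2),
      response_name = response_name,
      design = design
    ),
    class = "rsm_fit"
  )
}

#' @export
coef.rsm_fit <- function(object, ...) object$coefficients

#' @export
print.rsm_fit <- function(x, digits = 6, ...) {
  lhs <- switch(x$transform,
    identity = x$response_name,
    sqrt = paste0("sqrt(", x$response_name, ")"),
    inverse = paste0("1/(", x$response_name, ")")
  )
  b <- x$coefficients
  rhs <- paste0(
    format(b[1], digits = digits),
    paste0(vapply(seq_along(x$terms), function(i) {
      v <- b[i + 1]
      sprintf(" %s %s*%s", if (v < 0) "-" else "+",
              format(abs(v), digits = digits), x$terms[i])
    }, character(1)), collapse = "")
  )
  cat(lhs, "=", rhs, "\n")
  cat(sprintf("residual df %d, transform '%s'\n", x$df_residual, x$transform))
  invisible(x)
}

#' Predict from a response-surface model
#'
#' Evaluates the fitted polynomial at coded points and back-transforms to
#' the original response scale (square for a `sqrt` model, reciprocal for
#' an `inverse` model). Points far outside the coded cube are rejected
#' unless extrapolation is requested.
#'
#' @param object An `rsm_fit`.
#' @param newdata Numeric vector of length 3, or a matrix/data frame with
#'   columns `x1`, `x2`, `x3` of coded coordinates. Defaults to the
#'   design points.
#' @param extrapolate Allow coordinates outside `[-1.2, 1.2]`.
#' @param ... Unused.
#' @return Numeric vector of predictions on the original response scale.
#' @export
predict.rsm_fit <- function(object, newdata = NULL, extrapolate = FALSE, ...) {
  if (is.null(newdata)) {
    coded <- object$design$coded
  } else {
    if (is.numeric(newdata) && is.null(dim(newdata))) {
      newdata <- matrix(newdata, nrow = 1)
    }
    coded <- as.matrix(newdata)
    if (ncol(coded) != 3L) stop("coded points must have 3 columns", call. = FALSE)
    colnames(coded) <- c("x1", "x2", "x3")
  }
  if (!extrapolate && any(abs(coded) > 1.2 + 1e-12)) {
    stop("coded point outside [-1.2, 1.2]^3; set extrapolate = TRUE to allow",
         call. = FALSE)
  }
  eta <- drop(term_matrix(coded, object$terms) %*% object$coefficients)
  inverse_transform(eta, object$transform)
}

replicate_groups <- function(design) {
  key <- apply(design$coded, 1, paste, collapse = "/")
  split(seq_along(key), key)
}

#' Type III analysis of variance for a response-surface model
#'
#' Per-term F tests from partial (drop-one-term) sums of squares, the
#' overall model F test, and a lack-of-fit test that partitions the
#' residual sum of squares into pure error (within replicate groups, on
#' the transformed scale) and lack of fit. On the orthogonal linear block
#' of a Box-Behnken design the partial sums of squares coincide with
#' sequential ones.
#'
#' @param model An `rsm_fit`.
#' @return Object of class `rsm_anova`: list with `terms` (data frame:
#'   term, ss, df, statistic, p_value), `model` (F test), `lack_of_fit`
#'   (F test with `df_lof`, `df_pe`, `available`), and the underlying
#'   sums of squares `ss`.
#' @examples
#' runs <- berberine_runs()
#' des <- as_bbd_design(runs, berberine_factors())
#' fit <- fit_rsm(des, runs$PS, "linear", "sqrt", response_name = "PS")
#' anova_type3(fit)$model$statistic # about 416.5
#' @export
anova_type3 <- function(model) {
  stopifnot(inherits(model, "rsm_fit"))
  design <- model$design
  y <- model$response_transformed
  n <- length(y)
  sse <- sum(model$residuals^2)
  sst <- sum((y - mean(y))^2)
  ssr <- sst - sse
  df_res <- model$df_residual
  mse <- sse / df_res
  X <- term_matrix(design$coded, model$terms)

  drop_ss <- vapply(model$terms, function(t) {
    keep <- c("(Intercept)", setdiff(model$terms, t))
    sse_red <- sum(qr.resid(qr(X[, keep, drop = FALSE]), y)^2)
    sse_red - sse
  }, numeric(1))
  term_tab <- data.frame(
    term = model$terms,
    ss = unname(drop_ss),
    df = 1L,
    statistic = unname(drop_ss) / mse,
    p_value = stats::pf(unname(drop_ss) / mse, 1, df_res, lower.tail = FALSE),
    stringsAsFactors = FALSE
  )

  df_model <- length(model$terms)
  model_f <- (ssr / df_model) / mse
  model_p <- stats::pf(model_f, df_model, df_res, lower.tail = FALSE)

  groups <- replicate_groups(design)
  ss_pe <- sum(vapply(groups, function(i) sum((y[i] - mean(y[i]))^2), numeric(1)))
  df_pe <- sum(lengths(groups) - 1L)
  if (df_pe > 0L && df_res > df_pe) {
    ss_lof <- sse - ss_pe
    df_lof <- df_res - df_pe
    lof_f <- (ss_lof / df_lof) / (ss_pe / df_pe)
    lof <- list(available = TRUE, statistic = lof_f,
                p_value = stats::pf(lof_f, df_lof, df_pe, lower.tail = FALSE),
                df_lof = df_lof, df_pe = df_pe, ss_lof = ss_lof, ss_pe = ss_pe)
  } else {
    lof <- list(available = FALSE, statistic = NA_real_, p_value = NA_real_,
                df_lof = NA_integer_, df_pe = df_pe, ss_lof = NA_real_,
                ss_pe = if (df_pe > 0) ss_pe else NA_real_)
  }

  structure(
    list(
      terms = term_tab,
      model = list(statistic = model_f, p_value = model_p,
                   df1 = df_model, df2 = df_res),
      lack_of_fit = lof,
      ss = list(total = sst, regression = ssr, residual = sse)
    ),
    class = "rsm_anova"
  )
}

#' @export
print.rsm_anova <- function(x, ...) {
  cat(sprintf("Model F = %.4g on (%d, %d) df, p = %.4g\n",
              x$model$statistic, x$model$df1, x$model$df2, x$model$p_value))
  tt <- x$terms
  for (i in seq_len(nrow(tt))) {
    cat(sprintf("  %-6s F = %10.4g  p = %.4g\n",
                tt$term[i], tt$statistic[i], tt$p_value[i]))
  }
  if (x$lack_of_fit$available) {
    cat(sprintf("Lack of fit F = %.4g on (%d, %d) df, p = %.4g\n",
                x$lack_of_fit$statistic, x$lack_of_fit$df_lof,
                x$lack_of_fit$df_pe, x$lack_of_fit$p_value))
  } else {
    cat("Lack of fit: unavailable (no replicate groups)\n")
  }
  invisible(x)
}

#' Goodness-of-fit panel for a response-surface model
#'
#' The Design-Expert-style diagnostic set, all computed on the
#' transformed response scale: R-squared, adjusted R-squared, predicted
#' R-squared via the PRESS statistic (exact leave-one-out through the hat
#' matrix), residual standard deviation, coefficient of variation, and
#' adequate precision. Adequate precision is the signal-to-noise ratio
#' `(max - min fitted value at the design points) / sqrt(p * MSE / n)`
#' with `p` the number of model terms including the intercept.
#'
#' @param model An `rsm_fit`.
#' @return Object of class `rsm_fit_stats`: list with `r_squared`,
#'   `adj_r_squared`, `pred_r_squared`, `press`, `sd`, `cv_percent`,
#'   `adequate_precision`.
#' @export
fit_stats <- function(model) {
  stopifnot(inherits(model, "rsm_fit"))
  y <- model$response_transformed
  n <- length(y)
  p <- length(model$terms) + 1L
  sse <- sum(model$residuals^2)
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) {
    stop("undefined statistic: total sum of squares is zero", call. = FALSE)
  }
  mse <- sse / model$df_residual
  press <- sum((model$residuals / (1 - model$hat))^2)
  structure(
    list(
      r_squared = 1 - sse / sst,
      adj_r_squared = 1 - mse / (sst / (n - 1)),
      pred_r_squared = 1 - press / sst,
      press = press,
      sd = sqrt(mse),
      cv_percent = 100 * sqrt(mse) / mean(y),
      adequate_precision =
        (max(model$fitted) - min(model$fitted)) / sqrt(p * mse / n)
    ),
    class = "rsm_fit_stats"
  )
}

#' @export
print.rsm_fit_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "R2 %.4f  adj R2 %.4f  pred R2 %.4f\n",
    "SD %.4g  %%CV %.3g  adequate precision %.4g\n"),
    x$r_squared, x$adj_r_squared, x$pred_r_squared,
    x$sd, x$cv_percent, x$adequate_precision))
  invisible(x)
}

#' Backward model reduction by partial F tests
#'
#' Repeatedly removes the least significant removable term (largest
#' partial-F p-value above `alpha`) and refits, preserving weak heredity:
#' a linear term is never removed while one of its interactions or its
#' square remains, and the intercept is never removed.
#'
#' @param model A fitted `rsm_fit` (typically the full quadratic).
#' @param alpha Significance level for retention, in (0, 1].
#' @return An `rsm_fit` on the reduced term set.
#' @examples
#' runs <- berberine_runs()
#' des <- as_bbd_design(runs, berberine_factors())
#' full <- fit_rsm(des, runs$EE, "quadratic", "inverse", response_name = "EE")
#' reduce_model(full)$terms # drops x1:x2 and x2:x3
#' @export
reduce_model <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "rsm_fit"), alpha > 0, alpha <= 1)
  fit <- model
  repeat {
    parents <- unique(unlist(lapply(fit$terms, term_parents)))
    removable <- setdiff(fit$terms, parents)
    if (!length(removable)) break
    an <- anova_type3(fit)
    pv <- an$terms$p_value[match(removable, an$terms$term)]
    worst <- which.max(pv)
    if (pv[worst] <= alpha) break
    fit <- fit_rsm(fit$design, fit$response,
                   terms = setdiff(fit$terms, removable[worst]),
                   transform = fit$transform,
                   response_name = fit$response_name)
  }
  fit
}

#' JSON-ready report for a fitted response-surface model
#'
#' Bundles the equation (transform, terms, coefficients), Type III ANOVA
#' and fit statistics into one plain list, suitable for
#' `jsonlite::write_json()`.
#'
#' @param model An `rsm_fit`.
#' @return A nested list.
#' @export
rsm_report <- function(model) {
  an <- anova_type3(model)
  st <- fit_stats(model)
  list(
    response = model$response_name,
    transform = model$transform,
    terms = model$terms,
    coefficients = as.list(model$coefficients),
    anova = list(
      model = an$model,
      terms = an$terms,
      lack_of_fit = an$lack_of_fit
    ),
    stats = unclass(st)
  )
}
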