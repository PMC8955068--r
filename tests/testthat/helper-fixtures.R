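# shared fixtures: the bundled 17-run formulation study and its models

bb_runs <- function() berberine_runs()

bb_design <- function(runs = bb_runs()) {
  as_bbd_design(runs, berberine_factors())
}

bb_fits <- function(runs = bb_runs()) {
  fit_study_models(runs, berberine_config())
}

# the study's reported AUC0-t values: intranasal coated carrier and
# intravenous solution reference (ng/mL x min)
reference_aucs <- function() {
  pk <- pk_reference()
  pick <- function(group, tissue, route) {
    pk$auc_ng_ml_min[pk$group == group & pk$tissue == tissue &
                       pk$route == route]
  }
  list(
    brain_in = pick("coated_carrier", "brain", "IN"),
    blood_in = pick("coated_carrier", "blood", "IN"),
    brain_iv = pick("solution", "brain", "IV"),
    blood_iv = pick("solution", "blood", "IV"),
    sol_brain_in = pick("solution", "brain", "IN"),
    sol_blood_in = pick("solution", "blood", "IN")
  )
}

# independent closed-form oracle for a linear fit on a 3-factor
# Box-Behnken design: each linear coefficient is the +1/-1 contrast sum
# over 8, the intercept the grand mean of the transformed response
bbd_linear_oracle <- function(coded, y) {
  c(`(Intercept)` = mean(y),
    vapply(c(x1 = 1, x2 = 2, x3 = 3), function(j) {
      (sum(y[coded[, j] == 1]) - sum(y[coded[, j] == -1])) / 8
    }, numeric(1)))
}

write_temp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
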