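#' Normalize well viability to the vehicle controls
#'
#' Divides every well's ATP signal by the mean signal of the control
#' (vehicle) wells, so control wells average exactly 1.
#'
#' @param plate a `plate_table` (see [generate_plate()] /
#'   [read_plate_csv()]).
#' @return the plate with a `viability` column added.
#' @export
normalize_viability <- function(plate) {
  ctrl <- plate$atp_signal[plate$is_control]
  if (length(ctrl) < 1) stop("plate has no control wells")
  if (mean(ctrl) == 0) stop("control wells have zero mean signal")
  plate$viability <- plate$atp_signal / mean(ctrl)
  plate
}

#' Drug-treatment z-score against the vehicle control
#'
#' `(mean drug ATP - mean control ATP) / sd(control ATP)`, with the sample
#' (n-1) standard-deviation estimator.
#'
#' @param plate a `plate_table`.
#' @param drug drug name; its non-control wells are averaged.
#' @return the z-score.
#' @export
drug_zscore <- function(plate, drug) {
  ctrl <- plate$atp_signal[plate$is_control]
  trt <- plate$atp_signal[plate$drug == drug & !plate$is_control]
  if (drug %in% plate$drug[plate$is_control])
    trt <- plate$atp_signal[plate$drug == drug]
  if (length(ctrl) < 2) stop("need >= 2 control wells for a z-score")
  if (length(trt) < 1) stop("no wells for drug: ", drug)
  s <- stats::sd(ctrl)
  if (s == 0) stop("control wells have zero standard deviation")
  (mean(trt) - mean(ctrl)) / s
}

#' Control-normalized organoid growth rate
#'
#' Ratio of the drug wells' day-6/day-4 mean-size ratio to the control
#' wells' day-6/day-4 mean-size ratio. Evaluating the control group itself
#' returns 1 by construction.
#'
#' @param plate a `plate_table` with size_day4 and size_day6 columns.
#' @param drug drug name, or the control drug label to self-normalize.
#' @return normalized growth rate.
#' @export
growth_rate <- function(plate, drug) {
  sel <- if (any(plate$drug == drug & !plate$is_control)) {
    plate$drug == drug & !plate$is_control
  } else plate$drug == drug
  if (!any(sel)) stop("no wells for drug: ", drug)
  ctrl <- plate$is_control
  d4 <- mean(plate$size_day4[sel]); c4 <- mean(plate$size_day4[ctrl])
  if (d4 == 0 || c4 == 0) stop("zero mean day-4 size")
  (mean(plate$size_day6[sel]) / d4) / (mean(plate$size_day6[ctrl]) / c4)
}

#' Convert normalized viability to affected fraction
#'
#' `fa = 1 - viability`, clipped into `[clip[1], clip[2]]` so the log-odds
#' transform of the median-effect fit is defined; clipped entries are
#' flagged in the `"clipped"` attribute.
#'
#' @param viability numeric vector of control-normalized viabilities.
#' @param clip length-2 clipping bounds (default `c(0.005, 0.995)`).
#' @return affected fractions with a logical `clipped` attribute.
#' @export
fa_from_viability <- function(viability, clip = c(0.005, 0.995)) {
  fa <- 1 - viability
  clipped <- fa < clip[1] | fa > clip[2]
  fa <- pmin(pmax(fa, clip[1]), clip[2])
  attr(fa, "clipped") <- clipped
  fa
}

#' Fit the median-effect (Chou-Talalay) dose-response model
#'
#' Fits `log10(fa/(1-fa)) = m * log10(D) - m * log10(Dm)` by least squares:
#' the median-effect equation `fa/fu = (D/Dm)^m` in its linear form. `m` is
#' the sigmoidicity and `Dm` the dose giving half effect.
#'
#' @param doses positive doses.
#' @param affected_fractions fractions affected, strictly inside (0, 1); use
#'   [fa_from_viability()] to clip measured values first.
#' @return object of class `median_effect_fit` with components `m`, `Dm`,
#'   `r_squared` and `dose_range`, supporting `coef`, `predict` and `print`.
#' @export
median_effect_fit <- function(doses, affected_fractions) {
  if (any(doses <= 0)) stop("doses must be strictly positive")
  if (any(affected_fractions <= 0 | affected_fractions >= 1))
    stop("affected fractions must lie strictly in (0, 1); ",
         "clip measured values with fa_from_viability()")
  if (length(unique(doses)) < 2)
    stop("need at least 2 distinct doses")
  x <- log10(doses)
  y <- log10(affected_fractions / (1 - affected_fractions))
  fit <- stats::lm(y ~ x)
  m <- unname(stats::coef(fit)[2])
  Dm <- 10^(-unname(stats::coef(fit)[1]) / m)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  structure(list(m = m, Dm = Dm,
                 r_squared = r2,
                 dose_range = range(doses), lm_fit = fit),
            class = "median_effect_fit")
}

#' @export
coef.median_effect_fit <- function(object, ...) {
  c(m = object$m, Dm = object$Dm)
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat(sprintf("median-effect fit: m = %.4g, Dm = %.4g (r^2 = %.4f, doses %.3g-%.3g)\n",
              x$m, x$Dm, x$r_squared, x$dose_range[1], x$dose_range[2]))
  invisible(x)
}

#' Predict affected fraction at given doses
#'
#' @param object a `median_effect_fit`.
#' @param doses doses at which to evaluate `fa = (D/Dm)^m / (1 + (D/Dm)^m)`.
#' @param ... unused.
#' @export
predict.median_effect_fit <- function(object, doses, ...) {
  r <- (doses / object$Dm)^object$m
  r / (1 + r)
}

#' Dose producing a given affected fraction
#'
#' Inverts the median-effect equation: `Dx = Dm * (fa/(1-fa))^(1/m)`.
#'
#' @param fit a `median_effect_fit`.
#' @param fa affected fraction in (0, 1).
#' @return the dose `Dx`.
#' @export
dose_for_fa <- function(fit, fa) {
  if (any(fa <= 0 | fa >= 1)) stop("fa must lie strictly in (0, 1)")
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Chou-Talalay combination index at an observed combination effect
#'
#' `CI = d1/Dx1 + d2/Dx2` where `Dx_i` is the dose of drug i alone producing
#' the combination's affected fraction (the mutually exclusive form; set
#' `exclusive = FALSE` to add the cross term `d1*d2/(Dx1*Dx2)`). Log CI below
#' 0 indicates synergy, near 0 additivity, above 0 antagonism; the additivity
#' call uses a tolerance band on |log10 CI| while the raw value is always
#' returned.
#'
#' @param fit1,fit2 single-agent `median_effect_fit` objects.
#' @param d1,d2 doses of the two drugs in the combination (>= 0).
#' @param fa_combo affected fraction observed for the combination, in (0, 1).
#' @param exclusive use the mutually exclusive CI form (default TRUE).
#' @param additivity_tol half-width of the additive band on log10 CI.
#' @return data.frame with fa, ci, log10_ci and call.
#' @export
combination_index <- function(fit1, fit2, d1, d2, fa_combo,
                              exclusive = TRUE, additivity_tol = 0.1) {
  if (any(fa_combo <= 0 | fa_combo >= 1))
    stop("fa_combo must lie strictly in (0, 1)")
  if (any(c(d1, d2) < 0)) stop("doses must be >= 0")
  dx1 <- dose_for_fa(fit1, fa_combo)
  dx2 <- dose_for_fa(fit2, fa_combo)
  ci <- d1 / dx1 + d2 / dx2
  if (!exclusive) ci <- ci + (d1 * d2) / (dx1 * dx2)
  log_ci <- log10(ci)
  call <- ifelse(abs(log_ci) <= additivity_tol, "additivity",
                 ifelse(log_ci < 0, "synergy", "antagonism"))
  data.frame(fa = fa_combo, ci = ci, log10_ci = log_ci, call = call)
}

#' Fit a drug's median-effect model from a plate table
#'
#' Normalizes viability to the vehicle controls, averages replicate wells at
#' each dose, converts to affected fractions (with clipping) and fits the
#' median-effect model.
#'
#' @param plate a `plate_table`.
#' @param drug drug name.
#' @param clip clipping bounds passed to [fa_from_viability()].
#' @return a `median_effect_fit`.
#' @export
median_effect_from_plate <- function(plate, drug, clip = c(0.005, 0.995)) {
  plate <- normalize_viability(plate)
  wells <- plate[plate$drug == drug & !plate$is_control, ]
  if (nrow(wells) == 0) stop("no wells for drug: ", drug)
  v <- tapply(wells$viability, wells$dose, mean)
  doses <- as.numeric(names(v))
  median_effect_fit(doses, fa_from_viability(as.numeric(v), clip = clip))
}

#' Ellipsoid tumor volume from caliper measurements
#'
#' `V = 0.5236 * L * W^2`, the standard modified-ellipsoid formula for
#' subcutaneous allograft measurements.
#'
#' @param length,width caliper length and width (>= 0), any consistent unit.
#' @return volume in the cubed unit.
#' @export
tumor_volume <- function(length, width) {
  if (any(length < 0) || any(width < 0))
    stop("length and width must be non-negative")
  0.5236 * length * width^2
}
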