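#' Substrate reduction (percent)
#'
#' Percentage of the supplied substrate consumed during the feeding
#' trial: `100 * (W - R) / W`, where `W` is the total food added and `R`
#' the food remaining at the end of the experiment (both in grams).
#'
#' @param W total food added (g), > 0.
#' @param R food remaining (g), in `[0, W]`.
#' @return percent in `[0, 100]`.
#' @export
substrate_reduction <- function(W, R) {
  if (any(W <= 0)) stop("W must be > 0")
  if (any(R < 0 | R > W)) stop("R must satisfy 0 <= R <= W")
  100 * (W - R) / W
}

#' Efficiency of conversion of ingested food (ECI)
#'
#' Ratio of final biomass to substrate consumed: `B / (W - R)`, where `B`
#' is the final larval plus pupal biomass.
#'
#' @param B final biomass (g), >= 0.
#' @param W total food added (g).
#' @param R food remaining (g); `W > R` required (some consumption).
#' @return non-negative ratio.
#' @export
eci <- function(B, W, R) {
  if (any(B < 0)) stop("B must be >= 0")
  if (any(W <= R)) stop("ECI undefined when W <= R (no consumption)")
  B / (W - R)
}

#' Waste reduction index (WRI)
#'
#' Substrate reduction per unit time: `(100 * (W - R) / W) / days`,
#' i.e. [substrate_reduction()] divided by the feeding duration in days.
#'
#' @param W total food added (g).
#' @param R food remaining (g).
#' @param days feeding duration (days), >= 1.
#' @return index in percent per day.
#' @export
wri <- function(W, R, days) {
  if (any(days < 1)) stop("days must be >= 1")
  substrate_reduction(W, R) / days
}

#' Signed percent change of a treatment relative to a control
#'
#' `100 * (treatment - control) / control`; optionally rounded to the
#' nearest integer (half away from zero), the convention used when
#' reporting e.g. diet-energy restriction.
#'
#' @param treatment treatment value(s).
#' @param control control value(s), non-zero.
#' @param digits decimal places for reporting, or `NULL` for no rounding.
#' @return signed percent change.
#' @export
percent_change <- function(treatment, control, digits = NULL) {
  if (any(control == 0)) stop("control value must be non-zero")
  out <- 100 * (treatment - control) / control
  if (!is.null(digits)) out <- round_half_away(out, digits)
  out
}

#' Larval growth rate by ordinary least squares
#'
#' Fits weight ~ day and returns the slope (average fresh weight gained
#' per day of growth) with the coefficient of determination.
#'
#' @param days numeric vector of time points (>= 2 distinct values).
#' @param weights fresh weights (g) at those time points.
#' @return list with `slope` (g/day), `intercept`, and `r_squared`.
#' @export
growth_rate <- function(days, weights) {
  stopifnot(length(days) == length(weights), length(days) >= 2)
  if (length(unique(days)) < 2) stop("need at least two distinct time points")
  fit <- stats::lm(weights ~ days)
  sst <- sum((weights - mean(weights))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}

#' Summarize bioassay records per diet
#'
#' Computes substrate reduction, ECI and WRI per record and returns a
#' per-diet mean and standard-deviation summary table.
#'
#' @param records data.frame with columns `diet`, `W`, `R`, `B`, `days`
#'   (see [generate_bioassay()] and [read_bioassay()]).
#' @return data.frame, one row per diet, with `_mean`/`_sd` columns for
#'   the three indices and `days`.
#' @export
bioassay_summary <- function(records) {
  stopifnot(all(c("diet", "W", "R", "B", "days") %in% names(records)))
  records$sr <- substrate_reduction(records$W, records$R)
  records$eci <- eci(records$B, records$W, records$R)
  records$wri <- wri(records$W, records$R, records$days)
  agg <- function(f) stats::aggregate(
    records[c("sr", "eci", "wri", "days")],
    by = list(diet = records$diet), FUN = f)
  m <- agg(mean); s <- agg(stats::sd)
  out <- data.frame(diet = m$diet,
                    substrate_reduction_mean = m$sr, substrate_reduction_sd = s$sr,
                    eci_mean = m$eci, eci_sd = s$eci,
                    wri_mean = m$wri, wri_sd = s$wri,
                    days_mean = m$days, days_sd = s$days)
  out[order(out$diet), , drop = FALSE]
}

#' Printed diet energy values
#'
#' Energy density (kcal/g, Atwater factors) and energy intake
#' (kcal/day/larva) of the three study diets, used as inputs when
#' computing diet-energy restriction percentages.
#'
#' @return data.frame with columns `diet`, `kcal_per_g`,
#'   `kcal_per_day_per_larva`.
#' @export
diet_energy_table <- function() {
  data.frame(diet = c("FN", "NRF", "NRV"),
             kcal_per_g = c(1.62, 0.38, 0.19),
             kcal_per_day_per_larva = c(0.111, 0.023, 0.008),
             stringsAsFactors = FALSE)
}

#' Diet-energy restriction relative to the full-nutrient diet
#'
#' Percent change in energy density of each restricted diet relative to
#' the reference diet, rounded to the nearest integer.
#'
#' @param energy data.frame as returned by [diet_energy_table()].
#' @param reference reference diet label.
#' @param column which energy column to compare.
#' @return named vector of rounded percent changes (reference excluded).
#' @export
diet_energy_restriction <- function(energy = diet_energy_table(),
                                    reference = "FN",
                                    column = "kcal_per_g") {
  stopifnot(reference %in% energy$diet, column %in% names(energy))
  ctrl <- energy[[column]][energy$diet == reference]
  other <- energy[energy$diet != reference, ]
  stats::setNames(percent_change(other[[column]], ctrl, digits = 0),
                  other$diet)
}
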