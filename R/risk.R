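#' Average daily dose from an exposure scenario
#'
#' The standard intake equation
#' `ADD = C * IR * EF * ED / (BW * AT)`.
#'
#' @param concentration medium concentration, mg/L.
#' @param intake_rate intake rate, L/day.
#' @param exposure_frequency days/year.
#' @param exposure_duration years.
#' @param body_weight kg.
#' @param averaging_time days.
#' @return ADD in mg/(kg day).
#' @export
average_daily_dose <- function(concentration, intake_rate,
                               exposure_frequency, exposure_duration,
                               body_weight, averaging_time) {
  p <- c(concentration, intake_rate, exposure_frequency,
         exposure_duration, body_weight, averaging_time)
  if (any(p <= 0)) stop("all exposure parameters must be positive")
  concentration * intake_rate * exposure_frequency * exposure_duration /
    (body_weight * averaging_time)
}

#' Non-carcinogenic hazard index
#'
#' `HI = ADD / RfD`; acceptable iff `HI < 1` (strict).
#'
#' @param add average daily dose, mg/(kg day).
#' @param rfd reference dose, mg/(kg day), positive.
#' @return list `hi`, `class` (`"acceptable"` or `"unacceptable"`).
#' @export
hazard_index <- function(add, rfd) {
  if (rfd <= 0) stop("RfD must be positive")
  hi <- add / rfd
  list(hi = hi, class = if (hi < 1) "acceptable" else "unacceptable")
}

#' Lifetime cancer risk under the linear non-threshold model
#'
#' `RI = ADD * SF`; negligible below 1e-6, acceptable in
#' \[1e-6, 1e-4), unacceptable at or above 1e-4.
#'
#' @param add average daily dose, mg/(kg day).
#' @param sf cancer slope factor, (mg/(kg day))^-1, non-negative.
#' @return list `ri`, `class`.
#' @export
cancer_risk <- function(add, sf) {
  if (sf < 0) stop("slope factor must be non-negative")
  ri <- add * sf
  cls <- if (ri < 1e-6) "negligible"
         else if (ri < 1e-4) "acceptable"
         else "unacceptable"
  list(ri = ri, class = cls)
}

#' Gibbs free-energy change of a reaction path
#'
#' `dG = sum G(products) - sum G(reactants)`; the reaction is spontaneous
#' iff `dG < 0` (strict).
#'
#' @param g_products,g_reactants free energies (declared units, summed
#'   as given).
#' @return list `dg`, `spontaneous`.
#' @export
gibbs_change <- function(g_products, g_reactants) {
  dg <- sum(g_products) - sum(g_reactants)
  list(dg = dg, spontaneous = dg < 0)
}

#' Activation barrier relative to the reactants
#'
#' `dE = E(TS) - sum E(reactants)`.
#'
#' @param e_ts transition-state energy.
#' @param e_reactants reactant energies.
#' @return barrier height in the input units.
#' @export
barrier <- function(e_ts, e_reactants) {
  e_ts - sum(e_reactants)
}

#' Rank reaction paths by ascending barrier
#'
#' Lower barrier = easier substitution; the returned order is from easiest
#' to hardest.
#'
#' @param records data frame with columns `path` and `dE`.
#' @return `records` reordered by ascending `dE`.
#' @export
rank_paths <- function(records) {
  if (!all(c("path", "dE") %in% names(records)))
    stop("records must have `path` and `dE` columns")
  if (anyNA(records$dE)) stop("missing barrier energies")
  records[order(records$dE), , drop = FALSE]
}
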