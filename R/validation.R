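#' Single-factor vs multi-factor consistency check
#'
#' Compares the weighted share of a derivative's CEI change against the
#' change predicted by a single-endpoint model: the endpoint's weighted
#' CEI change is `cei_change * weight`, the single-factor change is the
#' relative change of the derivative's single-endpoint score against the
#' template's, and the relative error between the two conventions is
#' `100 * |weighted - single| / |denominator|`.  The default denominator is
#' the weighted CEI change; set `denominator = "single"` for the
#' single-factor change instead.
#'
#' @param cei_change derivative's CEI relative change vs the template, %.
#' @param weight endpoint weight in (0, 1].
#' @param score_template template's single-endpoint score (nonzero).
#' @param score_derivative derivative's single-endpoint score.
#' @param denominator `"weighted"` (default) or `"single"`.
#' @return data frame `single_change, weighted_cei_change, relative_error`
#'   (all %), full precision plus 2-decimal display columns.
#' @export
single_factor_compare <- function(cei_change, weight, score_template,
                                  score_derivative,
                                  denominator = c("weighted", "single")) {
  denominator <- match.arg(denominator)
  if (any(score_template == 0)) stop("template score must be nonzero")
  if (any(weight <= 0 | weight > 1)) stop("weight must be in (0, 1]")
  single <- relative_change(score_derivative, score_template)
  weighted <- cei_change * weight
  den <- if (denominator == "weighted") weighted else single
  if (any(den == 0)) stop("zero baseline for relative error")
  err <- 100 * abs(weighted - single) / abs(den)
  data.frame(
    single_change = single,
    weighted_cei_change = weighted,
    relative_error = err,
    single_change_display = round_half_up(single, 2),
    weighted_display = round_half_up(weighted, 2),
    relative_error_display = round_half_up(err, 2)
  )
}

#' Per-compound residuals between observed and predicted values
#'
#' `100 * |predicted - observed| / observed` per compound plus the
#' extremes, the residual bookkeeping of model-validation tables.
#'
#' @param observed numeric vector (nonzero).
#' @param predicted numeric vector of the same length.
#' @param compound optional compound labels.
#' @return list with per-compound `table` (observed, predicted,
#'   residual_pct) and `range = c(min, max)` of the residuals.
#' @export
residual_table <- function(observed, predicted, compound = NULL) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must be aligned")
  if (any(observed == 0)) stop("observed values must be nonzero")
  res <- 100 * abs(predicted - observed) / abs(observed)
  tab <- data.frame(
    compound = if (is.null(compound)) seq_along(observed) else compound,
    observed = observed, predicted = predicted,
    residual_pct = res
  )
  list(table = tab, range = c(min = min(res), max = max(res)))
}
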