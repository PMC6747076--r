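#' POP-characteristic screening cascade
#'
#' Screens derivative endpoint predictions against the template over three
#' persistent-organic-pollutant criteria applied in sequence:
#' \enumerate{
#'   \item genotoxicity: keep derivatives whose pLOEC relative change vs
#'     the template is \eqn{\ge 0} (a derivative matching the template
#'     exactly passes);
#'   \item photodegradability: among survivors, keep those with a strictly
#'     positive log t1/2 relative change;
#'   \item bioconcentration: among survivors, keep those with a strictly
#'     negative log Kow relative change.
#' }
#'
#' @param table data frame with columns `compound, ploec, log_t_half,
#'   log_kow` including the template row.
#' @param template compound id of the template row.
#' @return list with `table` (relative changes and per-stage pass flags),
#'   `stages` (surviving id sets), `cardinalities`, and `spans` (min/max
#'   relative change per endpoint over that stage's survivors).
#' @export
pop_screen <- function(table, template) {
  need <- c("compound", "ploec", "log_t_half", "log_kow")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing endpoint column(s): ",
                         paste(miss, collapse = ", "))
  ti <- match(template, table$compound)
  if (is.na(ti)) stop("template '", template, "' not found in table")
  tmpl <- table[ti, ]
  tab <- table[-ti, , drop = FALSE]
  tab$rel_ploec <- relative_change(tab$ploec, tmpl$ploec)
  tab$rel_log_t_half <- relative_change(tab$log_t_half, tmpl$log_t_half)
  tab$rel_log_kow <- relative_change(tab$log_kow, tmpl$log_kow)
  tab$passed_genotox <- tab$rel_ploec >= 0
  tab$passed_photodeg <- tab$passed_genotox & tab$rel_log_t_half > 0
  tab$passed_bioconc <- tab$passed_photodeg & tab$rel_log_kow < 0
  stages <- list(
    genotox = tab$compound[tab$passed_genotox],
    photodeg = tab$compound[tab$passed_photodeg],
    bioconc = tab$compound[tab$passed_bioconc]
  )
  span_or_na <- function(v) if (length(v)) range_summary(v)
                            else c(min = NA_real_, max = NA_real_)
  spans <- list(
    genotox = span_or_na(tab$rel_ploec[tab$passed_genotox]),
    photodeg = span_or_na(tab$rel_log_t_half[tab$passed_photodeg]),
    bioconc = span_or_na(tab$rel_log_kow[tab$passed_bioconc])
  )
  list(table = tab, stages = stages,
       cardinalities = lengths(stages), spans = spans)
}

#' Average several model predictions into a consensus value
#'
#' Arithmetic mean of the individual model predictions, optionally with
#' the relative change against a parent compound's consensus value.
#'
#' @param predictions numeric vector of model predictions (>= 1).
#' @param parent optional parent value for the relative change.
#' @return list `pred_avg` and, when `parent` is given, `rel_change` (%).
#' @export
average_prediction <- function(predictions, parent = NULL) {
  if (length(predictions) < 1L) stop("no predictions supplied")
  out <- list(pred_avg = mean(predictions))
  if (!is.null(parent))
    out$rel_change <- relative_change(out$pred_avg, parent)
  out
}

#' Apply a user-supplied linear QSAR model
#'
#' Dot product of named descriptors with named coefficients plus an
#' intercept — plumbing for plugging in literature regression models whose
#' coefficients the user supplies.
#'
#' @param descriptors named numeric vector.
#' @param coefficients named numeric vector over the same labels.
#' @param intercept model intercept.
#' @return predicted endpoint value.
#' @export
apply_linear_qsar <- function(descriptors, coefficients, intercept = 0) {
  if (!setequal(names(descriptors), names(coefficients)))
    stop("descriptor labels do not match coefficient labels")
  sum(descriptors[names(coefficients)] * coefficients) + intercept
}

#' Min/max summary of a set of relative changes
#'
#' @param values numeric vector (non-empty).
#' @return named vector `c(min, max)`.
#' @export
range_summary <- function(values) {
  if (length(values) == 0L) stop("empty value set")
  c(min = min(values), max = max(values))
}
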