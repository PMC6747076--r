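#' fuzzcomfa: fuzzy comprehensive evaluation driven 3D-QSAR
#'
#' Collapses several adverse-reaction endpoint scores per compound into one
#' comprehensive evaluation index (CEI) by fuzzy min-max membership and
#' weighted aggregation, models the CEI against CoMFA-style molecular
#' interaction fields by partial least squares, and carries the result
#' through derivative design, screening, validation and risk arithmetic.
#'
#' @keywords internal
"_PACKAGE"

#' Round half away from zero
#'
#' Display rounding used throughout the package for printed tables
#' (0.0005 -> 0.001, -0.0005 -> -0.001), unlike [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

check_score_matrix <- function(scores) {
  if (!is.matrix(scores) || !is.numeric(scores))
    stop("`scores` must be a numeric matrix (compounds in rows, endpoints in columns)")
  if (nrow(scores) < 2L)
    stop("at least 2 compounds per endpoint are required")
  if (any(!is.finite(scores)))
    stop("all scores must be finite; missing cells are not allowed")
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("endpoint", seq_len(ncol(scores)))
  if (is.null(rownames(scores)))
    rownames(scores) <- paste0("compound", seq_len(nrow(scores)))
  scores
}

#' Fuzzy membership matrix by per-endpoint min-max scaling
#'
#' Converts a compounds x endpoints score matrix into membership values in
#' \[0, 1\] with the large-scale membership function: for an endpoint where a
#' larger score means a stronger (worse) effect,
#' `r = (c - min) / (max - min)`, the minimum and maximum taken over
#' compounds within that endpoint.  For `smaller_is_better` endpoints the
#' mapping is mirrored, `(max - c) / (max - min)`.
#'
#' @param scores numeric matrix, compounds in rows, endpoints in columns
#'   (the layout toxicity score tables are printed in).
#' @param orientation either a single string, `"larger_is_better"` or
#'   `"smaller_is_better"`, applied to every endpoint, or a character vector
#'   (optionally named by endpoint) with one entry per endpoint.
#' @return numeric matrix of memberships with the same dimnames as `scores`;
#'   within each endpoint the best compound maps to 1 and the worst to 0.
#' @examples
#' s <- cbind(a = c(1, 3, 2), b = c(10, 20, 30))
#' build_membership_matrix(s)
#' @export
build_membership_matrix <- function(scores, orientation = "larger_is_better") {
  scores <- check_score_matrix(scores)
  orientation <- match.arg(
    orientation,
    c("larger_is_better", "smaller_is_better"),
    several.ok = TRUE
  )
  if (length(orientation) == 1L)
    orientation <- rep(orientation, ncol(scores))
  if (length(orientation) != ncol(scores))
    stop("`orientation` must have one entry per endpoint")
  if (!is.null(names(orientation)))
    orientation <- orientation[colnames(scores)]

  r <- scores
  for (j in seq_len(ncol(scores))) {
    cj <- scores[, j]
    rng <- range(cj)
    if (rng[1] == rng[2])
      stop("degenerate endpoint '", colnames(scores)[j],
           "': all compounds share the score ", rng[1])
    r[, j] <- if (orientation[j] == "larger_is_better")
      (cj - rng[1]) / (rng[2] - rng[1])
    else
      (rng[2] - cj) / (rng[2] - rng[1])
  }
  r
}

#' Weighted comprehensive evaluation index
#'
#' Aggregates a membership matrix with endpoint weights by the weighted
#' average model: `cei_j = sum_i a_i * r_ij`.  With weights summing to 1
#' every CEI lies in \[0, 1\].
#'
#' @param membership membership matrix from [build_membership_matrix()].
#' @param weights numeric vector of endpoint weights, non-negative and
#'   summing to 1 (within 1e-9); if named, matched to endpoint columns.
#' @return data frame with columns `compound`, `cei` (full precision) and
#'   `cei_display` (3 decimals, half away from zero).
#' @export
composite_index <- function(membership, weights) {
  if (!is.matrix(membership))
    stop("`membership` must be a matrix")
  if (length(weights) != ncol(membership))
    stop("dimension mismatch: ", length(weights), " weights for ",
         ncol(membership), " endpoints")
  if (any(weights < 0))
    stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weights must sum to 1 (got ", sum(weights), ")")
  if (!is.null(names(weights))) {
    if (!setequal(names(weights), colnames(membership)))
      stop("weight names do not match endpoint names")
    weights <- weights[colnames(membership)]
  }
  cei <- drop(membership %*% weights)
  data.frame(
    compound = rownames(membership),
    cei = unname(cei),
    cei_display = unname(round_half_up(cei, 3)),
    stringsAsFactors = FALSE
  )
}

#' Signed relative change in percent
#'
#' `100 * (value - reference) / reference`; the comparison arithmetic behind
#' all derivative and by-product tables.
#'
#' @param value numeric vector of new values.
#' @param reference baseline value(s), nonzero.
#' @return percent change, signed.
#' @examples
#' relative_change(0.619, 0.925) # -33.08...
#' @export
relative_change <- function(value, reference) {
  if (any(reference == 0))
    stop("reference value must be nonzero")
  100 * (value - reference) / reference
}

#' One-call fuzzy evaluation of a score table
#'
#' Composes [build_membership_matrix()] and [composite_index()]:
#' score matrix in, per-compound memberships and CEI out.
#'
#' @inheritParams build_membership_matrix
#' @inheritParams composite_index
#' @param csv optional path; when given the result is also written as CSV.
#' @return data frame `compound, r_<endpoint>..., cei, cei_display`.
#' @export
evaluate_table <- function(scores, weights, orientation = "larger_is_better",
                           csv = NULL) {
  r <- build_membership_matrix(scores, orientation)
  cei <- composite_index(r, weights)
  out <- data.frame(compound = cei$compound, r,
                    cei = cei$cei, cei_display = cei$cei_display,
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out)[1L + seq_len(ncol(r))] <- paste0("r_", colnames(r))
  if (!is.null(csv))
    utils::write.csv(out, csv, row.names = FALSE)
  out
}
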