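# Bundled data tables for a 29-compound fluoroquinolone series and the
# pazufloxacin derivative study: docking scores and printed CEIs, predicted
# derivative CEIs, POP-endpoint predictions, single-factor validation
# inputs, reaction thermochemistry, and chlorination by-product
# genotoxicity predictions.  Each CSV is checksum-pinned; editing a
# transcription invalidates the pin on purpose.
FIXTURE_MD5 <- c(
  table1_docking_cei.csv = "dddaac9bbb81dc8e0d8fce1e17957e6a",
  table4_derivative_cei.csv = "82d9ddd83d1577f923f4abe9e3bbe1c6",
  table5_pop_screen.csv = "adb723d6b2ec197cf4c2eff4a1be54e1",
  table6_single_factor.csv = "723b9fa3ee31cf8afeece9229d31e052",
  table7_thermo.csv = "57b56ef4d568e99f576ec75f232fc917",
  table9_byproducts_paz.csv = "585af85c03bf6cd7a041c35e971fb128",
  table10_byproducts_derivatives.csv = "51a63ea4b2e692d1406e667deaf2480c"
)

fixture_csv <- function(file) {
  path <- system.file("extdata", file, package = "fuzzcomfa", mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, unname(FIXTURE_MD5[file])))
    stop("fixture '", file, "' fails its checksum pin (", md5, ")")
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Docking-score / CEI table for the 29-compound series
#'
#' Docking scores of 29 fluoroquinolones against the three
#' adverse-reaction protein targets (GABA receptor 3IP9, cyclooxygenase
#' 3N8V, hERG channel 2L0W) together with the published comprehensive
#' evaluation index, plus the endpoint weights (0.50/0.40/0.10, the
#' relative clinical incidences of the three reactions).
#'
#' @return list: `scores` (29 x 3 matrix, compounds in rows),
#'   `cei_printed` (named numeric), `weights` (named, sums to 1), and the
#'   raw `table`.
#' @export
table1_fixture <- function() {
  tab <- fixture_csv("table1_docking_cei.csv")
  scores <- as.matrix(tab[, c("3IP9", "3N8V", "2L0W")])
  rownames(scores) <- tab$compound
  list(scores = scores,
       cei_printed = stats::setNames(tab$cei_printed, tab$compound),
       weights = c(`3IP9` = 0.50, `3N8V` = 0.40, `2L0W` = 0.10),
       table = tab)
}

#' Predicted CEIs of the 48 template derivatives
#'
#' @return data frame `id, name, cei, rel_change_printed` (48 rows) with
#'   attribute `template_cei` (0.925, the template's CEI).
#' @export
table4_fixture <- function() {
  tab <- fixture_csv("table4_derivative_cei.csv")
  attr(tab, "template_cei") <- 0.925
  tab
}

#' POP-endpoint predictions for template + 48 derivatives
#'
#' Genotoxicity (pLOEC), photodegradation half-life (log t1/2) and
#' octanol-water partition (log Kow) predictions for the template molecule
#' and its 48 derivatives; input to [pop_screen()].
#'
#' @return data frame `compound, ploec, log_t_half, log_kow` (49 rows).
#' @export
table5_fixture <- function() fixture_csv("table5_pop_screen.csv")

#' Single-factor validation inputs
#'
#' Template and top-three-derivative scores per endpoint from the three
#' single-endpoint models, endpoint weights, published CEIs, and the
#' published relative errors.
#'
#' @return list: `cei` (named, template + 3 derivatives), `endpoints`
#'   (data frame with weights and per-compound scores), `printed_errors`
#'   (matrix endpoints x derivatives).
#' @export
table6_fixture <- function() {
  tab <- fixture_csv("table6_single_factor.csv")
  cei_row <- tab[tab$endpoint == "cei", ]
  ep <- tab[tab$endpoint != "cei", ]
  derivs <- c("Derivative-1", "Derivative-2", "Derivative-3")
  printed <- as.matrix(ep[, c("err1_printed", "err2_printed", "err3_printed")])
  dimnames(printed) <- list(ep$endpoint, derivs)
  list(
    cei = stats::setNames(as.numeric(cei_row[, c("PAZ", derivs)]),
                          c("PAZ", derivs)),
    endpoints = ep[, c("endpoint", "weight", "PAZ", derivs)],
    printed_errors = printed
  )
}

#' Substitution-path thermochemistry table
#'
#' Lowest vibrational frequency, Gibbs free-energy change and activation
#' barrier for the three substitution paths of the template molecule
#' (energies in the units the source declares, taken verbatim).
#'
#' @return data frame `path, group, frequency_cm, dG, dE`.
#' @export
table7_fixture <- function() fixture_csv("table7_thermo.csv")

#' Genotoxicity predictions for template chlorination by-products
#'
#' Two-model predictions (Pred.59, Pred.61) for the 13 chlorination
#' by-products of the template molecule; input to [average_prediction()].
#'
#' @return list: `parent` (consensus value of the parent), `table`
#'   (13 by-product rows incl. printed consensus/relative-change columns).
#' @export
table9_fixture <- function() {
  tab <- fixture_csv("table9_byproducts_paz.csv")
  list(parent = tab$pred59[1], table = tab[-1, ])
}

#' Genotoxicity predictions for derivative chlorination by-products
#'
#' @return list of per-parent blocks, each `list(parent =, table =)` as in
#'   [table9_fixture()].
#' @export
table10_fixture <- function() {
  tab <- fixture_csv("table10_byproducts_derivatives.csv")
  out <- list()
  for (p in unique(tab$parent)) {
    blk <- tab[tab$parent == p, ]
    parent_row <- blk$compound == p
    out[[p]] <- list(parent = blk$pred59[parent_row],
                     table = blk[!parent_row, ])
  }
  out
}

#' Rigid template scaffold with labeled substitution sites
#'
#' A small synthetic scaffold standing in for the (unpublished) 3D
#' structure of a drug template: a rigid polar core with two substitutable
#' hydrogens, labeled as attachment positions 1 and 5 for
#' [enumerate_derivatives()].
#'
#' @param id molecule id.
#' @return a [molecule] with an `attachments` attribute.
#' @export
synthetic_scaffold <- function(id = "PAZ") {
  atoms <- data.frame(
    element = c("N", "C", "C", "C", "O", "H", "H"),
    x = c(0.00, 1.35, 2.05, 1.35, 2.05, -0.55, 1.35),
    y = c(0.00, 0.75, 2.05, 3.35, 4.45, -0.85, -1.25),
    z = c(0, 0, 0, 0, 0, 0.45, 0),
    charge = c(-0.30, 0.10, -0.05, 0.12, -0.35, 0.18, 0.05),
    stringsAsFactors = FALSE
  )
  mol <- molecule(id, atoms)
  # position 1: substitution at N1 (atom 1), replacing H (atom 6);
  # position 5: substitution at ring carbon C5 (atom 2), replacing H (atom 7)
  attr(mol, "attachments") <- list(
    `1` = list(anchor = 1L, replace = 6L),
    `5` = list(anchor = 2L, replace = 7L)
  )
  mol
}

#' Synthetic congeneric series with a known structure-activity law
#'
#' Emulates an aligned congeneric drug series whose activity is exactly
#' linear in two substituent properties: a shared rigid scaffold carries
#' one variable substituent atom per molecule whose van der Waals radius
#' (steric bulk) and partial charge are drawn uniformly from the given
#' ranges, and the response is
#' `activity = effect["size"] * u_size + effect["charge"] * u_charge +
#' N(0, noise_sd)`, with `u` the 0-1 normalized draw.  Because the steric
#' probe field is monotone in the substituent radius and the electrostatic
#' field linear in its charge, a field + PLS pipeline can recover this law
#' — noiselessly so for `noise_sd = 0`.
#'
#' @param n number of molecules (>= 6; default 29, the size of the
#'   real series the generator stands in for).
#' @param seed integer seed.
#' @param size_range substituent vdW radius range, Angstrom.
#' @param charge_range substituent partial charge range, e.
#' @param effect effect sizes of the two properties on the activity.
#' @param noise_sd activity noise standard deviation.
#' @param sdf optional path: write the series as SDF with charges.
#' @return list: `molecules` (each with a `framework_map` onto the first
#'   molecule's scaffold), `activity`, `u_size`, `u_charge`, and the drawn
#'   `radius`/`charge` per molecule.
#' @export
synthetic_series <- function(n = 29L, seed = 1L,
                             size_range = c(1.2, 2.0),
                             charge_range = c(-0.5, 0.5),
                             effect = c(size = 1.0, charge = 1.0),
                             noise_sd = 0.1, sdf = NULL) {
  if (n < 6L) stop("need at least 6 molecules")
  if (diff(size_range) <= 0 || diff(charge_range) <= 0)
    stop("degenerate property range")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  u_size <- stats::runif(n)
  u_charge <- stats::runif(n)
  radius <- size_range[1] + u_size * diff(size_range)
  charge <- charge_range[1] + u_charge * diff(charge_range)
  activity <- effect[["size"]] * u_size + effect[["charge"]] * u_charge +
    stats::rnorm(n, 0, noise_sd)
  scaffold <- data.frame(
    element = c("C", "C", "N", "O"),
    x = c(0, 1.40, 0.70, -1.10),
    y = c(0, 0.00, 1.21, -0.80),
    z = c(0, 0, 0, 0),
    charge = c(0.10, -0.05, -0.30, -0.25),
    stringsAsFactors = FALSE
  )
  mols <- lapply(seq_len(n), function(i) {
    p <- element_params(scaffold$element)
    atoms <- rbind(
      cbind(scaffold, vdw_radius = p$vdw_radius, lj_epsilon = p$lj_epsilon),
      data.frame(element = "C", x = 2.80, y = -0.80, z = 0,
                 charge = charge[i], vdw_radius = radius[i],
                 lj_epsilon = 0.107)
    )
    molecule(sprintf("synth-%02d", i), atoms,
             framework_map = stats::setNames(1:4, 1:4))
  })
  if (!is.null(sdf)) write_sdf(mols, sdf)
  list(molecules = mols, activity = activity,
       u_size = u_size, u_charge = u_charge,
       radius = radius, charge = charge)
}
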