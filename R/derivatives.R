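# Idealized substituent fragment geometries.  Each fragment is defined in a
# local frame with the attachment bond along +x: the first atom sits at the
# origin and is bonded to the scaffold anchor at distance `bond` along -x.
# Bond lengths in Angstrom from standard tables; no conformer search.
fragment_atoms <- function(element, x, y, z, charge) {
  data.frame(element = element, x = x, y = y, z = z, charge = charge,
             stringsAsFactors = FALSE)
}

FRAGMENT_LIBRARY <- list(
  # position-1 (N1) substituents
  Methyl = list(bond = 1.47, atoms = fragment_atoms(
    c("C", "H", "H", "H"),
    c(0, 0.36, 0.36, 0.36), c(0, 1.03, -0.51, -0.51),
    c(0, 0, 0.89, -0.89), c(-0.06, 0.02, 0.02, 0.02))),
  Hydrogen = list(bond = 1.01, atoms = fragment_atoms(
    "H", 0, 0, 0, 0.30)),
  Ethyl = list(bond = 1.47, atoms = fragment_atoms(
    c("C", "H", "H", "C", "H", "H", "H"),
    c(0, -0.36, -0.36, 1.45, 1.81, 1.81, 1.81),
    c(0, 0.51, 0.51, 0.60, 1.57, 0.09, 0.09),
    c(0, 0.89, -0.89, 0, 0, 0.89, -0.89),
    c(-0.04, 0.02, 0.02, -0.06, 0.02, 0.02, 0.02))),
  Vinyl = list(bond = 1.43, atoms = fragment_atoms(
    c("C", "H", "C", "H", "H"),
    c(0, -0.32, 1.21, 1.53, 1.85),
    c(0, 0.95, 0.62, 1.57, -0.33),
    c(0, 0, 0, 0, 0), c(-0.03, 0.05, -0.10, 0.05, 0.05))),
  Ethynyl = list(bond = 1.38, atoms = fragment_atoms(
    c("C", "C", "H"),
    c(0, 1.20, 2.26), c(0, 0, 0), c(0, 0, 0),
    c(-0.05, -0.15, 0.22))),
  Carbonyl = list(bond = 1.38, atoms = fragment_atoms(
    c("C", "O", "H"),
    c(0, 0.61, 0.52), c(0, 1.06, -0.93), c(0, 0, 0),
    c(0.25, -0.35, 0.08))),
  # position-5 (aromatic C5) substituents
  Hydroxyl = list(bond = 1.36, atoms = fragment_atoms(
    c("O", "H"), c(0, 0.30), c(0, 0.91), c(0, 0),
    c(-0.40, 0.30))),
  Carboxyl = list(bond = 1.48, atoms = fragment_atoms(
    c("C", "O", "O", "H"),
    c(0, 0.58, 0.65, 1.61), c(0, 1.06, -1.12, -0.98),
    c(0, 0, 0, 0), c(0.35, -0.40, -0.35, 0.30))),
  Sulfur = list(bond = 1.77, atoms = fragment_atoms(
    c("S", "H"), c(0, 0.42), c(0, 1.27), c(0, 0),
    c(-0.20, 0.12))),
  Fluorine = list(bond = 1.35, atoms = fragment_atoms(
    "F", 0, 0, 0, -0.22)),
  Chlorine = list(bond = 1.73, atoms = fragment_atoms(
    "Cl", 0, 0, 0, -0.15)),
  Bromine = list(bond = 1.89, atoms = fragment_atoms(
    "Br", 0, 0, 0, -0.12))
)

#' Default substituent sets for positions 1 and 5
#'
#' The twelve groups considered for derivatization: hydrocarbon-type
#' groups at position 1 (-CH3, -H, -C2H5, -C2H3, -C2H, -CO) and compact
#' polar/halogen groups at position 5 (-OH, -COOH, -SH, -F, -Cl, -Br).
#'
#' @param position 1 or 5.
#' @return character vector of group labels (names in the fragment
#'   library).
#' @export
substituent_groups <- function(position) {
  switch(as.character(position),
         "1" = c("Methyl", "Hydrogen", "Ethyl", "Vinyl", "Ethynyl", "Carbonyl"),
         "5" = c("Hydroxyl", "Carboxyl", "Sulfur", "Fluorine", "Chlorine",
                 "Bromine"),
         stop("position must be 1 or 5"))
}

# rotation taking unit e1 onto unit vector v
rotation_e1_to <- function(v) {
  v <- v / sqrt(sum(v^2))
  e1 <- c(1, 0, 0)
  c_ <- sum(e1 * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(-1, -1, 1)))
  u <- c(0, -v[3], v[2]) / sqrt(v[2]^2 + v[3]^2)  # axis = e1 x v normalized
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(acos(c_)) * K + (1 - c_) * (K %*% K)
}

attach_fragment <- function(mol, attachment, group) {
  frag <- FRAGMENT_LIBRARY[[group]]
  if (is.null(frag)) stop("unknown substituent group '", group, "'")
  anchor <- attachment$anchor
  replace <- attachment$replace
  a <- mol$atoms
  dir <- as.numeric(a[replace, c("x", "y", "z")] - a[anchor, c("x", "y", "z")])
  dir <- dir / sqrt(sum(dir^2))
  R <- rotation_e1_to(dir)
  local <- as.matrix(frag$atoms[, c("x", "y", "z")])
  placed <- local %*% t(R)
  base <- as.numeric(a[anchor, c("x", "y", "z")]) + frag$bond * dir
  placed <- sweep(placed, 2, base, `+`)
  newa <- frag$atoms
  newa$x <- placed[, 1]; newa$y <- placed[, 2]; newa$z <- placed[, 3]
  a <- rbind(a[-replace, c("element", "x", "y", "z", "charge")], newa)
  rownames(a) <- NULL
  a
}

derivative_name <- function(template_id, g1 = NULL, g5 = NULL) {
  parts <- character(0)
  if (!is.null(g1)) parts <- c(parts, paste0("1-", g1))
  if (!is.null(g5)) parts <- c(parts, paste0("5-", g5))
  paste(c(parts, template_id), collapse = "-")
}

#' Enumerate single and double substituted derivatives of a template
#'
#' Generates every single substitution at position 1, every single
#' substitution at position 5, and every pairwise double substitution, in
#' that order (position-1 group varying slowest among the doubles), for
#' `|P1| + |P5| + |P1|*|P5|` derivatives in total — 48 for the default
#' 6 + 6 groups.  Fragments are attached with idealized geometry along the
#' direction of the atom they replace.
#'
#' @param template a [molecule] carrying an `attachments` attribute: a
#'   list with entries `"1"` and `"5"`, each `list(anchor =, replace =)`
#'   giving the scaffold anchor atom index and the index of the atom
#'   (usually a hydrogen) removed by the substitution.
#' @param pos1_groups,pos5_groups group label vectors (defaults:
#'   [substituent_groups()]).
#' @return data frame of class `derivative_records` with columns
#'   `id, name, pos1, pos5` and a `molecules` attribute holding the
#'   structures (aligned to the template frame by construction).
#' @export
enumerate_derivatives <- function(template,
                                  pos1_groups = substituent_groups(1),
                                  pos5_groups = substituent_groups(5)) {
  att <- attr(template, "attachments")
  if (is.null(att) || !all(c("1", "5") %in% names(att)))
    stop("template lacks labeled attachment atoms for positions 1 and 5")
  combos <- list()
  for (g in pos1_groups) combos[[length(combos) + 1L]] <- list(g1 = g, g5 = NULL)
  for (g in pos5_groups) combos[[length(combos) + 1L]] <- list(g1 = NULL, g5 = g)
  for (g1 in pos1_groups) for (g5 in pos5_groups)
    combos[[length(combos) + 1L]] <- list(g1 = g1, g5 = g5)

  mols <- vector("list", length(combos))
  rec <- data.frame(
    id = seq_along(combos),
    name = character(length(combos)),
    pos1 = NA_character_, pos5 = NA_character_,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(combos)) {
    cb <- combos[[i]]
    a <- template$atoms[, c("element", "x", "y", "z", "charge")]
    # apply position 5 first so position-1 indices stay valid when the
    # replaced atoms are distinct; recompute indices defensively instead
    m <- template
    if (!is.null(cb$g5)) {
      a2 <- attach_fragment(m, att[["5"]], cb$g5)
      m <- molecule(m$id, a2)
      # position-1 attachment indices are unchanged only if they precede
      # the replaced atom; require that ordering of the template
      if (att[["1"]]$anchor >= att[["5"]]$replace ||
          att[["1"]]$replace >= att[["5"]]$replace)
        stop("template attachment atoms must precede replaced atoms of other positions")
    }
    if (!is.null(cb$g1)) {
      a2 <- attach_fragment(m, att[["1"]], cb$g1)
      m <- molecule(m$id, a2)
    }
    nm <- derivative_name(template$id, cb$g1, cb$g5)
    m$id <- nm
    mols[[i]] <- m
    rec$name[i] <- nm
    rec$pos1[i] <- if (is.null(cb$g1)) NA_character_ else cb$g1
    rec$pos5[i] <- if (is.null(cb$g5)) NA_character_ else cb$g5
  }
  attr(rec, "molecules") <- mols
  class(rec) <- c("derivative_records", "data.frame")
  rec
}

#' Predict derivative CEIs and relative changes
#'
#' Live mode (`model` and `table` supplied): each derivative structure is
#' run through the full field -> descriptor -> PLS chain on the training
#' grid and its CEI predicted.  Fixture mode (`cei` column already present
#' on `records`, e.g. a transcription of published predictions): only the
#' relative-change arithmetic is applied.
#'
#' @param records `derivative_records` (optionally with a `cei` column).
#' @param template_cei CEI of the unmodified template.
#' @param model fitted `pls_model` (live mode).
#' @param table `descriptor_table` the model was fit on (live mode).
#' @param probe probe used for the fields (live mode).
#' @return `records` with `cei` and `rel_change` (%) columns.
#' @export
predict_derivative_cei <- function(records, template_cei, model = NULL,
                                   table = NULL, probe = probe_spec()) {
  if (is.null(records$cei)) {
    if (is.null(model) || is.null(table))
      stop("records carry no predicted CEI; supply `model` and `table` for live prediction")
    mols <- attr(records, "molecules")
    blocks <- lapply(mols, field_block, grid = table$grid, probe = probe)
    X <- descriptor_rows(blocks, table)
    records$cei <- predict(model, X)
  }
  records$rel_change <- relative_change(records$cei, template_cei)
  records
}

#' Range of CEI reductions over a derivative table
#'
#' @param records data frame with a `rel_change` column (%).
#' @return named vector `c(min, max)` of the absolute reductions (%) over
#'   derivatives whose CEI decreased.
#' @export
summarize_reduction_range <- function(records) {
  red <- -records$rel_change[records$rel_change < 0]
  if (length(red) == 0L) stop("no derivative shows a CEI reduction")
  c(min = min(red), max = max(red))
}
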