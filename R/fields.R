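# CoMFA-style probe fields.  Internal unit is kcal/mol; the classical
# 30 kcal/mol truncation corresponds to 125.4 kJ/mol at 4.184 kJ/kcal.
COULOMB_K <- 332.0636   # kcal*Angstrom/(mol*e^2)
FIELD_CUTOFF <- 30.0    # kcal/mol

#' Default CoMFA probe: sp3 carbon, charge +1
#'
#' @param vdw_radius probe van der Waals radius, Angstrom.
#' @param lj_epsilon probe Lennard-Jones well depth, kcal/mol.
#' @param charge probe charge, elementary charges.
#' @return a `probe_spec` list.
#' @export
probe_spec <- function(vdw_radius = 1.70, lj_epsilon = 0.107, charge = 1.0) {
  if (vdw_radius <= 0) stop("probe radius must be positive")
  structure(list(vdw_radius = vdw_radius, lj_epsilon = lj_epsilon,
                 charge = charge), class = "probe_spec")
}

#' Build a shared rectangular lattice around a set of molecules
#'
#' Axis-aligned grid covering the union bounding box of all atoms extended
#' by `margin`, snapped outward to whole multiples of `spacing` so that
#' grids built from nested molecule sets are congruent.
#'
#' @param molecules list of [molecule] objects.
#' @param spacing lattice step, Angstrom.
#' @param margin extra space beyond the bounding box, Angstrom.
#' @return a `grid_spec`: `origin` (length-3), `spacing`, `counts`
#'   (points per axis, each at least 2).
#' @export
make_grid <- function(molecules, spacing = 2.0, margin = 4.0) {
  if (inherits(molecules, "molecule")) molecules <- list(molecules)
  if (length(molecules) < 1L) stop("need at least one molecule")
  if (spacing <= 0) stop("spacing must be positive")
  xyz <- do.call(rbind, lapply(molecules, coords))
  lo <- floor((apply(xyz, 2, min) - margin) / spacing) * spacing
  hi <- ceiling((apply(xyz, 2, max) + margin) / spacing) * spacing
  counts <- pmax(2L, as.integer(round((hi - lo) / spacing)) + 1L)
  structure(list(origin = unname(lo), spacing = spacing, counts = counts),
            class = "grid_spec")
}

#' Lattice point coordinates of a grid
#'
#' Points are ordered with the z index varying fastest, then y, then x
#' (the OpenDX layout, used consistently for descriptor columns).
#'
#' @param grid a `grid_spec`.
#' @return matrix with one row per lattice point and columns x, y, z.
#' @export
grid_points <- function(grid) {
  ax <- lapply(1:3, function(k)
    grid$origin[k] + grid$spacing * (seq_len(grid$counts[k]) - 1L))
  g <- expand.grid(z = ax[[3]], y = ax[[2]], x = ax[[1]],
                   KEEP.OUT.ATTRS = FALSE)
  as.matrix(g[, c("x", "y", "z")])
}

point_atom_dist <- function(pts, mol) {
  xyz <- coords(mol)
  d2 <- outer(rowSums(pts^2), rep(1, nrow(xyz))) +
    outer(rep(1, nrow(pts)), rowSums(xyz^2)) - 2 * pts %*% t(xyz)
  sqrt(pmax(d2, 0))
}

#' Steric (Lennard-Jones 6-12) probe field
#'
#' At each lattice point the probe-atom interaction energy
#' `sum_a eps_a * ((R_a / r)^12 - 2 (R_a / r)^6)` with Lorentz-Berthelot
#' style combining rules `R_a = r_vdw(atom) + r_vdw(probe)`,
#' `eps_a = sqrt(eps_atom * eps_probe)`.  Values are truncated at
#' +/- 30 kcal/mol; a lattice point coinciding with an atom receives the
#' cutoff.
#'
#' @param mol a [molecule].
#' @param grid a `grid_spec`.
#' @param probe a [probe_spec()].
#' @return numeric vector, kcal/mol, one value per lattice point.
#' @export
steric_field <- function(mol, grid, probe = probe_spec()) {
  pts <- grid_points(grid)
  r <- point_atom_dist(pts, mol)
  Rij <- mol$atoms$vdw_radius + probe$vdw_radius
  eps <- sqrt(mol$atoms$lj_epsilon * probe$lj_epsilon)
  e <- matrix(0, nrow(r), ncol(r))
  ok <- r > 1e-9
  for (a in seq_len(ncol(r))) {
    s6 <- (Rij[a] / r[ok[, a], a])^6
    e[ok[, a], a] <- eps[a] * (s6^2 - 2 * s6)
    e[!ok[, a], a] <- FIELD_CUTOFF
  }
  pmin(pmax(rowSums(e), -FIELD_CUTOFF), FIELD_CUTOFF)
}

#' Electrostatic (Coulomb, distance-dependent dielectric) probe field
#'
#' `sum_a 332.0636 * q_a * q_probe / (eps(r) * r)` with the
#' distance-dependent dielectric `eps(r) = r`, so each term falls off as
#' `1/r^2`.  Magnitudes are truncated at 30 kcal/mol.  Lattice points
#' buried inside the molecule (steric value at cutoff) are unphysical for
#' a charged probe; they are returned as-is but flagged via the
#' `"inside"` attribute so that descriptor assembly can impute them.
#'
#' @inheritParams steric_field
#' @return numeric vector (kcal/mol) with logical attribute `"inside"`.
#' @export
electrostatic_field <- function(mol, grid, probe = probe_spec()) {
  pts <- grid_points(grid)
  r <- point_atom_dist(pts, mol)
  q <- mol$atoms$charge
  e <- numeric(nrow(pts))
  if (probe$charge != 0) {
    inv <- 1 / pmax(r, 1e-9)^2
    e <- COULOMB_K * probe$charge * drop(inv %*% q)
    e <- pmin(pmax(e, -FIELD_CUTOFF), FIELD_CUTOFF)
  }
  st <- steric_field(mol, grid, probe)
  attr(e, "inside") <- st >= FIELD_CUTOFF
  e
}

#' Steric + electrostatic field block for one molecule
#'
#' @inheritParams steric_field
#' @return a `field_block`: molecule id, `steric` and `electrostatic`
#'   vectors (kcal/mol per lattice point), `inside` flags, and the grid.
#' @export
field_block <- function(mol, grid, probe = probe_spec()) {
  el <- electrostatic_field(mol, grid, probe)
  structure(list(id = mol$id,
                 steric = steric_field(mol, grid, probe),
                 electrostatic = as.numeric(el),
                 inside = attr(el, "inside"),
                 grid = grid),
            class = "field_block")
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$origin, b$origin)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) && all(a$counts == b$counts)
}

raw_block_matrix <- function(blocks) {
  n_pts <- length(blocks[[1]]$steric)
  S <- t(vapply(blocks, `[[`, numeric(n_pts), "steric"))
  E <- t(vapply(blocks, `[[`, numeric(n_pts), "electrostatic"))
  Fl <- t(vapply(blocks, `[[`, logical(n_pts), "inside"))
  list(S = S, E = E, flag = Fl, n_pts = n_pts)
}

#' Assemble the PLS design matrix from field blocks
#'
#' One row per molecule; columns are the steric then electrostatic lattice
#' values.  Electrostatic cells flagged as inside-the-molecule are imputed
#' by the column mean over the non-flagged molecules.  Columns with
#' standard deviation below `min_sigma` are dropped, and CoMFA-standard
#' block scaling is applied: each field block is divided by its pooled
#' column standard deviation so the two fields contribute equal overall
#' variance.  All bookkeeping needed to transform new molecules and to map
#' coefficients back to lattice points is retained.
#'
#' @param blocks list of [field_block()]s sharing one grid.
#' @param response data frame with `compound` and `cei` columns (e.g. from
#'   [composite_index()]) covering every block, or a named numeric vector.
#' @param min_sigma column standard-deviation filter, kcal/mol
#'   (the classical CoMFA "minimum sigma"; 2.0 by default).
#' @return a `descriptor_table`: `X` (scaled design matrix), `y`,
#'   `columns` (field type + lattice point index per retained column),
#'   `transform` (imputation means, kept columns, block scale factors),
#'   and the grid.
#' @export
assemble_descriptor_table <- function(blocks, response, min_sigma = 2.0) {
  grid <- blocks[[1]]$grid
  for (b in blocks) if (!same_grid(b$grid, grid))
    stop("field blocks were computed on different grids")
  ids <- vapply(blocks, `[[`, character(1), "id")
  if (is.data.frame(response)) {
    y <- response$cei[match(ids, response$compound)]
  } else {
    y <- unname(response[ids])
  }
  if (anyNA(y)) stop("response missing for: ",
                     paste(ids[is.na(y)], collapse = ", "))
  m <- raw_block_matrix(blocks)

  impute_means <- vapply(seq_len(m$n_pts), function(j) {
    out <- m$E[!m$flag[, j], j]
    if (length(out) == 0L) 0 else mean(out)
  }, numeric(1))
  E <- m$E
  for (j in seq_len(m$n_pts))
    E[m$flag[, j], j] <- impute_means[j]

  X0 <- cbind(m$S, E)
  field <- rep(c("steric", "electrostatic"), each = m$n_pts)
  point <- rep(seq_len(m$n_pts), 2L)
  sds <- apply(X0, 2, stats::sd)
  keep <- sds >= min_sigma
  if (!any(keep))
    stop("no descriptor columns survive min_sigma = ", min_sigma)

  block_scale <- c(steric = 1, electrostatic = 1)
  for (f in names(block_scale)) {
    v <- sum(sds[keep & field == f]^2)
    block_scale[f] <- if (v > 0) 1 / sqrt(v) else 1
  }
  X <- sweep(X0[, keep, drop = FALSE], 2,
             block_scale[field[keep]], `*`)
  colnames(X) <- paste0(substr(field[keep], 1, 1), point[keep])
  rownames(X) <- ids
  structure(list(
    X = X, y = y, ids = ids,
    columns = data.frame(field = field[keep], point = point[keep],
                         stringsAsFactors = FALSE),
    transform = list(impute_means = impute_means, keep = keep,
                     block_scale = block_scale, field = field,
                     point = point, min_sigma = min_sigma),
    grid = grid
  ), class = "descriptor_table")
}

#' Descriptor rows for new molecules under a fitted table's transform
#'
#' Applies the imputation means, column filter and block scaling recorded
#' by [assemble_descriptor_table()] to new field blocks, so that
#' predictions for unseen molecules go through the identical descriptor
#' space.
#'
#' @param blocks list of [field_block()]s on the training grid.
#' @param table a `descriptor_table`.
#' @return numeric matrix with one row per block, columns as in `table$X`.
#' @export
descriptor_rows <- function(blocks, table) {
  grid <- table$grid
  for (b in blocks) if (!same_grid(b$grid, grid))
    stop("field blocks do not match the training grid")
  tr <- table$transform
  m <- raw_block_matrix(blocks)
  E <- m$E
  for (j in seq_len(m$n_pts))
    E[m$flag[, j], j] <- tr$impute_means[j]
  X0 <- cbind(m$S, E)
  X <- sweep(X0[, tr$keep, drop = FALSE], 2,
             tr$block_scale[tr$field[tr$keep]], `*`)
  rownames(X) <- vapply(blocks, `[[`, character(1), "id")
  colnames(X) <- colnames(table$X)
  X
}
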