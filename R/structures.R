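# Per-element van der Waals radii (Angstrom) and Lennard-Jones well depths
# (kcal/mol), Tripos-force-field-style values for the elements that occur in
# fluoroquinolone-like series.  Anything else errors loudly rather than
# receiving a silent default.
ELEMENT_PARAMS <- data.frame(
  element = c("H", "C", "N", "O", "F", "S", "Cl", "Br"),
  vdw_radius = c(1.50, 1.70, 1.55, 1.52, 1.47, 1.80, 1.75, 1.85),
  lj_epsilon = c(0.042, 0.107, 0.095, 0.116, 0.109, 0.314, 0.240, 0.320),
  stringsAsFactors = FALSE
)

#' Lennard-Jones parameters for an element
#'
#' @param element character vector of element symbols.
#' @return data frame with `vdw_radius` (Angstrom) and `lj_epsilon`
#'   (kcal/mol) per input element.
#' @export
element_params <- function(element) {
  i <- match(element, ELEMENT_PARAMS$element)
  if (anyNA(i))
    stop("no Lennard-Jones parameters for element(s): ",
         paste(unique(element[is.na(i)]), collapse = ", "))
  ELEMENT_PARAMS[i, c("vdw_radius", "lj_epsilon")]
}

#' Construct a molecule
#'
#' A molecule is an id plus an atom table (element, Cartesian coordinates in
#' Angstrom, partial charge in elementary charges, and per-atom
#' Lennard-Jones parameters).  Missing `vdw_radius`/`lj_epsilon` columns are
#' filled from the bundled per-element table.
#'
#' @param id molecule identifier.
#' @param atoms data frame with columns `element, x, y, z, charge` and
#'   optionally `vdw_radius, lj_epsilon`.
#' @param framework_map optional named integer vector mapping atom indices
#'   of this molecule to atom indices of an alignment template.
#' @return object of class `molecule`.
#' @export
molecule <- function(id, atoms, framework_map = NULL) {
  need <- c("element", "x", "y", "z", "charge")
  if (!all(need %in% names(atoms)))
    stop("`atoms` must have columns: ", paste(need, collapse = ", "))
  if (nrow(atoms) < 1L) stop("a molecule needs at least one atom")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom coordinates must be finite")
  if (is.null(atoms$vdw_radius) || is.null(atoms$lj_epsilon)) {
    p <- element_params(atoms$element)
    atoms$vdw_radius <- p$vdw_radius
    atoms$lj_epsilon <- p$lj_epsilon
  }
  if (any(atoms$vdw_radius <= 0)) stop("vdw_radius must be positive")
  if (!is.null(framework_map)) {
    idx <- as.integer(framework_map)
    if (any(idx < 1L | idx > nrow(atoms)))
      stop("framework_map refers to atoms outside this molecule")
  }
  structure(
    list(id = id, atoms = as.data.frame(atoms, stringsAsFactors = FALSE),
         framework_map = framework_map),
    class = "molecule"
  )
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule>", x$id, "-", nrow(x$atoms), "atoms, net charge",
      signif(sum(x$atoms$charge), 4), "\n")
  invisible(x)
}

coords <- function(mol) as.matrix(mol$atoms[, c("x", "y", "z")])

#' Read aligned structures with partial charges
#'
#' Reads small-molecule structures from SDF (V2000) or MOL2.  MOL2 files
#' carry partial charges natively in the atom block; for SDF the charges are
#' expected in a `PARTIAL_CHARGES` data field (one whitespace-separated
#' value per atom), or supplied via `charge_hook`.
#'
#' @param path file path.
#' @param format `"sdf"` or `"mol2"`; guessed from the extension by default.
#' @param charge_hook optional `function(molecule)` returning a numeric
#'   vector of per-atom charges, used when the file has none.
#' @return list of [molecule] objects.
#' @export
read_structures <- function(path, format = c("auto", "sdf", "mol2"),
                            charge_hook = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sdf = "sdf", mol = "sdf", mol2 = "mol2",
                     stop("cannot guess format from extension '", ext, "'"))
  }
  if (format == "mol2") read_mol2_structures(path, charge_hook)
  else read_sdf_structures(path, charge_hook)
}

read_sdf_structures <- function(path, charge_hook = NULL) {
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
  if (length(sdfs) == 0L) stop("no molecules parsed from ", path)
  lapply(seq_along(sdfs), function(k) {
    sdf <- sdfs[[k]]
    ab <- ChemmineR::atomblock(sdf)
    if (is.null(ab) || nrow(ab) == 0L) stop("corrupt SDF record in ", path)
    el <- sub("_\\d+$", "", rownames(ab))
    db <- ChemmineR::datablock(sdf)
    ch <- NULL
    if ("PARTIAL_CHARGES" %in% names(db))
      ch <- as.numeric(strsplit(trimws(db[["PARTIAL_CHARGES"]]), "\\s+")[[1]])
    atoms <- data.frame(element = el, x = ab[, 1], y = ab[, 2], z = ab[, 3],
                        charge = NA_real_, stringsAsFactors = FALSE)
    id <- ChemmineR::sdfid(sdf)
    if (is.null(id) || !nzchar(id)) id <- paste0("mol", k)
    if (!is.null(ch)) {
      if (length(ch) != nrow(atoms))
        stop("PARTIAL_CHARGES length does not match atom count in ", id)
      atoms$charge <- ch
    }
    mol <- molecule(id, transform_na_charge(atoms))
    resolve_charges(mol, atoms$charge, charge_hook, path)
  })
}

# molecule() requires finite coordinates but charges may still be pending;
# give it zeros and fix afterwards.
transform_na_charge <- function(atoms) {
  atoms$charge[is.na(atoms$charge)] <- 0
  atoms
}

resolve_charges <- function(mol, raw_charges, charge_hook, path) {
  if (all(!is.na(raw_charges))) return(mol)
  if (is.null(charge_hook))
    stop("no partial charges found for '", mol$id, "' in ", path,
         " and no charge_hook supplied")
  ch <- charge_hook(mol)
  if (length(ch) != nrow(mol$atoms))
    stop("charge_hook returned ", length(ch), " charges for ",
         nrow(mol$atoms), " atoms")
  mol$atoms$charge <- ch
  mol
}

read_mol2_structures <- function(path, charge_hook = NULL) {
  # bonds are irrelevant here; bond-free files are legitimate input
  m <- suppressWarnings(bio3d::read.mol2(path))
  # bio3d returns a single mol2 object or a list of them
  mols <- if (inherits(m, "mol2")) list(m) else m
  lapply(seq_along(mols), function(k) {
    a <- mols[[k]]$atom
    el <- sub("\\..*$", "", a$elena)
    el2 <- sub("\\..*$", "", a$elety)  # element lives in the SYBYL atom type
    el <- ifelse(el2 %in% ELEMENT_PARAMS$element, el2, el)
    atoms <- data.frame(element = el, x = a$x, y = a$y, z = a$z,
                        charge = if (is.null(a$charge)) NA_real_ else a$charge,
                        stringsAsFactors = FALSE)
    id <- mols[[k]]$name
    if (is.null(id) || !nzchar(id)) id <- paste0("mol", k)
    mol <- molecule(id, transform_na_charge(atoms))
    resolve_charges(mol, atoms$charge, charge_hook, path)
  })
}

#' Write molecules as SDF (V2000) with a charge property field
#'
#' Minimal V2000 writer used by the synthetic-series generator; partial
#' charges are stored in a `PARTIAL_CHARGES` data field that
#' [read_structures()] understands.
#'
#' @param mols list of [molecule] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    a <- mol$atoms
    writeLines(c(mol$id, "  fuzzcomfa", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(a), 0L), con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       a$x, a$y, a$z, a$element), con)
    writeLines("M  END", con)
    writeLines("> <PARTIAL_CHARGES>", con)
    writeLines(paste(sprintf("%.6f", a$charge), collapse = " "), con)
    writeLines(c("", "$$$$"), con)
  }
  invisible(path)
}

#' Rigid-body least-squares superposition onto a template framework
#'
#' Kabsch superposition: the optimal rotation + translation (no scaling)
#' that maps the molecule's framework atoms onto the corresponding template
#' atoms in the least-squares sense, applied to the whole molecule.  The
#' framework correspondence plays the role of the shared pharmacophore
#' scaffold of a congeneric series.
#'
#' @param mol [molecule] with a `framework_map` (names or positions index
#'   atoms of `mol`, values index atoms of `template`).
#' @param template [molecule] providing the reference frame.
#' @return the transformed molecule, with attribute `"rmsd"` giving the
#'   post-fit RMSD (Angstrom) over the mapped atoms.
#' @export
superpose_on_framework <- function(mol, template) {
  fm <- mol$framework_map
  if (is.null(fm))
    stop("molecule '", mol$id, "' has no framework_map")
  mi <- if (!is.null(names(fm))) as.integer(names(fm)) else seq_along(fm)
  ti <- as.integer(fm)
  if (length(mi) < 3L)
    stop("underdetermined alignment: need at least 3 mapped atoms")
  P <- coords(mol)[mi, , drop = FALSE]       # moving
  Q <- coords(template)[ti, , drop = FALSE]  # fixed
  if (qr(sweep(P, 2, colMeans(P)))$rank < 2L)
    stop("underdetermined alignment: mapped atoms are collinear")
  pc <- colMeans(P); qc <- colMeans(Q)
  H <- t(sweep(P, 2, pc)) %*% sweep(Q, 2, qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  X <- sweep(coords(mol), 2, pc) %*% t(R)
  X <- sweep(X, 2, qc, `+`)
  out <- mol
  out$atoms$x <- X[, 1]; out$atoms$y <- X[, 2]; out$atoms$z <- X[, 3]
  fitted <- X[mi, , drop = FALSE]
  attr(out, "rmsd") <- sqrt(mean(rowSums((fitted - Q)^2)))
  out
}
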