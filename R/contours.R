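#' stdev*coeff grid for one field
#'
#' The classical CoMFA contour quantity: for every retained descriptor
#' column of the chosen field, the column standard deviation (of the
#' design matrix as modelled) times the PLS regression coefficient, mapped
#' back to its lattice point.  Columns removed by the minimum-sigma filter
#' contribute 0.
#'
#' @param model fitted `pls_model`.
#' @param table the `descriptor_table` the model was fit on.
#' @param field `"steric"` or `"electrostatic"`.
#' @return numeric vector over the full lattice (length = product of the
#'   grid counts), in OpenDX point order.
#' @export
stdev_coeff_grid <- function(model, table, field = c("steric", "electrostatic")) {
  field <- match.arg(field)
  if (!field %in% table$columns$field)
    stop("field '", field, "' not present in the descriptor table")
  vals <- numeric(prod(table$grid$counts))
  sel <- table$columns$field == field
  v <- (apply(table$X, 2, stats::sd) * model$coefficients)[sel]
  vals[table$columns$point[sel]] <- v
  vals
}

#' Favored/disfavored contour levels by contribution quantile
#'
#' The favored level is the `favored_fraction` quantile of the positive
#' stdev*coeff values and the disfavored level the `disfavored_fraction`
#' quantile of the negative values (the 80%/20% "contribution" contours of
#' standard CoMFA maps).  Quantiles use linear interpolation between order
#' statistics.  If one sign is absent its level is `NA` with a warning.
#'
#' @param values stdev*coeff grid values.
#' @param favored_fraction quantile for the positive side (default 0.80).
#' @param disfavored_fraction quantile for the negative side (default 0.20).
#' @return list `favored_level, disfavored_level`.
#' @export
contour_levels <- function(values, favored_fraction = 0.80,
                           disfavored_fraction = 0.20) {
  pos <- values[values > 0]
  neg <- values[values < 0]
  fav <- if (length(pos)) unname(stats::quantile(pos, favored_fraction))
         else { warning("no positive values; favored level absent"); NA_real_ }
  dis <- if (length(neg)) unname(stats::quantile(neg, disfavored_fraction))
         else { warning("no negative values; disfavored level absent"); NA_real_ }
  list(favored_level = fav, disfavored_level = dis)
}

#' Build a contour set for a field
#'
#' @inheritParams stdev_coeff_grid
#' @inheritParams contour_levels
#' @return a `contour_set`: field, grid, values, and the two levels.
#' @export
contour_set <- function(model, table, field = c("steric", "electrostatic"),
                        favored_fraction = 0.80, disfavored_fraction = 0.20) {
  field <- match.arg(field)
  values <- stdev_coeff_grid(model, table, field)
  lv <- contour_levels(values, favored_fraction, disfavored_fraction)
  structure(list(field = field, grid = table$grid, values = values,
                 favored_level = lv$favored_level,
                 disfavored_level = lv$disfavored_level),
            class = "contour_set")
}

#' Write a scalar lattice as an OpenDX (.dx) grid file
#'
#' Regular-grid OpenDX text format readable by PyMOL, VMD and Chimera.
#' Values must be in OpenDX point order (z fastest), which is the order
#' [grid_points()] produces.
#'
#' @param values numeric vector over the lattice.
#' @param grid a `grid_spec`.
#' @param path output path.
#' @param comment optional header comment line.
#' @return `path`, invisibly.
#' @export
write_dx <- function(values, grid, path, comment = NULL) {
  n <- grid$counts
  if (length(values) != prod(n))
    stop("length(values) != number of lattice points")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  writeLines(sprintf("object 1 class gridpositions counts %d %d %d",
                     n[1], n[2], n[3]), con)
  writeLines(sprintf("origin %.6f %.6f %.6f",
                     grid$origin[1], grid$origin[2], grid$origin[3]), con)
  writeLines(sprintf("delta %.6f 0 0", grid$spacing), con)
  writeLines(sprintf("delta 0 %.6f 0", grid$spacing), con)
  writeLines(sprintf("delta 0 0 %.6f", grid$spacing), con)
  writeLines(sprintf("object 2 class gridconnections counts %d %d %d",
                     n[1], n[2], n[3]), con)
  writeLines(sprintf(
    "object 3 class array type double rank 0 items %d data follows",
    prod(n)), con)
  full <- c(values, rep(0, (3 - length(values) %% 3) %% 3))
  m <- matrix(sprintf("%.8e", full), ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, paste, collapse = " ")
  extra <- (3 - length(values) %% 3) %% 3
  if (extra > 0) {  # trim padding off the last line
    last <- strsplit(lines[length(lines)], " ")[[1]]
    lines[length(lines)] <- paste(last[seq_len(3 - extra)], collapse = " ")
  }
  writeLines(lines, con)
  writeLines('attribute "dep" string "positions"', con)
  writeLines('object "regular positions regular connections" class field', con)
  writeLines('component "positions" value 1', con)
  writeLines('component "connections" value 2', con)
  writeLines('component "data" value 3', con)
  invisible(path)
}

#' Read an OpenDX grid written by [write_dx()]
#'
#' @param path .dx file path.
#' @return list `values`, `grid`.
#' @export
read_dx <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  counts_line <- grep("gridpositions counts", lines, value = TRUE)[1]
  counts <- as.integer(strsplit(counts_line, "\\s+")[[1]][6:8])
  origin <- as.numeric(strsplit(grep("^origin", lines, value = TRUE)[1],
                                "\\s+")[[1]][2:4])
  delta <- as.numeric(strsplit(grep("^delta", lines, value = TRUE)[1],
                               "\\s+")[[1]][2])
  i0 <- grep("data follows", lines)[1]
  i1 <- grep('attribute "dep"', lines)[1]
  values <- as.numeric(unlist(strsplit(trimws(lines[(i0 + 1):(i1 - 1)]),
                                       "\\s+")))
  list(values = values[seq_len(prod(counts))],
       grid = structure(list(origin = origin, spacing = delta,
                             counts = counts), class = "grid_spec"))
}

#' Write a contour set as an OpenDX file pair
#'
#' Writes `<path>.dx` with the stdev*coeff values and
#' `<path>_levels.json` with the favored/disfavored isolevels, ready for
#' rendering in an external viewer.
#'
#' @param set a `contour_set`.
#' @param path output path stem (no extension).
#' @return character vector of the two paths written, invisibly.
#' @export
write_contours <- function(set, path) {
  dx <- paste0(path, ".dx")
  js <- paste0(path, "_levels.json")
  write_dx(set$values, set$grid, dx,
           comment = paste("stdev*coeff", set$field, "field"))
  jsonlite::write_json(
    list(field = set$field,
         favored_level = set$favored_level,
         disfavored_level = set$disfavored_level),
    js, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(c(dx, js))
}
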