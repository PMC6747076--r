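# Shared builders for the synthetic field/PLS pipeline; the full pipeline
# object is built once per test run and reused.

toy_molecule <- function(id = "m", element = "C", x = 0, y = 0, z = 0,
                         charge = 0, vdw_radius = NULL, lj_epsilon = NULL) {
  atoms <- data.frame(element = element, x = x, y = y, z = z,
                      charge = charge, stringsAsFactors = FALSE)
  if (!is.null(vdw_radius)) {
    atoms$vdw_radius <- vdw_radius
    atoms$lj_epsilon <- lj_epsilon
  }
  molecule(id, atoms)
}

.pipeline_cache <- new.env(parent = emptyenv())

synthetic_pipeline <- function() {
  if (!is.null(.pipeline_cache$pipe)) return(.pipeline_cache$pipe)
  ss <- synthetic_series(n = 29, seed = 7, noise_sd = 0.1)
  grid <- make_grid(ss$molecules)
  blocks <- lapply(ss$molecules, field_block, grid = grid)
  resp <- data.frame(compound = vapply(ss$molecules, `[[`, "", "id"),
                     cei = ss$activity)
  tab <- assemble_descriptor_table(blocks, resp, min_sigma = 0.5)
  cv <- loo_crossvalidate(tab$X, tab$y, max_components = 6)
  n_opt <- select_components(cv)
  fit <- fit_pls(tab$X, tab$y, n_opt)
  .pipeline_cache$pipe <- list(series = ss, grid = grid, blocks = blocks,
                               table = tab, cv = cv, n_opt = n_opt,
                               fit = fit)
  .pipeline_cache$pipe
}
xyz_of <- function(mol) as.matrix(mol$atoms[, c("x", "y", "z")])
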