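test_that("grid construction snaps outward to whole steps", {
  m <- toy_molecule("a", charge = 0)
  g <- make_grid(m, spacing = 2, margin = 4)
  expect_equal(g$origin, c(-4, -4, -4))
  expect_equal(g$counts, rep(5L, 3))
  expect_equal(nrow(grid_points(g)), 125L)
  # zero margin on a point molecule still yields >= 2 points per axis
  g0 <- make_grid(m, spacing = 1, margin = 0)
  expect_true(all(g0$counts >= 2L))
})

test_that("the grid encloses every molecule", {
  m1 <- toy_molecule("a", x = -3, charge = 0)
  m2 <- toy_molecule("b", x = 7, y = 5, charge = 0)
  g <- make_grid(list(m1, m2), spacing = 2, margin = 4)
  pts <- grid_points(g)
  hi <- g$origin + (g$counts - 1) * g$spacing
  for (m in list(m1, m2)) {
    expect_true(all(xyz_of(m) >= rep(g$origin, each = nrow(xyz_of(m)))))
    expect_true(all(xyz_of(m) <= rep(hi, each = nrow(xyz_of(m)))))
  }
})

test_that("steric field has the Lennard-Jones closed forms and cutoff", {
  probe <- probe_spec()
  m <- toy_molecule("c", charge = 0)  # single carbon at origin
  far <- structure(list(origin = c(60, 0, 0), spacing = 1, counts = c(2L, 2L, 2L)),
                   class = "grid_spec")
  expect_true(all(abs(steric_field(m, far, probe)) < 1e-6))

  Rij <- 1.70 + probe$vdw_radius
  eps <- sqrt(0.107 * probe$lj_epsilon)
  at_min <- structure(list(origin = c(Rij, 0, 0), spacing = 1, counts = c(2L, 2L, 2L)),
                      class = "grid_spec")
  expect_equal(steric_field(m, at_min, probe)[1], -eps, tolerance = 1e-10)

  close <- structure(list(origin = c(0.5, 0, 0), spacing = 1, counts = c(2L, 2L, 2L)),
                     class = "grid_spec")
  expect_equal(steric_field(m, close, probe)[1], 30.0)
})

test_that("electrostatic field follows the 1/r^2 law with truncation", {
  g <- structure(list(origin = c(2, 0, 0), spacing = 1, counts = c(2L, 2L, 2L)),
                 class = "grid_spec")
  m <- toy_molecule("q", charge = 1)
  neutral <- probe_spec(charge = 0)
  expect_true(all(electrostatic_field(m, g, neutral) == 0))
  # 332.0636 / (2 * 2) = 83.0159 exceeds the 30 kcal/mol cutoff
  expect_equal(electrostatic_field(m, g, probe_spec())[1], 30.0)
  weak <- toy_molecule("q", charge = 0.01)
  expect_equal(electrostatic_field(weak, g, probe_spec())[1],
               332.0636 * 0.01 / 4, tolerance = 1e-10)
  # sign flip of the atomic charges negates the field outside flagged points
  e1 <- electrostatic_field(weak, g, probe_spec())
  weak2 <- weak; weak2$atoms$charge <- -weak2$atoms$charge
  e2 <- electrostatic_field(weak2, g, probe_spec())
  out <- !attr(e1, "inside")
  expect_equal(as.numeric(e1)[out], -as.numeric(e2)[out], tolerance = 1e-12)
})

test_that("fields are equivariant under a shared translation", {
  m <- toy_molecule("two", element = c("C", "O"), x = c(0, 1.2),
                    y = c(0, 0.4), z = c(0, -0.3), charge = c(0.2, -0.2))
  g <- make_grid(m, spacing = 1.5, margin = 3)
  b0 <- field_block(m, g)
  shift <- c(2.5, -1.0, 0.7)
  m2 <- m
  m2$atoms$x <- m2$atoms$x + shift[1]
  m2$atoms$y <- m2$atoms$y + shift[2]
  m2$atoms$z <- m2$atoms$z + shift[3]
  g2 <- structure(list(origin = g$origin + shift, spacing = g$spacing,
                       counts = g$counts), class = "grid_spec")
  b2 <- field_block(m2, g2)
  expect_equal(b2$steric, b0$steric, tolerance = 1e-8)
  expect_equal(b2$electrostatic, b0$electrostatic, tolerance = 1e-8)
  expect_identical(b2$inside, b0$inside)
})

test_that("fields reflect under a mirror plane", {
  m <- toy_molecule("two", element = c("C", "N"), x = c(0.3, 1.4),
                    y = c(0.2, -0.5), z = c(0.1, 0.6), charge = c(0.1, -0.1))
  g <- make_grid(m, spacing = 2, margin = 4)
  b <- field_block(m, g)
  # mirror through z = 0: negate z of atoms and grid origin span
  m2 <- m; m2$atoms$z <- -m2$atoms$z
  hi_z <- g$origin[3] + (g$counts[3] - 1) * g$spacing
  g2 <- structure(list(origin = c(g$origin[1], g$origin[2], -hi_z),
                       spacing = g$spacing, counts = g$counts),
                  class = "grid_spec")
  b2 <- field_block(m2, g2)
  # the mirrored lattice runs in reverse z order
  arr <- array(b$steric, dim = rev(g$counts))
  arr2 <- array(b2$steric, dim = rev(g$counts))
  expect_equal(arr2, arr[dim(arr)[1]:1, , , drop = FALSE], tolerance = 1e-8)
})

test_that("fields are additive over atoms away from the cutoff", {
  a1 <- toy_molecule("a1", x = -1, charge = 0.05)
  a2 <- toy_molecule("a2", x = 1, charge = -0.03)
  both <- molecule("both", rbind(a1$atoms, a2$atoms))
  g <- structure(list(origin = c(-8, 4, -8), spacing = 2,
                      counts = c(9L, 3L, 9L)), class = "grid_spec")
  s <- steric_field(both, g)
  s1 <- steric_field(a1, g); s2 <- steric_field(a2, g)
  ok <- abs(s) < 29 & abs(s1) < 29 & abs(s2) < 29
  expect_true(mean(ok) > 0.9)
  expect_equal(s[ok], (s1 + s2)[ok], tolerance = 1e-8)
  e <- as.numeric(electrostatic_field(both, g))
  e1 <- as.numeric(electrostatic_field(a1, g))
  e2 <- as.numeric(electrostatic_field(a2, g))
  expect_equal(e[ok], (e1 + e2)[ok], tolerance = 1e-8)
})

test_that("descriptor assembly aligns rows, filters and scales blocks", {
  m1 <- toy_molecule("m1", element = c("C", "O"), x = c(0, 1.3),
                     y = c(0, 0), z = c(0, 0), charge = c(0.2, -0.2))
  m2 <- m1; m2$id <- "m2"
  m3 <- toy_molecule("m3", element = c("C", "O"), x = c(0, 1.6),
                     y = c(0, 0.4), z = c(0, 0), charge = c(0.4, -0.4))
  g <- make_grid(list(m1, m3), spacing = 2, margin = 3)
  blocks <- lapply(list(m1, m2, m3), field_block, grid = g)
  resp <- data.frame(compound = c("m1", "m2", "m3"), cei = c(0.2, 0.2, 0.8))
  tab <- assemble_descriptor_table(blocks, resp, min_sigma = 0.01)
  expect_identical(rownames(tab$X)[1:2], c("m1", "m2"))
  expect_equal(tab$X[1, ], tab$X[2, ])  # identical molecules, identical rows
  expect_equal(nrow(tab$columns), ncol(tab$X))
  # per-block pooled column variance is equalized by the block scaling
  v <- tapply(apply(tab$X, 2, stats::sd)^2, tab$columns$field, sum)
  expect_equal(unname(v["steric"]), unname(v["electrostatic"]), tolerance = 1e-9)
  expect_error(assemble_descriptor_table(blocks, resp, min_sigma = 1e6),
               "min_sigma")
  # transform applied to the training blocks reproduces the training rows
  expect_equal(descriptor_rows(blocks, tab), tab$X, tolerance = 1e-12)
})

test_that("mismatched grids are rejected", {
  m <- toy_molecule("m", charge = 0.1)
  b1 <- field_block(m, make_grid(m, spacing = 2, margin = 4))
  b2 <- field_block(m, make_grid(m, spacing = 1, margin = 4))
  resp <- data.frame(compound = "m", cei = 0.5)
  expect_error(assemble_descriptor_table(list(b1, b2), resp), "grid")
})
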