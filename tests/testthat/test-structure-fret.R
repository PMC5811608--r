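test_that("a minimal hand-written PDB is read with correct coordinates", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.500   2.000   3.000  1.00  0.00           C",
    "ATOM      3  CB  ALA A   1       3.000   3.500   3.000  1.00  0.00           C",
    "END"), path)
  m <- read_structure(path)
  expect_equal(nrow(m$atoms), 3L)
  expect_equal(m$atoms$x, c(1.0, 2.5, 3.0))
  expect_equal(m$atoms$element, c("N", "C", "C"))
  expect_equal(m$atoms$radius, c(1.55, 1.70, 1.70))
})

test_that("structures round-trip through PDB at coordinate precision", {
  toy <- generate_toy_structure(n_atoms_per_domain = 10, separation = 30,
                                seed = 6)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(toy, path)
  back <- read_structure(path)
  expect_equal(nrow(back$atoms), nrow(toy$atoms))
  expect_lt(max(abs(back$atoms$x - toy$atoms$x)), 1e-3 + 1e-9)
  expect_lt(max(abs(back$atoms$y - toy$atoms$y)), 1e-3 + 1e-9)
  expect_lt(max(abs(back$atoms$z - toy$atoms$z)), 1e-3 + 1e-9)
})

test_that("alternate locations keep the highest-occupancy copy", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA  ALA A   2       9.000   0.000   0.000  1.00  0.00           C",
    "END"), path)
  m <- read_structure(path)
  expect_equal(nrow(m$atoms), 2L)
  expect_equal(m$atoms$x[m$atoms$resno == 1], 5.0)
})

test_that("renumbering maps are applied explicitly and completely", {
  toy <- generate_toy_structure(n_atoms_per_domain = 2, seed = 1)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(toy, path)
  m <- read_structure(path, renumber = data.frame(auth = 1:4,
                                                  target = 101:104))
  expect_equal(sort(unique(m$atoms$resno)), 101:104)
  expect_error(read_structure(path, renumber = data.frame(auth = 1:2,
                                                          target = 1:2)),
               "misses")
})

test_that("ca_distance is zero on a residue against itself and exact on a
           constructed separation", {
  toy <- generate_toy_structure(n_atoms_per_domain = 4, separation = 51,
                                seed = 3)
  expect_equal(ca_distance(toy, 1, 1), 0)
  expect_equal(ca_distance(toy, 1, 5), 51.0)
  expect_error(ca_distance(toy, 1, 999), "999")
})

test_that("an unobstructed accessible volume fills the linker ball", {
  m <- structure_model(data.frame(element = "C", name = "CA", resno = 1,
                                  chain = "A", x = 0, y = 0, z = 0))
  p <- dye_params(L = 10, grid_spacing = 1)
  av <- compute_av(m, 1, atom = "CA", params = p)
  r <- sqrt(rowSums(av$points^2))
  expect_true(all(r <= p$L + 1e-9))
  # centroid at the attachment point by symmetry
  expect_lt(max(abs(colMeans(av$points))), p$grid_spacing / 10)
  # volume close to the analytic ball volume (chamfer metric and voxel
  # discretisation each cost a few per cent)
  vol <- nrow(av$points) * p$grid_spacing^3
  expect_lt(abs(vol / (4 / 3 * pi * p$L^3) - 1), 0.10)
})

test_that("a wall of atoms confines the cloud to one half-space", {
  # plane of atoms at x = +2 A (the attachment atom sits at the origin)
  grid <- expand.grid(y = seq(-25, 25, by = 1.5), z = seq(-25, 25, by = 1.5))
  wall <- data.frame(element = "C", name = "CA",
                     resno = seq_len(nrow(grid)) + 1, chain = "A",
                     x = 2, y = grid$y, z = grid$z)
  att <- data.frame(element = "C", name = "CA", resno = 1, chain = "A",
                    x = 0, y = 0, z = 0)
  m <- structure_model(rbind(att, wall))
  av <- compute_av(m, 1, atom = "CA", params = dye_params(L = 12,
                                                          grid_spacing = 1))
  expect_true(all(av$points[, "x"] < 2))
  # centroid pushed away from the wall along the free normal
  expect_lt(mean(av$points[, "x"]), -1)
  expect_lt(abs(mean(av$points[, "y"])), 0.5)
})

test_that("accessible volumes shrink as the dye radius grows", {
  toy <- generate_toy_structure(n_atoms_per_domain = 25, domain_radius = 8,
                                separation = 18, seed = 12)
  key <- function(av) paste(av$points[, 1], av$points[, 2], av$points[, 3])
  av_small <- compute_av(toy, 1, atom = "CA",
                         params = dye_params(r = 2, grid_spacing = 1))
  av_big <- compute_av(toy, 1, atom = "CA",
                       params = dye_params(r = 4.5, grid_spacing = 1))
  expect_true(all(key(av_big) %in% key(av_small)))
  expect_lt(nrow(av_big$points), nrow(av_small$points))
})

test_that("a fully occluded site raises an informative error", {
  # attachment atom tightly caged by a dense shell
  shell <- expand.grid(x = seq(-3, 3, by = 1), y = seq(-3, 3, by = 1),
                       z = seq(-3, 3, by = 1))
  shell <- shell[rowSums(abs(shell)) > 0, ]
  cage <- data.frame(element = "C", name = "CA",
                     resno = seq_len(nrow(shell)) + 1, chain = "A",
                     x = shell$x, y = shell$y, z = shell$z)
  att <- data.frame(element = "C", name = "CA", resno = 1, chain = "A",
                    x = 0, y = 0, z = 0)
  m <- structure_model(rbind(att, cage))
  expect_error(compute_av(m, 1, atom = "CA",
                          params = dye_params(L = 8, grid_spacing = 1)),
               "occluded")
})

test_that("mean FRET reproduces closed-form single-distance values", {
  d <- av_point_cloud(c(0, 0, 0))
  a51 <- av_point_cloud(c(51, 0, 0))
  expect_equal(mean_fret(d, a51, R0 = 51)$mean_E, 0.5)
  a153 <- av_point_cloud(c(153, 0, 0))
  expect_equal(mean_fret(d, a153, R0 = 51)$mean_E, 1 / 730,
               tolerance = 1e-12)
})

test_that("mean FRET equals the exhaustive pair average and is symmetric", {
  set.seed(4)
  pd <- matrix(rnorm(9, sd = 3), 3)
  pa <- matrix(rnorm(9, sd = 3) + c(40, 0, 0), 3)
  cd <- av_point_cloud(pd); ca <- av_point_cloud(pa)
  pred <- mean_fret(cd, ca, R0 = 51)
  manual <- mean(sapply(1:3, function(i) sapply(1:3, function(j) {
    r <- sqrt(sum((pd[i, ] - pa[j, ])^2))
    1 / (1 + (r / 51)^6)
  })))
  expect_equal(pred$mean_E, manual, tolerance = 1e-12)
  expect_true(pred$exhaustive)
  expect_equal(mean_fret(ca, cd, R0 = 51)$mean_E, pred$mean_E)
})

test_that("Monte-Carlo pair sampling converges to the exhaustive mean", {
  set.seed(5)
  pd <- matrix(rnorm(300, sd = 5), ncol = 3)
  pa <- matrix(rnorm(300, sd = 5) + c(45, 0, 0), ncol = 3)
  cd <- av_point_cloud(pd); ca <- av_point_cloud(pa)
  exact <- mean_fret(cd, ca, R0 = 51, n_samples = 1e5)
  expect_true(exact$exhaustive)
  n_mc <- 4000
  mc <- mean_fret(cd, ca, R0 = 51, n_samples = n_mc, seed = 77)
  expect_false(mc$exhaustive)
  # spread of single-pair efficiencies bounds the MC error
  r <- sqrt(rowSums((pd[sample(100, 100, replace = TRUE), ] -
                       pa[sample(100, 100, replace = TRUE), ])^2))
  sd_e <- stats::sd(1 / (1 + (r / 51)^6))
  expect_lt(abs(mc$mean_E - exact$mean_E), 3 * sd_e / sqrt(n_mc))
})

test_that("mean FRET decreases when the clouds are pulled apart", {
  d <- av_point_cloud(matrix(rnorm(60), ncol = 3))
  base <- matrix(rnorm(60), ncol = 3)
  e_at <- function(sep) mean_fret(d, av_point_cloud(sweep(base, 2,
    c(sep, 0, 0), "+")), R0 = 51)$mean_E
  es <- vapply(c(30, 45, 60, 80), e_at, numeric(1))
  expect_true(all(diff(es) < 0))
})
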