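# hand-built field volume on the small parcellation grid
synthetic_field <- function(parc, fx, fy = 0, fz = 0) {
  d <- parc$dims
  mk <- function(v) array(v, dim = d)
  structure(list(Ex = mk(fx), Ey = mk(fy), Ez = mk(fz),
                 mask = mk(TRUE), dims = d, spacing = parc$spacing,
                 origin = parc$origin, affine = parc$affine),
            class = "field_volume")
}

test_that("rasterization reproduces a uniform field and masks the outside", {
  m <- small_mesh()
  # constant-gradient potential => uniform element field (0.5, 0, 0) V/m
  phi <- -m$nodes[, 1] * 0.5 / 1000
  sol <- structure(list(
    potentials = phi,
    field = fieldsteer:::element_field_from_potentials(m, phi)$field,
    enorm = NULL, montage = NULL, mesh = m,
    diagnostics = list()), class = "potential_solution")
  fv <- rasterize_field(sol, small_grid())
  inside <- fv$mask
  expect_equal(unname(range(fv$Ex[inside])), c(0.5, 0.5), tolerance = 1e-9)
  expect_true(all(is.na(fv$Ex[!inside])))
  # valid-voxel volume approximates the mesh volume
  vox_vol <- sum(inside) * fv$spacing^3
  expect_lt(abs(vox_vol - mesh_volume(m)) / mesh_volume(m), 0.03)
  # a grid that misses the mesh entirely is rejected
  far <- structure(list(dims = c(5L, 5L, 5L), spacing = 1,
                        origin = c(500, 500, 500),
                        affine = rbind(cbind(diag(3), 500), c(0, 0, 0, 1))),
                   class = "field_grid")
  expect_error(rasterize_field(sol, far), "overlap")
})

test_that("lobule means implement unweighted voxel averages", {
  parc <- small_parc()
  fv <- synthetic_field(parc, fx = 1)
  tab <- lobule_means(fv, parc)
  expect_identical(nrow(tab), 29L)
  expect_equal(tab$Ex, rep(1, 29))
  expect_equal(tab$Enorm, rep(1, 29))
  expect_true(all(tab$n_voxels > 0))
  # signed means cancel where magnitudes do not: +1/-1 checkerboard
  d <- parc$dims
  sgn <- array(rep_len(c(1, -1), prod(d)), dim = d)
  fv2 <- synthetic_field(parc, fx = sgn)
  tab2 <- lobule_means(fv2, parc)
  big <- tab2$n_voxels > 100 # even/odd imbalance shrinks with region size
  expect_lt(max(abs(tab2$Ex[big])), 0.05)
  expect_equal(tab2$Enorm, rep(1, 29))
  # magnitude mean dominates componentwise means everywhere
  expect_true(all(tab2$Enorm >= pmax(abs(tab2$Ex), abs(tab2$Ey),
                                     abs(tab2$Ez)) - 1e-12))
})

test_that("lobule means match a direct tapply computation", {
  parc <- small_parc()
  set.seed(21)
  d <- parc$dims
  fv <- synthetic_field(parc, fx = array(rnorm(prod(d)), d),
                        fy = array(rnorm(prod(d)), d))
  tab <- lobule_means(fv, parc)
  lab <- as.integer(parc$labels)
  keep <- lab > 0
  ref <- tapply(as.numeric(fv$Ex)[keep], lab[keep], mean)
  expect_equal(tab$Ex, as.numeric(ref), tolerance = 1e-12)
  refE <- tapply(sqrt(as.numeric(fv$Ex)[keep]^2 + as.numeric(fv$Ey)[keep]^2),
                 lab[keep], mean)
  expect_equal(tab$Enorm, as.numeric(refE), tolerance = 1e-12)
})

test_that("zero-voxel regions and grid mismatches are rejected by name", {
  parc <- small_parc()
  fv <- synthetic_field(parc, fx = 1)
  fv$mask[parc$labels == 3L] <- FALSE # empty out Left_VI
  expect_error(lobule_means(fv, parc), "Left_VI")
  fv2 <- synthetic_field(parc, fx = 1)
  fv2$affine[1, 4] <- fv2$affine[1, 4] + 5
  expect_error(lobule_means(fv2, parc), "affine")
})

test_that("region means are stable under grid refinement on smooth fields", {
  m <- small_mesh()
  mo <- make_montage_preset("celnik", m)
  sol <- solve_potential(m, mo)
  p2 <- small_parc()
  p1 <- build_parcellation(m, spacing = 1.4)
  g1 <- structure(list(dims = p1$dims, spacing = p1$spacing,
                       origin = p1$origin, affine = p1$affine),
                  class = "field_grid")
  t2 <- lobule_means(rasterize_field(sol, small_grid()), p2)
  t1 <- lobule_means(rasterize_field(sol, g1), p1)
  expect_lt(max(abs(t1$Enorm - t2$Enorm) / t2$Enorm), 0.02)
})

test_that("current density reproduces the published worked values", {
  expect_identical(current_density(2, 25), 0.08)
  expect_identical(current_density(1, 3.14), 0.32)
  expect_identical(current_density(0, 7), 0)
  expect_equal(current_density(1, 3.14, digits = NULL), 1 / 3.14,
               tolerance = 1e-15)
  expect_error(current_density(1, 0), "area")
})
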