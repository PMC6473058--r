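single_tet_mesh <- function(verts, sigma = 1) {
  structure(list(
    nodes = verts,
    elements = matrix(1:4, 1L),
    element_label = 1L,
    shells = shell_spec("tissue", 100, sigma),
    volumes = NULL, param = NULL), class = "head_mesh")
}

test_that("montage presets carry the published currents and pad areas", {
  m <- small_mesh()
  cel <- make_montage_preset("celnik", m)
  expect_equal(cel$currents_mA, c(2, -2))
  expect_equal(cel$electrodes$area_cm2, c(25, 25))
  man <- make_montage_preset("manto", m)
  expect_equal(man$currents_mA, c(2, -2))
  expect_equal(man$electrodes$area_cm2, c(25, 25))
  hd <- make_montage_preset("hd4x1", m)
  expect_equal(hd$currents_mA, c(1, rep(-0.25, 4)))
  expect_equal(hd$electrodes$area_cm2[1], pi, tolerance = 1e-12) # 3.14 cm^2
  for (mo in list(cel, man, hd)) expect_identical(sum(mo$currents_mA), 0)
  expect_error(make_montage_preset("nope", m))
  expect_error(montage(cel$electrodes, c(2, -1.5)), "sum to 0")
})

test_that("local stiffness of a single tetrahedron matches hand assembly", {
  # independent oracle: barycentric gradients from the inverse of the
  # [1; x; y; z] coordinate matrix, K = sigma * V * G G^T
  verts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  sigma <- 2.5
  M <- rbind(1, t(verts))
  G <- solve(M)[, 2:4, drop = FALSE] # rows: grad lambda_i
  V <- abs(det(rbind(t(verts[2:4, ]) - verts[1, ]))) / 6
  K_ref <- sigma * V * G %*% t(G)
  mesh <- single_tet_mesh(verts, sigma)
  K <- as.matrix(assemble_system(mesh))
  expect_equal(K, K_ref, tolerance = 1e-12, ignore_attr = TRUE)
  # regular tetrahedron too
  verts2 <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  M2 <- rbind(1, t(verts2))
  G2 <- solve(M2)[, 2:4, drop = FALSE]
  V2 <- abs(det(rbind(t(verts2[2:4, ]) - verts2[1, ]))) / 6
  K2 <- as.matrix(assemble_system(single_tet_mesh(verts2)))
  expect_equal(K2, V2 * G2 %*% t(G2), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("stiffness operator is linear in sigma with the constant nullspace", {
  m <- small_mesh()
  K1 <- assemble_system(m)
  Kc <- assemble_system(m, tissues = 3 * tissue_conductivities(m))
  expect_equal(Kc@x, 3 * K1@x, tolerance = 1e-12)
  ones <- rep(1, nrow(m$nodes))
  expect_lt(max(abs(K1 %*% ones)), 1e-10 * max(abs(K1@x)))
  # missing conductivity is reported by label
  expect_error(assemble_system(m, tissues = c(a = 1, b = 1)), "label")
})

test_that("zero-current montage yields identically zero potential and field", {
  m <- small_mesh()
  tab <- electrode_spec(c("a", "b"), rbind(c(0, 0, 92), c(92, 0, 0)),
                        radius_cm = 0.5, role = c("stim", "reference"))
  sol <- solve_potential(m, montage(tab, c(0, 0)))
  expect_identical(max(abs(sol$potentials)), 0)
  expect_identical(max(abs(sol$field)), 0)
})

test_that("the Neumann load conserves current and couples every electrode", {
  m <- small_mesh()
  mo <- make_montage_preset("hd4x1", m)
  ld <- fieldsteer:::electrode_load(m, mo)
  expect_lt(abs(sum(ld$f)), 1e-12)
  expect_true(all(ld$facet_count >= 1L))
})

test_that("swapping source and sink negates the solution; scaling doubles it", {
  m <- small_mesh()
  R <- 92
  tab <- electrode_spec(c("a", "b"), rbind(c(0, -R, 0), c(0, 0, R)),
                        radius_cm = 0.5, role = c("stim", "reference"))
  s1 <- solve_potential(m, montage(tab, c(1, -1)))
  s2 <- solve_potential(m, montage(tab, c(-1, 1)))
  expect_equal(s1$potentials, -s2$potentials, tolerance = 1e-10)
  s3 <- solve_potential(m, montage(tab, c(2, -2)))
  expect_equal(s3$field, 2 * s1$field, tolerance = 1e-10)
  expect_equal(s3$potentials, 2 * s1$potentials, tolerance = 1e-10)
})

test_that("potentials are gauged to zero mean over scalp nodes", {
  m <- small_mesh()
  sol <- solve_potential(m, uniform_ball_montage(m))
  scalp <- fieldsteer:::scalp_nodes(m)
  expect_lt(abs(mean(sol$potentials[scalp])), 1e-12 * max(abs(sol$potentials)))
})

test_that("reciprocity: drive and measurement electrodes are exchangeable", {
  m <- small_mesh()
  R <- 92
  tabA <- electrode_spec(c("a1", "a2"), rbind(c(0, -R, 0), c(0, 0, R)),
                         radius_cm = 0.5, role = c("stim", "reference"))
  tabB <- electrode_spec(c("b1", "b2"), rbind(c(R, 0, 0), c(-60, 40, 56.5)),
                         radius_cm = 0.5, role = c("stim", "reference"))
  moA <- montage(tabA, c(1, -1)); moB <- montage(tabB, c(1, -1))
  solA <- solve_potential(m, moA)
  solB <- solve_potential(m, moB)
  uB_under_A <- electrode_potential_difference(m, moB, solA)
  uA_under_B <- electrode_potential_difference(m, moA, solB)
  expect_equal(uB_under_A, uA_under_B, tolerance = 1e-8)
})

test_that("deflated CG agrees with the direct solve at its tolerance", {
  m <- small_mesh()
  mo <- make_montage_preset("celnik", m)
  sd_ <- solve_potential(m, mo, method = "cholesky")
  sc <- solve_potential(m, mo, method = "cg", tol = 1e-10)
  expect_lt(sqrt(sum((sd_$potentials - sc$potentials)^2)) /
              sqrt(sum(sd_$potentials^2)), 1e-7)
  expect_lte(sc$diagnostics$residual, 1e-10)
  expect_error(solve_potential(m, mo, method = "cg", maxit = 3L),
               "converge")
})

test_that("element fields differentiate linear potentials exactly", {
  m <- small_mesh()
  # impose phi = x / 1000 (V): E = -grad phi = (-1, 0, 0) V/m
  ef <- fieldsteer:::element_field_from_potentials(m, m$nodes[, 1] / 1000)
  expect_equal(ef$field[, 1], rep(-1, nrow(m$elements)), tolerance = 1e-9)
  expect_lt(max(abs(ef$field[, 2:3])), 1e-9)
  expect_equal(ef$enorm, rep(1, nrow(m$elements)), tolerance = 1e-9)
})

test_that("FEM interior potentials track the series oracle on the ball", {
  mesh <- fixture("homog_mesh_12", function() {
    build_shell_phantom(shell_spec("uniform", 92, 1), resolution = 12)
  })
  sol <- solve_potential(mesh, uniform_ball_montage(mesh))
  obs <- interior_obs_points(92)
  pf <- interpolate_potential(sol, obs)
  po <- potential_multishell(shell_spec("uniform", 92, 1),
                             list(position = c(0, 0, 92), current = 1),
                             list(position = c(0, 0, -92), current = -1),
                             obs, n_terms = 150)$potential
  pf <- pf - mean(pf); po <- po - mean(po)
  expect_lt(sqrt(sum((pf - po)^2) / sum(po^2)), 0.10)
})
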