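# Shared fixtures, built lazily once per test run. Sizes are chosen so
# the full suite stays at desk scale: the "small" phantom (14 mm
# elements, 2 mm voxels) backs the unit tests, while the acceptance
# suite uses the default-resolution phantom (8 mm elements, 1 mm
# voxels) the package ships as its standard configuration.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

small_mesh <- function() fixture("small_mesh", function() {
  build_shell_phantom(default_head_shells(), resolution = 14)
})

small_parc <- function() fixture("small_parc", function() {
  build_parcellation(small_mesh(), spacing = 2)
})

small_grid <- function() fixture("small_grid", function() {
  p <- small_parc()
  structure(list(dims = p$dims, spacing = p$spacing, origin = p$origin,
                 affine = p$affine), class = "field_grid")
})

small_catalog <- function() fixture("small_catalog", function() {
  candidate_layout(small_mesh(), n = 6)
})

small_leadfield <- function() fixture("small_leadfield", function() {
  assemble_leadfield(small_mesh(), small_catalog(), small_parc())
})

# default-resolution phantom for the acceptance suite
accept_mesh <- function() fixture("accept_mesh", function() {
  build_shell_phantom(default_head_shells(), resolution = 8)
})

accept_parc <- function() fixture("accept_parc", function() {
  build_parcellation(accept_mesh(), spacing = 1)
})

accept_grid <- function() fixture("accept_grid", function() {
  p <- accept_parc()
  structure(list(dims = p$dims, spacing = p$spacing, origin = p$origin,
                 affine = p$affine), class = "field_grid")
})

accept_catalog8 <- function() fixture("accept_catalog8", function() {
  candidate_layout(accept_mesh(), n = 8)
})

accept_leadfield8 <- function() fixture("accept_leadfield8", function() {
  assemble_leadfield(accept_mesh(), accept_catalog8(), accept_parc())
})

# denser catalog used for the targeting demonstration: cerebellar
# steering needs inferior-posterior scalp coverage, as the whole-head
# EEG-derived catalogs provide
accept_leadfield24 <- function() fixture("accept_leadfield24", function() {
  cat24 <- candidate_layout(accept_mesh(), n = 24)
  assemble_leadfield(accept_mesh(), cat24, accept_parc())
})

right_posterior_inferior_lobules <- function() {
  c("Right_VIIb", "Right_VIIIa", "Right_VIIIb", "Right_IX")
}

# deterministic quasi-uniform observation points on spherical shells,
# used for FEM-vs-series comparisons (well interior to the scalp)
interior_obs_points <- function(R, fractions = c(0.2, 0.4, 0.6, 0.8),
                                n_per_shell = 64) {
  ob <- NULL
  for (f in fractions) {
    i <- seq_len(n_per_shell) - 1L
    z <- 1 - 2 * (i + 0.5) / n_per_shell
    az <- i * pi * (3 - sqrt(5))
    d <- cbind(sqrt(pmax(0, 1 - z^2)) * cos(az),
               sqrt(pmax(0, 1 - z^2)) * sin(az), z)
    ob <- rbind(ob, d * f * R)
  }
  ob
}

# single-tissue ball and an antipodal 1 cm disc pair at +-1 mA
uniform_ball_montage <- function(mesh) {
  tab <- electrode_spec(c("top", "bottom"),
                        rbind(c(0, 0, mesh$shells$outer_radius[1]),
                              c(0, 0, -mesh$shells$outer_radius[1])),
                        radius_cm = 0.5, role = c("stim", "reference"))
  montage(tab, c(1, -1), "antipodal")
}

# weighted potential difference "seen" by a montage's electrode pair:
# load-vector inner product, the quantity that is exactly symmetric
# under exchange of drive and measurement for a symmetric operator
electrode_potential_difference <- function(mesh, mont, solution) {
  f <- fieldsteer:::electrode_load(mesh, mont)$f
  sum(f * solution$potentials)
}

# balanced synthetic field observation table with known cell means
balanced_anova_table <- function(cell_means, n_per_cell, sd = 0,
                                 seed = 1) {
  set.seed(seed)
  dims <- dim(cell_means)
  dn <- dimnames(cell_means)
  rows <- expand.grid(lapply(dn, identity), stringsAsFactors = TRUE)
  out <- rows[rep(seq_len(nrow(rows)), each = n_per_cell), , drop = FALSE]
  mu <- as.vector(cell_means)[rep(seq_len(nrow(rows)), each = n_per_cell)]
  out$y <- mu + if (sd > 0) stats::rnorm(nrow(out), 0, sd) else 0
  rownames(out) <- NULL
  out
}
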