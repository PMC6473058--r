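#' Tissue conductivity table of a mesh
#'
#' @param mesh A `head_mesh`.
#' @return Named numeric vector, conductivity (S/m) per tissue label id.
#' @export
tissue_conductivities <- function(mesh) {
  sig <- mesh$shells$conductivity
  names(sig) <- mesh$shells$name
  sig
}

check_tissues <- function(mesh, tissues) {
  if (is.null(tissues)) tissues <- tissue_conductivities(mesh)
  labs <- sort(unique(mesh$element_label))
  if (any(labs > length(tissues))) {
    missing <- setdiff(labs, seq_along(tissues))
    stop("element label(s) without conductivity: ",
         paste(missing, collapse = ", "))
  }
  if (any(tissues <= 0)) stop("all conductivities must be > 0")
  tissues
}

#' Create a stimulation montage
#'
#' A montage pairs an electrode table with injected currents. Currents
#' must balance to zero (Neumann compatibility of the current-flow
#' problem).
#'
#' @param electrodes Electrode table ([electrode_spec()]).
#' @param currents_mA Numeric vector of per-electrode currents in mA
#'   (anodes positive).
#' @param name Montage name.
#' @return Object of class `montage`.
#' @export
montage <- function(electrodes, currents_mA, name = "custom") {
  stopifnot(is.data.frame(electrodes), nrow(electrodes) >= 1L,
            length(currents_mA) == nrow(electrodes))
  if (abs(sum(currents_mA)) > 1e-12) {
    stop("montage currents must sum to 0 mA (got ", sum(currents_mA), ")")
  }
  structure(list(electrodes = electrodes,
                 currents_mA = as.numeric(currents_mA),
                 name = name),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("montage '%s': %d electrodes, total anodal %.3g mA\n",
              x$name, nrow(x$electrodes), sum(pmax(x$currents_mA, 0))))
  invisible(x)
}

#' Published cerebellar tDCS montage presets
#'
#' The three standard two-electrode / high-definition cerebellar
#' montages, placed on the phantom scalp by their 10/10-system
#' descriptions: the anode over the right cerebellum 1 cm below and
#' 3 cm lateral to the inion, with (celnik) the cathode over the right
#' buccinator muscle or (manto) the cathode over the contralateral
#' supraorbital area, both 5 x 5 cm pads at 2 mA; and (hd4x1) a
#' 3.14 cm^2 anode over the midline low occiput with four 3.14 cm^2
#' cathodes at occipito-parietal positions, 1 mA total. Rectangular
#' pads are realized as equal-area geodesic discs, preserving the
#' electrode current density.
#'
#' @param name `"celnik"`, `"manto"` or `"hd4x1"`.
#' @param mesh A `head_mesh` providing the scalp radius.
#' @return A [montage()].
#' @export
make_montage_preset <- function(name, mesh) {
  name <- match.arg(name, c("celnik", "manto", "hd4x1"))
  R <- mesh$shells$outer_radius[1]
  deg <- function(mm) mm / R * 180 / pi
  # anode over the right cerebellum: 1 cm below, 3 cm lateral to the inion
  th_an <- 90 + deg(10)
  az_an <- deg(30) / sin(th_an * pi / 180)
  anode <- scalp_position(R, th_an, az_an)
  if (name == "celnik") {
    cath <- scalp_position(R, 105, 100) # right buccinator analogue
    tab <- electrode_spec(c("cb_anode", "buccinator"), rbind(anode, cath),
                          shape = "rect", width_cm = 5, height_cm = 5,
                          role = c("stim", "reference"))
    montage(tab, c(2, -2), "celnik")
  } else if (name == "manto") {
    cath <- scalp_position(R, 70, 197) # contralateral supraorbital analogue
    tab <- electrode_spec(c("cb_anode", "supraorbital"), rbind(anode, cath),
                          shape = "rect", width_cm = 5, height_cm = 5,
                          role = c("stim", "reference"))
    montage(tab, c(2, -2), "manto")
  } else {
    centers <- rbind(scalp_position(R, 90, 0),   # anode: midline low occiput
                     scalp_position(R, 72, 0),   # Oz analogue
                     scalp_position(R, 72, 25),  # O2 analogue
                     scalp_position(R, 80, 40),  # PO8 analogue
                     scalp_position(R, 78, 58))  # P8 analogue
    tab <- electrode_spec(c("hd_anode", "Oz", "O2", "PO8", "P8"), centers,
                          shape = "disc", radius_cm = 1,
                          role = c("stim", rep("reference", 4L)))
    montage(tab, c(1, rep(-0.25, 4L)), "hd4x1")
  }
}

#' Assemble the finite-element stiffness operator
#'
#' First-order (P1) tetrahedral stiffness matrix of the current-flow
#' operator `-div(sigma grad phi)`: symmetric positive-semidefinite
#' with the constant vector in its nullspace. Units are S/m and mm, so
#' that with loads in mA the solution comes out in volts.
#'
#' @param mesh A `head_mesh` passing the quality gate.
#' @param tissues Named conductivity vector per label id (default: the
#'   mesh's shell table).
#' @return A sparse symmetric matrix (`Matrix::dsCMatrix`).
#' @export
assemble_system <- function(mesh, tissues = NULL) {
  tissues <- check_tissues(mesh, tissues)
  q <- mesh_quality(mesh)
  if (!q$ok) stop("mesh fails the quality gate (non-positive element volumes)")
  el <- mesh$elements
  m <- nrow(el)
  nn <- nrow(mesh$nodes)
  bp <- bary_precompute(mesh)
  v <- tet_volumes(mesh)
  coef <- as.numeric(tissues[mesh$element_label]) * v
  # gradients of the four P1 basis functions (per element)
  g2 <- bp$inv[, 1:3, drop = FALSE]
  g3 <- bp$inv[, 4:6, drop = FALSE]
  g4 <- bp$inv[, 7:9, drop = FALSE]
  g1 <- -(g2 + g3 + g4)
  G <- list(g1, g2, g3, g4)
  ii <- vector("list", 16L); jj <- vector("list", 16L); xx <- vector("list", 16L)
  t <- 0L
  for (i in 1:4) for (j in 1:4) {
    t <- t + 1L
    ii[[t]] <- el[, i]
    jj[[t]] <- el[, j]
    xx[[t]] <- coef * rowSums(G[[i]] * G[[j]])
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(nn, nn))
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

# Nodes on the outer (scalp) surface.
scalp_nodes <- function(mesh) sort(unique(as.vector(mesh$surface$faces)))

# Map each electrode to its scalp facets and build the Neumann load
# vector: each electrode's current is distributed over the facets whose
# centroid lies within the electrode radius of its center
# (geodesically for the spherical phantom), proportionally to facet
# area; a facet's load is shared equally by its three nodes. Electrodes
# too small to capture a facet centroid couple to the nearest facet.
electrode_load <- function(mesh, mont) {
  surf <- mesh$surface
  nn <- nrow(mesh$nodes)
  f <- numeric(nn)
  cen <- surf$centroid
  cen_u <- cen / sqrt(rowSums(cen^2))
  spherical <- !is.null(mesh$param)
  R <- if (!is.null(mesh$shells)) mesh$shells$outer_radius[1] else
    max(sqrt(rowSums(cen^2)))
  tab <- mont$electrodes
  facet_count <- integer(nrow(tab))
  for (e in seq_len(nrow(tab))) {
    ctr <- c(tab$x[e], tab$y[e], tab$z[e])
    if (spherical) {
      u <- ctr / sqrt(sum(ctr^2))
      dist <- R * acos(pmin(pmax(cen_u %*% u, -1), 1))
    } else {
      dist <- sqrt(rowSums(sweep(cen, 2L, ctr)^2))
    }
    sel <- which(dist <= tab$radius_mm[e])
    if (length(sel) == 0L) sel <- which.min(dist)
    facet_count[e] <- length(sel)
    w <- surf$area[sel] / sum(surf$area[sel]) * mont$currents_mA[e]
    fnodes <- surf$faces[sel, , drop = FALSE]
    contrib <- rep(w / 3, 3L)
    f_idx <- as.vector(fnodes)
    add <- rowsum(contrib, f_idx)
    f[as.integer(rownames(add))] <- f[as.integer(rownames(add))] + add[, 1L]
  }
  list(f = f, facet_count = facet_count)
}

#' Pre-assembled operator for repeated solves
#'
#' Assembles the stiffness matrix once and factorizes it (sparse
#' Cholesky after grounding one node), so that many montages can be
#' solved against the same head model, as in lead-field assembly.
#'
#' @inheritParams assemble_system
#' @return Object of class `fem_operator`.
#' @export
fem_operator <- function(mesh, tissues = NULL) {
  tissues <- check_tissues(mesh, tissues)
  K <- assemble_system(mesh, tissues)
  fac <- Matrix::Cholesky(K[-1L, -1L], LDL = FALSE, perm = TRUE, super = TRUE)
  structure(list(mesh = mesh, tissues = tissues, K = K, factor = fac,
                 scalp = scalp_nodes(mesh)),
            class = "fem_operator")
}

#' Solve the current-flow problem for a montage
#'
#' Solves `div(sigma grad phi) = 0` with Neumann current injection at
#' the electrode patches and insulating boundary elsewhere, then
#' differentiates to the element-wise electric field. The singular
#' compatible system is solved either by sparse Cholesky on the
#' grounded system (default; exact up to roundoff) or by deflated
#' Jacobi-preconditioned conjugate gradients; either way the returned
#' potentials are re-gauged to zero mean over the scalp-surface nodes.
#'
#' @param mesh A `head_mesh` (ignored when `operator` is given).
#' @param mont A [montage()] with balanced currents.
#' @param tissues Optional conductivity vector per label.
#' @param method `"cholesky"` (direct, default) or `"cg"`.
#' @param tol Relative residual tolerance for `"cg"`.
#' @param maxit Iteration cap for `"cg"`.
#' @param operator Optional pre-built [fem_operator()].
#' @return Object of class `potential_solution`: `potentials` (V per
#'   node, zero mean over scalp nodes), `field` (m x 3, V/m per
#'   element), `enorm` (V/m), `montage`, `diagnostics` (method,
#'   iterations, relative residual, facets per electrode) and `mesh`.
#' @export
solve_potential <- function(mesh, mont, tissues = NULL,
                            method = c("cholesky", "cg"),
                            tol = 1e-8, maxit = 10000L, operator = NULL) {
  method <- match.arg(method)
  if (!is.null(operator)) {
    mesh <- operator$mesh
    tissues <- operator$tissues
  } else {
    tissues <- check_tissues(mesh, tissues)
  }
  stopifnot(inherits(mont, "montage"))
  if (abs(sum(mont$currents_mA)) > 1e-12) {
    stop("montage currents must balance (sum ", sum(mont$currents_mA), " mA)")
  }
  ld <- electrode_load(mesh, mont)
  f <- ld$f
  nn <- nrow(mesh$nodes)
  scalp <- if (!is.null(operator)) operator$scalp else scalp_nodes(mesh)

  if (all(f == 0)) {
    phi <- numeric(nn)
    diag_info <- list(method = method, iterations = 0L, residual = 0,
                      facet_count = ld$facet_count)
  } else if (method == "cholesky") {
    if (is.null(operator)) operator <- fem_operator(mesh, tissues)
    x <- Matrix::solve(operator$factor, f[-1L])
    phi <- c(0, as.numeric(x))
    r <- as.numeric(operator$K %*% phi) - f
    diag_info <- list(method = "cholesky", iterations = 1L,
                      residual = sqrt(sum(r^2)) / sqrt(sum(f^2)),
                      facet_count = ld$facet_count)
  } else {
    K <- if (!is.null(operator)) operator$K else assemble_system(mesh, tissues)
    sol <- cg_deflated(K, f, tol = tol, maxit = maxit)
    if (!sol$converged) {
      stop(sprintf(paste0("conjugate-gradient solve did not converge: ",
                          "relative residual %.3e after %d iterations"),
                   sol$residual, sol$iterations))
    }
    phi <- sol$x
    diag_info <- list(method = "cg", iterations = sol$iterations,
                      residual = sol$residual, facet_count = ld$facet_count)
  }
  phi <- phi - mean(phi[scalp])
  EF <- element_field_from_potentials(mesh, phi)
  structure(list(potentials = phi, field = EF$field, enorm = EF$enorm,
                 montage = mont, diagnostics = diag_info, mesh = mesh),
            class = "potential_solution")
}

# Deflated, Jacobi-preconditioned conjugate gradients for the singular
# compatible Neumann system; iterates orthogonally to the constant
# nullspace instead of grounding a node.
cg_deflated <- function(K, f, tol = 1e-8, maxit = 10000L) {
  n <- length(f)
  proj <- function(v) v - mean(v)
  d <- Matrix::diag(K)
  d[d <= 0] <- 1
  b <- proj(f)
  x <- numeric(n)
  r <- b
  z <- proj(r / d)
  p <- z
  rz <- sum(r * z)
  nb <- sqrt(sum(b^2))
  it <- 0L
  res <- 1
  while (it < maxit) {
    it <- it + 1L
    Kp <- as.numeric(K %*% p)
    alpha <- rz / sum(p * Kp)
    x <- x + alpha * p
    r <- r - alpha * Kp
    res <- sqrt(sum(r^2)) / nb
    if (res <= tol) break
    z <- proj(r / d)
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- z + beta * p
  }
  list(x = proj(x), iterations = it, residual = res, converged = res <= tol)
}

# E = -grad(phi), constant per first-order element; mm -> m conversion
# gives V/m.
element_field_from_potentials <- function(mesh, phi) {
  bp <- bary_precompute(mesh)
  el <- mesh$elements
  d2 <- phi[el[, 2L]] - phi[el[, 1L]]
  d3 <- phi[el[, 3L]] - phi[el[, 1L]]
  d4 <- phi[el[, 4L]] - phi[el[, 1L]]
  gx <- bp$inv[, 1L] * d2 + bp$inv[, 4L] * d3 + bp$inv[, 7L] * d4
  gy <- bp$inv[, 2L] * d2 + bp$inv[, 5L] * d3 + bp$inv[, 8L] * d4
  gz <- bp$inv[, 3L] * d2 + bp$inv[, 6L] * d3 + bp$inv[, 9L] * d4
  field <- -1000 * cbind(Ex = gx, Ey = gy, Ez = gz) # V/mm -> V/m
  list(field = field, enorm = sqrt(rowSums(field^2)))
}

#' Element-wise electric field of a solved potential
#'
#' @param solution A `potential_solution`.
#' @return List with `field` (m x 3 matrix, V/m) and `enorm` (V/m).
#' @export
element_field <- function(solution) {
  stopifnot(inherits(solution, "potential_solution"))
  list(field = solution$field, enorm = solution$enorm)
}

#' Interpolate a solved potential at arbitrary points
#'
#' Linear (barycentric) interpolation of the node potentials; used for
#' comparison against the closed-form series solution.
#'
#' @param solution A `potential_solution`.
#' @param pts Matrix (k x 3) of points, mm.
#' @return Numeric vector of potentials (V); `NA` outside the mesh.
#' @export
interpolate_potential <- function(solution, pts) {
  mesh <- solution$mesh
  pts <- as.matrix(pts)
  eid <- locate_points(mesh, pts)
  out <- rep(NA_real_, nrow(pts))
  ok <- !is.na(eid)
  if (!any(ok)) return(out)
  bp <- bary_precompute(mesh)
  e <- eid[ok]
  dx <- pts[ok, 1L] - bp$a[e, 1L]
  dy <- pts[ok, 2L] - bp$a[e, 2L]
  dz <- pts[ok, 3L] - bp$a[e, 3L]
  iv <- bp$inv
  l2 <- iv[e, 1L] * dx + iv[e, 2L] * dy + iv[e, 3L] * dz
  l3 <- iv[e, 4L] * dx + iv[e, 5L] * dy + iv[e, 6L] * dz
  l4 <- iv[e, 7L] * dx + iv[e, 8L] * dy + iv[e, 9L] * dz
  l1 <- 1 - l2 - l3 - l4
  phi <- solution$potentials
  el <- mesh$elements
  out[ok] <- l1 * phi[el[e, 1L]] + l2 * phi[el[e, 2L]] +
    l3 * phi[el[e, 3L]] + l4 * phi[el[e, 4L]]
  out
}

#' @export
print.potential_solution <- function(x, ...) {
  cat(sprintf(paste0("potential_solution: montage '%s', %d nodes, ",
                     "method %s, rel. residual %.2e\n"),
              x$montage$name, length(x$potentials),
              x$diagnostics$method, x$diagnostics$residual))
  cat(sprintf("  peak |E| %.4g V/m\n", max(x$enorm)))
  invisible(x)
}
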