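#' Shell specification for the spherical head phantom
#'
#' A shell is one tissue layer of the concentric multi-shell phantom,
#' described by its outer radius and isotropic conductivity.
#'
#' @param name Tissue label (character scalar).
#' @param outer_radius Outer radius of the shell in mm.
#' @param conductivity Isotropic conductivity in S/m; must be positive.
#' @return A one-row data frame with columns `name`, `outer_radius`,
#'   `conductivity`.
#' @seealso [default_head_shells()], [build_shell_phantom()]
#' @export
shell_spec <- function(name, outer_radius, conductivity) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(outer_radius), length(outer_radius) == 1L,
            outer_radius > 0,
            is.numeric(conductivity), length(conductivity) == 1L)
  if (conductivity <= 0) stop("conductivity must be > 0 (got ", conductivity, ")")
  data.frame(name = name, outer_radius = as.numeric(outer_radius),
             conductivity = as.numeric(conductivity),
             stringsAsFactors = FALSE)
}

#' Default five-tissue head shells
#'
#' Scalp, skull, CSF, gray matter and white matter with the standard
#' isotropic conductivities used for tDCS volume-conductor modeling
#' (scalp 0.465, skull 0.010, CSF 1.654, gray matter 0.276, white matter
#' 0.126 S/m). The shell radii (92, 86, 81, 79, 67 mm) are configuration
#' defaults chosen to be anatomically ordered and of plausible
#' thickness; they do not correspond to any particular subject.
#'
#' @return A five-row shell table (outermost first), as produced by
#'   [shell_spec()].
#' @export
default_head_shells <- function() {
  rbind(
    shell_spec("scalp",        92, 0.465),
    shell_spec("skull",        86, 0.010),
    shell_spec("csf",          81, 1.654),
    shell_spec("gray_matter",  79, 0.276),
    shell_spec("white_matter", 67, 0.126)
  )
}

as_shell_table <- function(shells) {
  if (is.list(shells) && !is.data.frame(shells)) shells <- do.call(rbind, shells)
  stopifnot(is.data.frame(shells),
            all(c("name", "outer_radius", "conductivity") %in% names(shells)))
  if (nrow(shells) < 1L) stop("need at least one shell")
  if (any(shells$conductivity <= 0)) stop("all shell conductivities must be > 0")
  r <- shells$outer_radius
  if (nrow(shells) > 1L && any(diff(r) >= 0)) {
    stop("shell outer radii must be strictly decreasing from the scalp inward; got ",
         paste(r, collapse = ", "))
  }
  shells
}

# ---------------------------------------------------------------------------
# Equiangular cubed-sphere surface triangulation.
# Integer grid points on the surface of the cube [0, s]^3 are deduplicated,
# warped per-coordinate by tan(pi * c / 4) (equiangular gnomonic mapping,
# which keeps cell sizes nearly uniform across each cube face) and
# normalized to unit directions. Each quad cell is split into two triangles
# along the diagonal through its smallest surface-node index, which makes
# the triangulation conforming across faces and reproducible.
cubed_sphere_surface <- function(s) {
  stopifnot(s >= 1L)
  sp1 <- s + 1L
  keyof <- function(i, j, k) i + sp1 * (j + sp1 * k)
  # enumerate the 6 faces; axes: (fixed axis, value) x free grid
  grids <- list()
  for (axis in 1:3) for (side in c(0L, s)) {
    u <- rep(0:s, times = sp1); v <- rep(0:s, each = sp1)
    ijk <- matrix(0L, sp1 * sp1, 3L)
    free <- setdiff(1:3, axis)
    ijk[, free[1L]] <- u; ijk[, free[2L]] <- v; ijk[, axis] <- side
    grids[[length(grids) + 1L]] <- ijk
  }
  all_ijk <- do.call(rbind, grids)
  key <- keyof(all_ijk[, 1L], all_ijk[, 2L], all_ijk[, 3L])
  first <- !duplicated(key)
  pts_ijk <- all_ijk[first, , drop = FALSE]
  id_of <- integer(max(key) + 1L)
  id_of[key[first] + 1L] <- seq_len(nrow(pts_ijk))
  # unit directions via equiangular warp
  cc <- 2 * pts_ijk / s - 1
  tt <- tan(pi * cc / 4)
  dirs <- tt / sqrt(rowSums(tt^2))
  # triangles per face, with lookup (face, cell u, cell v) -> 2 triangle ids
  ntri_per_face <- 2L * s * s
  tri <- matrix(0L, 6L * ntri_per_face, 3L)
  tri_lookup <- array(0L, dim = c(6L, s, s, 2L))
  t_at <- 0L
  face_axes <- matrix(0L, 6L, 2L) # free axes per face, for locate
  face_axis <- integer(6L); face_side <- integer(6L)
  f <- 0L
  for (axis in 1:3) for (side in c(0L, s)) {
    f <- f + 1L
    free <- setdiff(1:3, axis)
    face_axes[f, ] <- free; face_axis[f] <- axis
    face_side[f] <- if (side == 0L) -1L else 1L
    for (q in seq_len(s)) for (p in seq_len(s)) {
      corner <- function(du, dv) {
        ijk <- integer(3L)
        ijk[free[1L]] <- p - 1L + du; ijk[free[2L]] <- q - 1L + dv
        ijk[axis] <- side
        id_of[keyof(ijk[1L], ijk[2L], ijk[3L]) + 1L]
      }
      n00 <- corner(0L, 0L); n10 <- corner(1L, 0L)
      n11 <- corner(1L, 1L); n01 <- corner(0L, 1L)
      if (min(n00, n11) < min(n10, n01)) {
        tri[t_at + 1L, ] <- c(n00, n10, n11)
        tri[t_at + 2L, ] <- c(n00, n11, n01)
      } else {
        tri[t_at + 1L, ] <- c(n10, n11, n01)
        tri[t_at + 2L, ] <- c(n10, n01, n00)
      }
      tri_lookup[f, p, q, ] <- c(t_at + 1L, t_at + 2L)
      t_at <- t_at + 2L
    }
  }
  list(dirs = dirs, tri = tri, s = s, tri_lookup = tri_lookup,
       face_axes = face_axes, face_axis = face_axis, face_side = face_side)
}

# Split a radially extruded triangular prism into 3 conforming tetrahedra.
# Bottom surface indices (j1, j2, j3); top nodes are bottom + offset, so the
# global-id order within the triangle decides all face diagonals (diagonal
# through the smallest id of each quad face), making adjacent prisms agree.
# Returns a 3 x 6 index matrix into the local ordering (1:3 bottom, 4:6 top).
prism_split_pattern <- function(j1, j2, j3) {
  jj <- c(j1, j2, j3)
  rot <- which.min(jj)
  ord <- ((rot - 1L + 0:2) %% 3L) + 1L # rotate min to first
  V <- c(ord, ord + 3L) # V1..V3 bottom, V4..V6 top (V4 above V1)
  if (jj[ord[2L]] < jj[ord[3L]]) {
    rbind(V[c(1L, 2L, 3L, 6L)], V[c(1L, 2L, 6L, 5L)], V[c(1L, 5L, 6L, 4L)])
  } else {
    rbind(V[c(1L, 2L, 3L, 5L)], V[c(1L, 5L, 3L, 6L)], V[c(1L, 5L, 6L, 4L)])
  }
}

#' Build a concentric multi-shell spherical head phantom mesh
#'
#' Constructs a watertight tetrahedral mesh of a ball of nested spherical
#' tissue shells. An equiangular cubed-sphere triangulation of the unit
#' sphere is extruded radially between discrete radial levels that are
#' aligned exactly with the shell interfaces (each shell receives at
#' least one full layer of elements); each surface-triangle prism is
#' split into three conforming tetrahedra and the innermost level is
#' closed with a tetrahedral fan to the center. Every element therefore
#' lies between two concentric spheres and is labeled by the shell whose
#' radial slab contains its centroid.
#'
#' Coordinates are RAS in mm with the origin at the sphere center:
#' +X right (mediolateral), +Y anterior (posteroanterior), +Z superior
#' (inferosuperior).
#'
#' @param shells Shell table (outermost first) as from [shell_spec()] /
#'   [default_head_shells()], or a list of one-row shell specs.
#' @param resolution Target element edge length in mm; sets both the
#'   radial layer count per shell (at least one layer each) and the
#'   angular subdivision.
#' @param max_aspect Reject the construction when the ratio of angular
#'   element size to the thinnest shell thickness would exceed this
#'   bound (elements too flat to be trustworthy).
#' @return An object of class `head_mesh`: a list with `nodes`
#'   (n x 3, mm), `elements` (m x 4 node indices, positively oriented),
#'   `element_label` (tissue id per element, 1 = outermost shell),
#'   `shells` (the shell/conductivity table), `r_levels` (radial levels,
#'   mm), `surface` (boundary triangles with areas and centroids) and
#'   `param` (the structured parameterization used for fast point
#'   location).
#' @export
build_shell_phantom <- function(shells, resolution = 8, max_aspect = 10) {
  shells <- as_shell_table(shells)
  S <- nrow(shells)
  R <- shells$outer_radius[1]
  if (resolution <= 0) stop("resolution must be > 0")
  bounds <- c(0, rev(shells$outer_radius)) # increasing from the center
  seg <- diff(bounds)
  layers <- pmax(1L, as.integer(round(seg / resolution)))
  n <- sum(layers)
  s <- max(2L, as.integer(round((pi / 2) * R / resolution)))
  if (S > 1L) {
    aspect <- ((pi / 2) * R / s) / min(seg[-1])
    if (aspect > max_aspect) {
      stop(sprintf(paste0(
        "resolution %.3g mm is too coarse to resolve the thinnest shell ",
        "(%.3g mm thick): element aspect ratio %.1f would exceed %.1f"),
        resolution, min(seg[-1]), aspect, max_aspect))
    }
  }
  r_levels <- c(0, unlist(mapply(
    function(a, b, k) seq(a, b, length.out = k + 1L)[-1],
    bounds[-length(bounds)], bounds[-1], layers, SIMPLIFY = FALSE)))
  stopifnot(length(r_levels) == n + 1L)

  surf <- cubed_sphere_surface(s)
  Ns <- nrow(surf$dirs)
  Nt <- nrow(surf$tri)

  # nodes: center (id 1) then one copy of the surface per radial level
  nodes <- matrix(0, 1L + n * Ns, 3L)
  for (k in seq_len(n)) {
    nodes[1L + (k - 1L) * Ns + seq_len(Ns), ] <- surf$dirs * r_levels[k + 1L]
  }
  colnames(nodes) <- c("x", "y", "z")
  lev_id <- function(k) 1L + (k - 1L) * Ns # id offset for level k (1-based)

  # core: fan from the center to the innermost level
  core <- cbind(1L, surf$tri + lev_id(1L))
  # prism layers between level k and k + 1
  pat <- vector("list", Nt)
  for (t in seq_len(Nt)) {
    pat[[t]] <- prism_split_pattern(surf$tri[t, 1L], surf$tri[t, 2L],
                                    surf$tri[t, 3L])
  }
  layer_blocks <- vector("list", max(n - 1L, 0L))
  if (n > 1L) {
    # local index template: rows = 3 * Nt tets, cols = 4, entries in 1..6
    tpl <- do.call(rbind, pat)
    tri_rep <- surf$tri[rep(seq_len(Nt), each = 3L), , drop = FALSE]
    for (k in seq_len(n - 1L)) {
      locals <- cbind(tri_rep + lev_id(k), tri_rep + lev_id(k + 1L))
      idx <- matrix(locals[cbind(rep(seq_len(3L * Nt), 4L), as.vector(tpl))],
                    ncol = 4L)
      layer_blocks[[k]] <- idx
    }
  }
  elements <- do.call(rbind, c(list(core), layer_blocks))
  storage.mode(elements) <- "integer"

  # orientation fix: all signed volumes positive
  v <- tet_signed_volumes(nodes, elements)
  neg <- v < 0
  if (any(neg)) {
    tmp <- elements[neg, 3L]
    elements[neg, 3L] <- elements[neg, 4L]
    elements[neg, 4L] <- tmp
    v[neg] <- -v[neg]
  }
  if (any(v <= 0)) stop("degenerate (zero-volume) tetrahedra in phantom mesh")

  # tissue labels by centroid radius
  cx <- (nodes[elements[, 1L], 1L] + nodes[elements[, 2L], 1L] +
         nodes[elements[, 3L], 1L] + nodes[elements[, 4L], 1L]) / 4
  cy <- (nodes[elements[, 1L], 2L] + nodes[elements[, 2L], 2L] +
         nodes[elements[, 3L], 2L] + nodes[elements[, 4L], 2L]) / 4
  cz <- (nodes[elements[, 1L], 3L] + nodes[elements[, 2L], 3L] +
         nodes[elements[, 3L], 3L] + nodes[elements[, 4L], 3L]) / 4
  rc <- sqrt(cx^2 + cy^2 + cz^2)
  segidx <- findInterval(rc, bounds, rightmost.closed = TRUE)
  segidx[segidx < 1L] <- 1L
  segidx[segidx > S] <- S
  element_label <- as.integer(S + 1L - segidx) # 1 = outermost shell as listed

  mesh <- structure(list(
    nodes = nodes,
    elements = elements,
    element_label = element_label,
    shells = shells,
    r_levels = r_levels,
    resolution = resolution,
    volumes = v,
    param = list(n = n, s = s, Ns = Ns, Nt = Nt, r_levels = r_levels,
                 surf = surf)
  ), class = "head_mesh")
  mesh$surface <- extract_surface(mesh)
  mesh
}

# Signed volume of each tetrahedron (mm^3).
tet_signed_volumes <- function(nodes, elements) {
  a <- nodes[elements[, 1L], , drop = FALSE]
  b <- nodes[elements[, 2L], , drop = FALSE] - a
  c_ <- nodes[elements[, 3L], , drop = FALSE] - a
  d <- nodes[elements[, 4L], , drop = FALSE] - a
  (b[, 1L] * (c_[, 2L] * d[, 3L] - c_[, 3L] * d[, 2L]) +
   b[, 2L] * (c_[, 3L] * d[, 1L] - c_[, 1L] * d[, 3L]) +
   b[, 3L] * (c_[, 1L] * d[, 2L] - c_[, 2L] * d[, 1L])) / 6
}

#' Tetrahedron volumes of a head mesh
#' @param mesh A `head_mesh`.
#' @return Numeric vector of element volumes (mm^3), all positive.
#' @export
tet_volumes <- function(mesh) {
  if (!is.null(mesh$volumes)) return(mesh$volumes)
  abs(tet_signed_volumes(mesh$nodes, mesh$elements))
}

#' Total mesh volume
#' @param mesh A `head_mesh`.
#' @return Total volume in mm^3.
#' @export
mesh_volume <- function(mesh) sum(tet_volumes(mesh))

# Boundary triangles: faces that occur exactly once across all tetrahedra.
extract_surface <- function(mesh) {
  el <- mesh$elements
  m <- nrow(el)
  faces <- rbind(el[, c(1L, 2L, 3L)], el[, c(1L, 2L, 4L)],
                 el[, c(1L, 3L, 4L)], el[, c(2L, 3L, 4L)])
  f1 <- pmin(faces[, 1L], faces[, 2L], faces[, 3L])
  f3 <- pmax(faces[, 1L], faces[, 2L], faces[, 3L])
  f2 <- faces[, 1L] + faces[, 2L] + faces[, 3L] - f1 - f3
  o <- order(f1, f2, f3)
  s1 <- f1[o]; s2 <- f2[o]; s3 <- f3[o]
  nf <- length(s1)
  same_prev <- c(FALSE, s1[-1] == s1[-nf] & s2[-1] == s2[-nf] & s3[-1] == s3[-nf])
  same_next <- c(same_prev[-1], FALSE)
  solo <- !(same_prev | same_next)
  bidx <- o[solo]
  bfaces <- faces[bidx, , drop = FALSE]
  a <- mesh$nodes[bfaces[, 1L], , drop = FALSE]
  b <- mesh$nodes[bfaces[, 2L], , drop = FALSE]
  cc <- mesh$nodes[bfaces[, 3L], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  cr <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  area <- 0.5 * sqrt(rowSums(cr^2))
  centroid <- (a + b + cc) / 3
  list(faces = bfaces, area = area, centroid = centroid,
       element = ((bidx - 1L) %% m) + 1L)
}

#' Mesh quality summary
#'
#' Quality gate used by the solver: all element volumes must be
#' positive and every tissue label must be populated; label volumes sum
#' to the total mesh volume by construction.
#'
#' @param mesh A `head_mesh`.
#' @return List with `n_nodes`, `n_elements`, `min_volume`,
#'   `total_volume`, `label_volumes` (named, summing to `total_volume`)
#'   and `ok`.
#' @export
mesh_quality <- function(mesh) {
  v <- tet_volumes(mesh)
  lv <- tapply(v, mesh$element_label, sum)
  if (!is.null(mesh$shells)) {
    names(lv) <- mesh$shells$name[as.integer(names(lv))]
  }
  n_expected <- if (!is.null(mesh$shells)) nrow(mesh$shells) else length(lv)
  list(n_nodes = nrow(mesh$nodes), n_elements = nrow(mesh$elements),
       min_volume = min(v), total_volume = sum(v), label_volumes = lv,
       ok = min(v) > 0 && length(lv) == n_expected)
}

#' @export
print.head_mesh <- function(x, ...) {
  cat(sprintf("head_mesh: %d nodes, %d tetrahedra, %d tissue label(s)\n",
              nrow(x$nodes), nrow(x$elements),
              length(unique(x$element_label))))
  cat(sprintf("  volume %.4g mm^3\n", mesh_volume(x)))
  invisible(x)
}

# Per-element barycentric precomputation: first vertex and the inverse of
# the edge matrix, stored columnwise for vectorized evaluation.
bary_precompute <- function(mesh) {
  nodes <- mesh$nodes; el <- mesh$elements
  a <- nodes[el[, 1L], , drop = FALSE]
  e1 <- nodes[el[, 2L], , drop = FALSE] - a
  e2 <- nodes[el[, 3L], , drop = FALSE] - a
  e3 <- nodes[el[, 4L], , drop = FALSE] - a
  # inverse of T = [e1 e2 e3] (columns) via adjugate
  det <- e1[, 1L] * (e2[, 2L] * e3[, 3L] - e2[, 3L] * e3[, 2L]) -
         e2[, 1L] * (e1[, 2L] * e3[, 3L] - e1[, 3L] * e3[, 2L]) +
         e3[, 1L] * (e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L])
  inv <- cbind(
    (e2[, 2L] * e3[, 3L] - e2[, 3L] * e3[, 2L]) / det,  # i11
    (e3[, 1L] * e2[, 3L] - e2[, 1L] * e3[, 3L]) / det,  # i12
    (e2[, 1L] * e3[, 2L] - e3[, 1L] * e2[, 2L]) / det,  # i13
    (e3[, 2L] * e1[, 3L] - e1[, 2L] * e3[, 3L]) / det,  # i21
    (e1[, 1L] * e3[, 3L] - e3[, 1L] * e1[, 3L]) / det,  # i22
    (e3[, 1L] * e1[, 2L] - e1[, 1L] * e3[, 2L]) / det,  # i23
    (e1[, 2L] * e2[, 3L] - e2[, 2L] * e1[, 3L]) / det,  # i31
    (e2[, 1L] * e1[, 3L] - e1[, 1L] * e2[, 3L]) / det,  # i32
    (e1[, 1L] * e2[, 2L] - e2[, 1L] * e1[, 2L]) / det)  # i33
  list(a = a, inv = inv)
}

# Minimum barycentric coordinate of points pts w.r.t. candidate elements
# eid (vectors of equal length); large negative = far outside.
bary_min <- function(bp, eid, pts) {
  dx <- pts[, 1L] - bp$a[eid, 1L]
  dy <- pts[, 2L] - bp$a[eid, 2L]
  dz <- pts[, 3L] - bp$a[eid, 3L]
  iv <- bp$inv
  l1 <- iv[eid, 1L] * dx + iv[eid, 2L] * dy + iv[eid, 3L] * dz
  l2 <- iv[eid, 4L] * dx + iv[eid, 5L] * dy + iv[eid, 6L] * dz
  l3 <- iv[eid, 7L] * dx + iv[eid, 8L] * dy + iv[eid, 9L] * dz
  pmin(1 - l1 - l2 - l3, l1, l2, l3)
}

#' Locate points in a phantom mesh
#'
#' Maps query points to the containing tetrahedral element. For
#' structured phantom meshes the radial slab and cubed-sphere cell are
#' found analytically, then the handful of candidate tetrahedra are
#' tested exactly (barycentric coordinates); points outside the outer
#' sphere get `NA`. Imported meshes without a parameterization fall back
#' to a bucket-grid search.
#'
#' @param mesh A `head_mesh`.
#' @param pts Numeric matrix (k x 3) of query points in mm.
#' @return Integer vector of element indices (`NA` when outside).
#' @export
locate_points <- function(mesh, pts) {
  pts <- as.matrix(pts)
  stopifnot(ncol(pts) == 3L)
  if (is.null(mesh$param)) return(locate_points_generic(mesh, pts))
  pr <- mesh$param
  n <- pr$n; s <- pr$s; Nt <- pr$Nt
  r_levels <- pr$r_levels
  R <- r_levels[length(r_levels)]
  surf <- pr$surf
  np <- nrow(pts)
  out <- rep(NA_integer_, np)
  r <- sqrt(rowSums(pts^2))
  inside <- r <= R
  if (!any(inside)) return(out)
  p <- pts[inside, , drop = FALSE]
  ri <- r[inside]

  # radial slab: 0 = core (below first level), else between level k, k+1
  k <- findInterval(ri, r_levels, rightmost.closed = TRUE) - 1L
  k[k < 0L] <- 0L
  k[k > n - 1L] <- n - 1L

  # cubed-sphere cell of the direction
  ax <- max.col(abs(p), ties.method = "first")
  sgn <- sign(p[cbind(seq_len(nrow(p)), ax)])
  sgn[sgn == 0] <- 1
  face <- (ax - 1L) * 2L + ifelse(sgn < 0, 1L, 2L) # order used in construction
  dom <- abs(p[cbind(seq_len(nrow(p)), ax)])
  dom[dom == 0] <- 1
  u_ax <- surf$face_axes[face, 1L]; v_ax <- surf$face_axes[face, 2L]
  cu <- (4 / pi) * atan(p[cbind(seq_len(nrow(p)), u_ax)] / dom)
  cv <- (4 / pi) * atan(p[cbind(seq_len(nrow(p)), v_ax)] / dom)
  pu <- pmin(pmax(floor((cu + 1) / 2 * s), 0), s - 1) + 1L
  pv <- pmin(pmax(floor((cv + 1) / 2 * s), 0), s - 1) + 1L
  tri1 <- surf$tri_lookup[cbind(face, pu, pv, 1L)]
  tri2 <- surf$tri_lookup[cbind(face, pu, pv, 2L)]

  bp <- bary_precompute(mesh)
  nel <- nrow(mesh$elements)
  best_e <- rep(NA_integer_, nrow(p))
  best_b <- rep(-Inf, nrow(p))
  # vectorized candidate test: element eid[t] against point row rows[t]
  consider <- function(eid, rows) {
    ok <- which(eid >= 1L & eid <= nel)
    if (length(ok) == 0L) return(invisible())
    bb <- bary_min(bp, eid[ok], p[rows[ok], , drop = FALSE])
    r_ok <- rows[ok]
    better <- bb > best_b[r_ok]
    idx <- r_ok[better]
    best_b[idx] <<- bb[better]
    best_e[idx] <<- eid[ok][better]
    invisible()
  }
  # all candidate tets of radial slab kk (0 = core) under triangles tid
  pass_layer <- function(kk, tid, rows) {
    core <- kk == 0L
    e0 <- integer(length(rows))
    e0[core] <- tid[core]
    e0[!core] <- Nt + (kk[!core] - 1L) * 3L * Nt + (tid[!core] - 1L) * 3L + 1L
    consider(e0, rows)
    for (dt in 1:2) { # remaining prism tets (none in the core)
      ee <- e0 + dt
      ee[core] <- 0L
      consider(ee, rows)
    }
  }
  rows_all <- seq_len(nrow(p))
  pass_layer(k, tri1, rows_all)
  pass_layer(k, tri2, rows_all)
  # fallback for points straddling the chordal level surfaces: test the
  # neighboring radial layers of both candidate triangles; points still
  # marginally outside afterwards sit on a chordal face and keep the
  # nearest candidate (field error O(h) on a O(h^2) sliver of voxels)
  for (dk in c(-1L, 1L)) {
    need <- which(best_b < -1e-9)
    if (length(need) == 0L) break
    kk <- k[need] + dk
    okk <- which(kk >= 0L & kk <= n - 1L)
    if (length(okk) == 0L) next
    rows <- need[okk]
    pass_layer(kk[okk], tri1[rows], rows)
    pass_layer(kk[okk], tri2[rows], rows)
  }
  out[inside] <- best_e
  out
}

# Brute-force point location for meshes without a structured
# parameterization (e.g. imported from file): uniform bucket grid over
# element bounding boxes, then barycentric containment tests.
locate_points_generic <- function(mesh, pts, tol = 1e-9) {
  nodes <- mesh$nodes; el <- mesh$elements
  m <- nrow(el)
  out <- rep(NA_integer_, nrow(pts))
  a <- nodes[el[, 1L], , drop = FALSE]
  lo <- pmin(a, nodes[el[, 2L], ], nodes[el[, 3L], ], nodes[el[, 4L], ])
  hi <- pmax(a, nodes[el[, 2L], ], nodes[el[, 3L], ], nodes[el[, 4L], ])
  h <- max(hi - lo)
  gmin <- apply(lo, 2L, min); gmax <- apply(hi, 2L, max)
  nbin <- pmax(1L, pmin(64L, as.integer(floor((gmax - gmin) / h))))
  wid <- (gmax - gmin) / nbin
  binidx <- function(xyz) {
    b <- floor(sweep(sweep(xyz, 2L, gmin), 2L, wid, "/"))
    b <- pmin(pmax(b, 0L), matrix(nbin - 1L, nrow(b), 3L, byrow = TRUE))
    b[, 1L] + nbin[1L] * (b[, 2L] + nbin[2L] * b[, 3L]) + 1L
  }
  keys <- vector("list", prod(nbin))
  blo <- floor(sweep(sweep(lo, 2L, gmin), 2L, wid, "/"))
  bhi <- floor(sweep(sweep(hi, 2L, gmin), 2L, wid, "/"))
  blo <- pmin(pmax(blo, 0L), matrix(nbin - 1L, m, 3L, byrow = TRUE))
  bhi <- pmin(pmax(bhi, 0L), matrix(nbin - 1L, m, 3L, byrow = TRUE))
  for (e in seq_len(m)) {
    for (bz in blo[e, 3L]:bhi[e, 3L]) for (by in blo[e, 2L]:bhi[e, 2L])
      for (bx in blo[e, 1L]:bhi[e, 1L]) {
        id <- bx + nbin[1L] * (by + nbin[2L] * bz) + 1L
        keys[[id]] <- c(keys[[id]], e)
      }
  }
  pb <- binidx(pts)
  for (i in seq_len(nrow(pts))) {
    cand <- keys[[pb[i]]]
    for (e in cand) {
      bc <- tet_barycentric(nodes[el[e, ], , drop = FALSE], pts[i, ])
      if (all(bc >= -tol)) { out[i] <- e; break }
    }
  }
  out
}

tet_barycentric <- function(verts, p) {
  Tm <- t(verts[2:4, , drop = FALSE]) - verts[1L, ]
  lam <- solve(Tm, p - verts[1L, ])
  c(1 - sum(lam), lam)
}
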