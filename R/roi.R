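#' Voxel grid covering a mesh
#'
#' Isotropic voxel grid whose bounding box covers the mesh (RAS axes,
#' centered on the origin). The affine maps 0-based voxel indices to mm
#' coordinates of voxel centers, NIfTI-style.
#'
#' @param mesh A `head_mesh`, or a numeric radius in mm.
#' @param spacing Voxel size in mm (default 1, i.e. 1 mm^3 voxels).
#' @param pad Extra margin in mm around the mesh.
#' @return Object of class `field_grid` with `dims`, `spacing`,
#'   `origin` (mm center of voxel (1,1,1)) and `affine` (4 x 4).
#' @export
field_grid <- function(mesh, spacing = 1, pad = 1) {
  R <- if (inherits(mesh, "head_mesh")) {
    max(abs(range(mesh$nodes)))
  } else if (inherits(mesh, "field_grid")) {
    return(mesh)
  } else {
    as.numeric(mesh)
  }
  half <- R + pad
  n <- as.integer(ceiling(2 * half / spacing))
  if (n %% 2L == 0L) n <- n + 1L # odd => a voxel center at the origin
  origin <- -((n - 1) / 2) * spacing
  affine <- diag(c(spacing, spacing, spacing, 1))
  affine[1:3, 4L] <- origin
  structure(list(dims = c(n, n, n), spacing = spacing,
                 origin = rep(origin, 3L), affine = affine),
            class = "field_grid")
}

# Voxel centers in mm, x fastest (R array order).
voxel_centers <- function(grid) {
  d <- grid$dims
  ax <- function(k) grid$origin[k] + (seq_len(d[k]) - 1L) * grid$spacing
  cbind(rep(ax(1L), times = d[2L] * d[3L]),
        rep(rep(ax(2L), each = d[1L]), times = d[3L]),
        rep(ax(3L), each = d[1L] * d[2L]))
}

#' Precompute the voxel-to-element map for a grid
#'
#' Point location of every voxel center in the mesh; reusable across
#' any number of solutions on the same mesh/grid pair (e.g. all
#' lead-field simulations).
#'
#' @param mesh A `head_mesh`.
#' @param grid A [field_grid()].
#' @param chunk Voxels per location chunk (memory control).
#' @return Integer vector (length `prod(dims)`) of element indices,
#'   `NA` outside the mesh.
#' @export
voxel_element_map <- function(mesh, grid, chunk = 2e6) {
  ctr <- voxel_centers(grid)
  nv <- nrow(ctr)
  out <- integer(nv)
  at <- 1L
  while (at <= nv) {
    hi <- min(at + as.integer(chunk) - 1L, nv)
    out[at:hi] <- locate_points(mesh, ctr[at:hi, , drop = FALSE])
    at <- hi + 1L
  }
  out
}

#' Rasterize an element-wise field to a voxel volume
#'
#' Each voxel takes the (constant) field of the element containing its
#' center; voxels whose centers lie in no element are masked invalid
#' (NA, distinguishable from a zero field).
#'
#' @param solution A `potential_solution`.
#' @param grid A [field_grid()]; default 1 mm voxels over the mesh.
#' @param elem_map Optional precomputed [voxel_element_map()].
#' @return Object of class `field_volume`: arrays `Ex`, `Ey`, `Ez`
#'   (V/m, NA outside), logical `mask`, and the grid geometry.
#' @export
rasterize_field <- function(solution, grid = NULL, elem_map = NULL) {
  stopifnot(inherits(solution, "potential_solution"))
  mesh <- solution$mesh
  if (is.null(grid)) grid <- field_grid(mesh)
  if (is.null(elem_map)) {
    # grid must overlap the mesh at all
    R <- max(abs(range(mesh$nodes)))
    lo <- grid$origin; hi <- grid$origin + (grid$dims - 1L) * grid$spacing
    if (any(lo > R) || any(hi < -R)) {
      stop("voxel grid does not overlap the mesh")
    }
    elem_map <- voxel_element_map(mesh, grid)
  }
  ok <- !is.na(elem_map)
  if (!any(ok)) stop("voxel grid does not overlap the mesh")
  take <- function(col) {
    v <- rep(NA_real_, length(elem_map))
    v[ok] <- solution$field[elem_map[ok], col]
    array(v, dim = grid$dims)
  }
  structure(list(Ex = take(1L), Ey = take(2L), Ez = take(3L),
                 mask = array(ok, dim = grid$dims),
                 dims = grid$dims, spacing = grid$spacing,
                 origin = grid$origin, affine = grid$affine),
            class = "field_volume")
}

#' @export
print.field_volume <- function(x, ...) {
  cat(sprintf("field_volume: %d x %d x %d voxels at %g mm, %d valid\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing, sum(x$mask)))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$affine), dim(b$affine)) &&
    all(a$dims == b$dims) && max(abs(a$affine - b$affine)) <= tol
}

#' Region-averaged fields over a parcellation
#'
#' Unweighted voxel means of Ex, Ey, Ez and of the field magnitude
#' Enorm (mean of per-voxel magnitudes, not the magnitude of the mean
#' vector) over each cerebellar lobule and the pooled non-cerebellar
#' brain.
#'
#' @param field A `field_volume`.
#' @param parc A `parcellation_volume` on the same grid.
#' @return Data frame with one row per region (lobules then brain
#'   mask): `region`, `n_voxels`, `Ex`, `Ey`, `Ez`, `Enorm` (V/m).
#' @export
lobule_means <- function(field, parc) {
  stopifnot(inherits(field, "field_volume"),
            inherits(parc, "parcellation_volume"))
  if (!same_grid(field, parc)) {
    stop("field and parcellation grids differ:\nfield affine:\n",
         paste(utils::capture.output(print(field$affine)), collapse = "\n"),
         "\nparcellation affine:\n",
         paste(utils::capture.output(print(parc$affine)), collapse = "\n"))
  }
  ids <- c(parc$lobule_ids, parc$brain_mask_id)
  lab <- as.integer(parc$labels)
  valid <- as.logical(field$mask) & lab > 0L
  lab <- lab[valid]
  ex <- as.numeric(field$Ex)[valid]
  ey <- as.numeric(field$Ey)[valid]
  ez <- as.numeric(field$Ez)[valid]
  en <- sqrt(ex^2 + ey^2 + ez^2)
  n_vox <- tabulate(lab, nbins = parc$brain_mask_id)[ids]
  if (any(n_vox == 0L)) {
    stop("region(s) with zero valid voxels: ",
         paste(parc$region_names[which(n_vox == 0L)], collapse = ", "))
  }
  sums <- function(v) rowsum(v, lab, reorder = TRUE)
  sm <- cbind(sums(ex), sums(ey), sums(ez), sums(en))
  # rowsum orders by sorted unique labels, which is ids here
  data.frame(region = parc$region_names,
             n_voxels = as.integer(n_vox),
             Ex = sm[, 1L] / n_vox, Ey = sm[, 2L] / n_vox,
             Ez = sm[, 3L] / n_vox, Enorm = sm[, 4L] / n_vox,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Electrode current density
#'
#' Current density at the electrode-skin interface, reported by
#' convention to two decimals (mA/cm^2).
#'
#' @param current_mA Electrode current in mA.
#' @param area_cm2 Electrode area in cm^2 (> 0).
#' @param digits Rounding (default 2, the conventional reporting
#'   precision); `NULL` for full precision.
#' @return Current density in mA/cm^2.
#' @export
current_density <- function(current_mA, area_cm2, digits = 2) {
  if (any(area_cm2 <= 0)) stop("electrode area must be > 0 cm^2")
  j <- current_mA / area_cm2
  if (!is.null(digits)) j <- round(j, digits)
  j
}
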