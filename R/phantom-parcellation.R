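#' Wedge-parcellated pseudo-cerebellum for the spherical phantom
#'
#' Labels a voxel grid covering the phantom with a synthetic cerebellar
#' parcellation: the posterior-inferior quadrant (y < 0, z < 0) of the
#' gray-matter shell is treated as the cerebellum and tiled into
#' wedge-shaped lobule analogues, split into left/right hemispheres
#' (and, for the standard 28-region layout, a midline vermis strip for
#' the lower lobules, mimicking the topology of cerebellar atlases:
#' 2 hemispheres x 10 lobules + 8 vermis regions). All remaining
#' gray/white-matter voxels form the non-cerebellar brain mask. The
#' construction is purely analytic, hence deterministic.
#'
#' @param mesh A `head_mesh` (supplies the gray-matter radii and grid
#'   extent) or a `field_grid`.
#' @param n_lobules Number of cerebellar regions (default 28).
#' @param spacing Voxel size in mm (isotropic; default 1).
#' @param r_range Radial band of the cerebellar shell, mm; defaults to
#'   the gray-matter shell of the mesh.
#' @param grid Optional pre-built [field_grid()] to label.
#' @return Object of class `parcellation_volume`: `labels` (3D integer
#'   array: 0 background, 1..n lobules, `brain_mask_id` non-cerebellar
#'   brain), `region_names`, `lobule_ids`, `brain_mask_id`, and the
#'   grid geometry (`dims`, `spacing`, `origin`, `affine`).
#' @export
build_parcellation <- function(mesh, n_lobules = 28, spacing = 1,
                               r_range = NULL, grid = NULL) {
  if (n_lobules < 2) stop("n_lobules must be >= 2")
  if (is.null(grid)) grid <- field_grid(mesh, spacing = spacing)
  if (is.null(r_range)) {
    sh <- mesh$shells
    gi <- match("gray_matter", sh$name)
    if (!is.na(gi) && gi < nrow(sh)) {
      r_range <- c(sh$outer_radius[gi + 1L], sh$outer_radius[gi])
    } else {
      R <- sh$outer_radius[1]
      r_range <- c(0.73, 0.86) * R
    }
  }
  brain_outer <- r_range[2]

  ctr <- voxel_centers(grid)
  r <- sqrt(rowSums(ctr^2))
  labels <- integer(nrow(ctr))

  in_brain <- r <= brain_outer
  in_band <- r >= r_range[1] & r <= brain_outer
  post_inf <- ctr[, 2L] < 0 & ctr[, 3L] < 0
  cb <- in_band & post_inf

  # wedge coordinate: angle swept from posterior-horizontal (alpha = 0)
  # to inferior-vertical (alpha = 90 deg) in the (y, z) plane
  alpha <- atan2(-ctr[cb, 3L], -ctr[cb, 2L])
  lat <- asin(pmin(pmax(ctr[cb, 1L] / r[cb], -1), 1)) # lateral angle

  if (n_lobules == 28) {
    band_names <- c("I_IV", "V", "VI", "Crus_I", "Crus_II",
                    "VIIb", "VIIIa", "VIIIb", "IX", "X")
    nb <- length(band_names)
    band <- pmin(pmax(ceiling(alpha / (pi / 2) * nb), 1L), nb)
    vermis_half_deg <- 7.5
    strip <- ifelse(lat < -vermis_half_deg * pi / 180, 1L,        # left
                    ifelse(lat > vermis_half_deg * pi / 180, 3L,  # right
                           2L))                                   # vermis
    # vermis exists for bands VI..X only; upper bands split by midline
    strip[strip == 2L & band <= 2L] <- ifelse(ctr[cb, 1L][strip == 2L & band <= 2L] >= 0, 3L, 1L)
    region_names <- c(paste0("Left_", band_names),
                      paste0("Right_", band_names),
                      paste0("Vermis_", band_names[3:10]))
    lab_cb <- integer(sum(cb))
    lab_cb[strip == 1L] <- band[strip == 1L]            # Left_*: 1..10
    lab_cb[strip == 3L] <- nb + band[strip == 3L]       # Right_*: 11..20
    lab_cb[strip == 2L] <- 20L + band[strip == 2L] - 2L # Vermis_*: 21..28
  } else {
    nb <- ceiling(n_lobules / 2)
    band <- pmin(pmax(ceiling(alpha / (pi / 2) * nb), 1L), nb)
    left <- ctr[cb, 1L] < 0
    lab_cb <- ifelse(left, band, nb + band)
    lab_cb[lab_cb > n_lobules] <- n_lobules # odd counts fold the last wedge
    region_names <- c(paste0("Left_W", seq_len(nb)),
                      paste0("Right_W", seq_len(n_lobules - nb)))
  }
  brain_mask_id <- n_lobules + 1L
  labels[in_brain] <- brain_mask_id
  labels[cb] <- lab_cb
  region_names <- c(region_names, "NonCerebellarBrain")

  present <- sort(unique(labels[labels > 0 & labels <= n_lobules]))
  if (length(present) != n_lobules) {
    stop("parcellation failed to populate every lobule: got ",
         length(present), " of ", n_lobules,
         " (grid too coarse for the wedge size?)")
  }
  structure(list(labels = array(as.integer(labels), dim = grid$dims),
                 region_names = region_names,
                 lobule_ids = seq_len(n_lobules),
                 brain_mask_id = brain_mask_id,
                 dims = grid$dims, spacing = grid$spacing,
                 origin = grid$origin, affine = grid$affine),
            class = "parcellation_volume")
}

#' @export
print.parcellation_volume <- function(x, ...) {
  nl <- length(x$lobule_ids)
  cat(sprintf(paste0("parcellation_volume: %d x %d x %d voxels at %g mm, ",
                     "%d lobules + brain mask\n"),
              x$dims[1], x$dims[2], x$dims[3], x$spacing, nl))
  invisible(x)
}

#' Voxel counts per region
#' @param parc A `parcellation_volume`.
#' @return Named integer vector over lobules and the brain mask.
#' @export
region_voxel_counts <- function(parc) {
  ids <- c(parc$lobule_ids, parc$brain_mask_id)
  cnt <- tabulate(parc$labels, nbins = parc$brain_mask_id)[ids]
  names(cnt) <- parc$region_names
  cnt
}
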