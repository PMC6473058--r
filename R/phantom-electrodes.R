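#' Construct an electrode table
#'
#' Electrodes are scalp patches described by their center (on the outer
#' surface), shape and area. Rectangular pads are realized on the
#' spherical scalp as geodesic discs of equal area, which preserves the
#' current density at the electrode-skin interface.
#'
#' @param id Electrode name(s).
#' @param center Matrix (k x 3) or length-3 vector of centers, mm.
#' @param shape `"disc"` or `"rect"`.
#' @param radius_cm Disc radius in cm (for `shape = "disc"`).
#' @param width_cm,height_cm Pad dimensions in cm (for `shape = "rect"`).
#' @param role `"stim"` or `"reference"`.
#' @return A data frame (electrode table) with columns `id`, `x`, `y`,
#'   `z`, `shape`, `area_cm2`, `radius_mm` (equal-area disc radius used
#'   for surface coupling) and `role`.
#' @export
electrode_spec <- function(id, center, shape = "disc", radius_cm = 0.5,
                           width_cm = NULL, height_cm = NULL,
                           role = "stim") {
  if (is.null(dim(center))) center <- matrix(center, ncol = 3L)
  k <- length(id)
  stopifnot(nrow(center) == k)
  shape <- rep_len(shape, k)
  role <- rep_len(role, k)
  area <- numeric(k)
  for (i in seq_len(k)) {
    if (shape[i] == "disc") {
      area[i] <- pi * rep_len(radius_cm, k)[i]^2
    } else if (shape[i] == "rect") {
      if (is.null(width_cm) || is.null(height_cm)) {
        stop("rect electrodes need width_cm and height_cm")
      }
      area[i] <- rep_len(width_cm, k)[i] * rep_len(height_cm, k)[i]
    } else {
      stop("unknown electrode shape: ", shape[i])
    }
  }
  if (any(area <= 0)) stop("electrode area must be > 0")
  data.frame(id = as.character(id),
             x = center[, 1L], y = center[, 2L], z = center[, 3L],
             shape = shape, area_cm2 = area,
             radius_mm = sqrt(area / pi) * 10,
             role = role, stringsAsFactors = FALSE)
}

# Scalp position from polar angle (degrees from the vertex) and azimuth
# (degrees from posterior midline, positive toward the right ear).
scalp_position <- function(R, theta_deg, az_deg) {
  th <- theta_deg * pi / 180
  az <- az_deg * pi / 180
  R * c(sin(th) * sin(az), -sin(th) * cos(az), cos(th))
}

#' Candidate scalp electrode layouts
#'
#' Generates a catalog of candidate stimulation electrodes on the scalp
#' sphere, including a reference electrode at the vertex, emulating the
#' whole-head EEG-derived catalogs used for montage optimization.
#'
#' @param mesh_or_radius A `head_mesh` or the scalp radius in mm.
#' @param n Total number of electrodes including the vertex reference
#'   (>= 2).
#' @param scheme `"quasi-uniform"` (deterministic Fibonacci lattice over
#'   a spherical cap) or `"ring"` (reference plus one ring at fixed
#'   polar angle).
#' @param reference_id Name for the vertex reference electrode.
#' @param diameter_cm Electrode disc diameter in cm (default 1 cm).
#' @param cap_deg Angular extent of the scalp cap covered by the layout,
#'   degrees from the vertex. The default (150) extends well below the
#'   inion line, as cerebellar montages and whole-head EEG-derived
#'   catalogs do; cerebellar targeting degrades without
#'   inferior-posterior coverage.
#' @param ring_theta_deg Polar angle of the ring for `scheme = "ring"`.
#' @return Electrode table as [electrode_spec()], reference first, with
#'   attribute `min_separation_deg` (minimum pairwise angular
#'   separation).
#' @export
candidate_layout <- function(mesh_or_radius, n, scheme = "quasi-uniform",
                             reference_id = "Cz", diameter_cm = 1,
                             cap_deg = 150, ring_theta_deg = 90) {
  R <- if (inherits(mesh_or_radius, "head_mesh")) {
    mesh_or_radius$shells$outer_radius[1]
  } else {
    as.numeric(mesh_or_radius)
  }
  stopifnot(n >= 2, diameter_cm > 0, cap_deg > 0, cap_deg <= 180)
  scheme <- match.arg(scheme, c("quasi-uniform", "ring"))
  if (scheme == "quasi-uniform") {
    # Fibonacci lattice over the cap; slot 1 pinned at the vertex
    i <- seq_len(n) - 1L
    zmin <- cos(cap_deg * pi / 180)
    z <- 1 - i / (n - 1 + 1e-12) * (1 - zmin)
    golden <- pi * (3 - sqrt(5))
    az <- i * golden
    dirs <- cbind(sqrt(pmax(0, 1 - z^2)) * cos(az),
                  sqrt(pmax(0, 1 - z^2)) * sin(az), z)
    dirs[1L, ] <- c(0, 0, 1)
  } else {
    th <- ring_theta_deg * pi / 180
    az <- seq(0, 2 * pi, length.out = n)[-1] # n - 1 ring positions
    dirs <- rbind(c(0, 0, 1),
                  cbind(sin(th) * sin(az), -sin(th) * cos(az),
                        rep(cos(th), n - 1L)))
  }
  centers <- dirs * R
  ids <- c(reference_id, sprintf("E%02d", seq_len(n - 1L)))
  tab <- electrode_spec(ids, centers, shape = "disc",
                        radius_cm = diameter_cm / 2,
                        role = c("reference", rep("stim", n - 1L)))
  # minimum pairwise angular separation
  cosang <- tcrossprod(dirs)
  diag(cosang) <- -1
  min_sep <- acos(pmin(pmax(max(cosang), -1), 1)) * 180 / pi
  # packability: centers closer than one electrode diameter overlap
  min_allowed <- (diameter_cm * 10 / R) * 180 / pi
  if (min_sep < min_allowed) {
    stop(sprintf(paste0("%d electrodes exceed the packable positions at ",
                        "%.2g cm diameter: minimum separation %.2f deg < ",
                        "%.2f deg"), n, diameter_cm, min_sep, min_allowed))
  }
  attr(tab, "min_separation_deg") <- min_sep
  tab
}
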