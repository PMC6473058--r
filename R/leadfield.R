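#' Assemble the lead-field (transfer) matrix
#'
#' Simulates one bipolar montage per candidate electrode (that
#' electrode at +1 mA against the common reference at -1 mA), extracts
#' the region-averaged fields, and collects them as the columns of one
#' matrix per field direction. Column m of `LF_d` is then the
#' volume-average field in direction d at each region per unit (1 mA)
#' current through electrode m, and region fields for an arbitrary
#' zero-sum current vector follow by superposition (`b = LF x`).
#'
#' The stiffness operator is factorized once and reused across all
#' solves, as is the voxel-to-element map of the extraction grid.
#'
#' @param mesh A `head_mesh`.
#' @param catalog Electrode table ([candidate_layout()]); the reference
#'   electrode is the row with `role == "reference"` unless
#'   `reference_id` is given.
#' @param parc A `parcellation_volume` defining the regions and grid.
#' @param tissues Optional conductivity vector per label.
#' @param reference_id Id of the common reference electrode.
#' @param elem_map Optional precomputed [voxel_element_map()].
#' @param verbose Print progress.
#' @return Object of class `lead_field`: `LF` (list of three
#'   regions x electrodes matrices `X`, `Y`, `Z`, units (V/m)/mA),
#'   `regions`, `electrodes` (catalog), `reference_id` and `provenance`
#'   (mesh/tissue hashes, grid spacing).
#' @export
assemble_leadfield <- function(mesh, catalog, parc, tissues = NULL,
                               reference_id = NULL, elem_map = NULL,
                               verbose = FALSE) {
  stopifnot(is.data.frame(catalog), nrow(catalog) >= 2L)
  if (is.null(reference_id)) {
    ri <- which(catalog$role == "reference")
    if (length(ri) != 1L) stop("catalog must have exactly one reference ",
                               "electrode (or pass reference_id)")
    reference_id <- catalog$id[ri]
  }
  if (!reference_id %in% catalog$id) {
    stop("reference electrode '", reference_id, "' not in catalog")
  }
  tissues <- check_tissues(mesh, tissues)
  grid <- structure(list(dims = parc$dims, spacing = parc$spacing,
                         origin = parc$origin, affine = parc$affine),
                    class = "field_grid")
  if (is.null(elem_map)) elem_map <- voxel_element_map(mesh, grid)
  op <- fem_operator(mesh, tissues)
  stim_ids <- catalog$id[catalog$id != reference_id]
  nreg <- length(parc$region_names)
  LF <- lapply(c(X = 1, Y = 2, Z = 3), function(d) {
    matrix(NA_real_, nreg, length(stim_ids),
           dimnames = list(parc$region_names, stim_ids))
  })
  iref <- match(reference_id, catalog$id)
  for (j in seq_along(stim_ids)) {
    ie <- match(stim_ids[j], catalog$id)
    mo <- montage(catalog[c(ie, iref), , drop = FALSE], c(1, -1),
                  name = paste0("bipolar_", stim_ids[j]))
    sol <- tryCatch(
      solve_potential(mont = mo, operator = op),
      error = function(e) stop("lead-field solve failed for electrode '",
                               stim_ids[j], "': ", conditionMessage(e)))
    fv <- rasterize_field(sol, grid, elem_map)
    tab <- lobule_means(fv, parc)
    LF$X[, j] <- tab$Ex; LF$Y[, j] <- tab$Ey; LF$Z[, j] <- tab$Ez
    if (verbose) message("lead field column ", j, "/", length(stim_ids),
                         " (", stim_ids[j], ")")
  }
  structure(list(LF = LF, regions = parc$region_names,
                 electrodes = catalog, reference_id = reference_id,
                 provenance = list(
                   mesh_hash = object_hash(mesh[c("nodes", "elements",
                                                  "element_label")]),
                   tissues = tissues,
                   grid_spacing = parc$spacing,
                   n_regions = nreg)),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf(paste0("lead_field: %d regions x %d electrodes ",
                     "(reference '%s'), directions X/Y/Z\n"),
              nrow(x$LF$X), ncol(x$LF$X), x$reference_id))
  invisible(x)
}

# md5 of a serialized object, used for provenance stamps.
object_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2L)
  unname(tools::md5sum(tf))
}

#' Predict region fields for an electrode current vector
#'
#' Superposition through the lead field: `b_d = LF_d x` for the
#' non-reference currents; the reference electrode carries the implied
#' return current and needs no column.
#'
#' @param lf A `lead_field`.
#' @param x Named numeric vector of currents in mA (names are electrode
#'   ids; may include the reference). Must sum to 0 within 1e-9 mA.
#' @return Matrix (regions x 3, columns X/Y/Z) of predicted fields in
#'   V/m.
#' @export
predict_fields <- function(lf, x) {
  stopifnot(inherits(lf, "lead_field"), !is.null(names(x)))
  unknown <- setdiff(names(x), lf$electrodes$id)
  if (length(unknown) > 0L) {
    stop("unknown electrode id(s): ", paste(unknown, collapse = ", "))
  }
  if (abs(sum(x)) > 1e-9) {
    stop("current vector must sum to 0 mA (got ", sum(x), ")")
  }
  stim_ids <- colnames(lf$LF$X)
  xs <- setNames(numeric(length(stim_ids)), stim_ids)
  common <- intersect(names(x), stim_ids)
  xs[common] <- x[common]
  out <- cbind(X = as.numeric(lf$LF$X %*% xs),
               Y = as.numeric(lf$LF$Y %*% xs),
               Z = as.numeric(lf$LF$Z %*% xs))
  rownames(out) <- lf$regions
  out
}
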