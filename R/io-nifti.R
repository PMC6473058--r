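grid_affine_nifti <- function(obj) {
  aff <- obj$affine
  structure(aff, code = 2L)
}

#' Write a parcellation as a NIfTI-1 label volume
#'
#' Integer labels are stored losslessly; the grid affine goes into the
#' sform/qform.
#'
#' @param parc A `parcellation_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_parcellation_nifti <- function(parc, path) {
  img <- RNifti::asNifti(parc$labels, datatype = "int16")
  # sform only: RNifti reconstructs the exact affine from it, while a
  # quaternion qform would round the voxel spacing
  RNifti::sform(img) <- grid_affine_nifti(parc)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 label volume as a parcellation
#'
#' @param path Input NIfTI.
#' @param n_lobules Number of lobule labels (ids 1..n; the next id is
#'   the non-cerebellar brain mask).
#' @param region_names Optional region names (length n_lobules + 1).
#' @return A `parcellation_volume`.
#' @export
read_parcellation_nifti <- function(path, n_lobules = 28,
                                    region_names = NULL) {
  img <- RNifti::readNifti(path)
  labels <- array(as.integer(img), dim = dim(img))
  aff <- unclass(RNifti::xform(img))
  spacing <- aff[1L, 1L]
  if (is.null(region_names)) {
    region_names <- c(paste0("Region_", seq_len(n_lobules)),
                      "NonCerebellarBrain")
  }
  stopifnot(length(region_names) == n_lobules + 1L)
  structure(list(labels = labels, region_names = region_names,
                 lobule_ids = seq_len(n_lobules),
                 brain_mask_id = n_lobules + 1L,
                 dims = dim(labels), spacing = spacing,
                 origin = aff[1:3, 4L], affine = aff),
            class = "parcellation_volume")
}

#' Write a field volume as 4D NIfTI (Ex, Ey, Ez)
#'
#' Fields are stored at 32-bit float precision (relative round-trip
#' error below 1e-6); masked voxels are stored as NaN, so a masked
#' voxel stays distinguishable from a zero field.
#'
#' @param field A `field_volume`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field_nifti <- function(field, path) {
  arr <- array(NA_real_, dim = c(field$dims, 3L))
  arr[, , , 1L] <- field$Ex; arr[, , , 2L] <- field$Ey
  arr[, , , 3L] <- field$Ez
  img <- RNifti::asNifti(arr, datatype = "float")
  RNifti::sform(img) <- grid_affine_nifti(field)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4D NIfTI field volume
#'
#' @param path Input NIfTI with three volumes (Ex, Ey, Ez).
#' @return A `field_volume`.
#' @export
read_field_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4L] != 3L) {
    stop("expected a 4D NIfTI with 3 volumes (Ex, Ey, Ez); got dims ",
         paste(d, collapse = " x "))
  }
  arr <- array(as.numeric(img), dim = d)
  aff <- unclass(RNifti::xform(img))
  ex <- arr[, , , 1L]
  structure(list(Ex = ex, Ey = arr[, , , 2L], Ez = arr[, , , 3L],
                 mask = !is.na(ex) & !is.nan(ex),
                 dims = d[1:3], spacing = aff[1L, 1L],
                 origin = aff[1:3, 4L], affine = aff),
            class = "field_volume")
}
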