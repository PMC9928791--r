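#' Construct a PET volume
#'
#' A `pet_volume` is a 3D array of standardized uptake values (SUV,
#' dimensionless, all >= 0) with physical voxel spacing in mm.
#'
#' @param suv 3D numeric array of SUV values.
#' @param voxel_spacing_mm Positive length-3 numeric, mm per voxel along each
#'   axis.
#' @return An object of class `pet_volume` with fields `suv` and
#'   `voxel_spacing_mm`.
#' @export
pet_volume <- function(suv, voxel_spacing_mm) {
  if (length(dim(suv)) != 3L) stop("suv must be a 3D array")
  if (any(suv < 0)) stop("SUV values must be >= 0")
  voxel_spacing_mm <- as.numeric(voxel_spacing_mm)
  if (length(voxel_spacing_mm) != 3L || any(voxel_spacing_mm <= 0))
    stop("voxel_spacing_mm must be three positive values")
  structure(list(suv = suv, voxel_spacing_mm = voxel_spacing_mm),
            class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat("PET volume:", paste(dim(x$suv), collapse = " x "), "voxels @",
      paste(x$voxel_spacing_mm, collapse = " x "), "mm\n")
  cat(sprintf("  SUV range [%.3g, %.3g]\n", min(x$suv), max(x$suv)))
  invisible(x)
}

# voxel volume in cc (1 cc = 1000 mm^3)
voxel_cc <- function(volume) prod(volume$voxel_spacing_mm) / 1000

#' Read / write SUV volumes as NIfTI
#'
#' Voxel spacing is carried in the NIfTI pixdim header field.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param volume A [pet_volume()] (or, for masks, an integer/logical array
#'   packaged the same way).
#' @return `read_pet_volume()` returns a `pet_volume`;
#'   `write_pet_volume()` returns `path` invisibly.
#' @export
read_pet_volume <- function(path) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  pet_volume(array(as.numeric(img), dim = dim(img)[1:3]), spacing)
}

#' @rdname read_pet_volume
#' @export
write_pet_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$suv)
  RNifti::pixdim(img) <- volume$voxel_spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
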