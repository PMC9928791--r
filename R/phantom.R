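#' Specification of a synthetic PET phantom
#'
#' Describes a digital phantom: a uniform background plus spherical lesions
#' (uniform plateau or isotropic Gaussian profile) with optional additive
#' Gaussian noise, clipped at zero.  Intended as ground truth for exercising
#' lesion segmentation; it does not model scanner physics.
#'
#' @param grid_shape Integer length-3, voxels per axis.
#' @param voxel_spacing_mm Positive length-3 numeric (mm).
#' @param background_suv Non-negative background SUV.
#' @param lesions List of lesions; each a list with `center` (1-based voxel
#'   coordinate, length 3), `radius_mm` (> 0), `peak_suv` (> background) and
#'   `profile` (`"uniform"` or `"gaussian"`; for the Gaussian profile the SD
#'   is `radius_mm / 2` and the lesion is truncated at `radius_mm`).
#' @param noise_sd Additive Gaussian noise SD in SUV units (>= 0).
#' @param seed Integer seed for the noise draw.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, voxel_spacing_mm, background_suv = 0,
                         lesions = list(), noise_sd = 0, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            length(voxel_spacing_mm) == 3L, all(voxel_spacing_mm > 0),
            background_suv >= 0, noise_sd >= 0)
  for (les in lesions) {
    if (length(les$center) != 3L ||
        any(les$center < 1L) || any(les$center > grid_shape))
      stop("lesion center must lie inside the grid")
    if (les$radius_mm <= 0) stop("lesion radius must be > 0")
    if (les$peak_suv <= background_suv)
      stop("lesion peak SUV must exceed the background SUV")
    if (!is.null(les$profile) && !les$profile %in% c("uniform", "gaussian"))
      stop("lesion profile must be 'uniform' or 'gaussian'")
  }
  structure(list(grid_shape = grid_shape,
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 background_suv = background_suv, lesions = lesions,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phantom PET volume with ground-truth lesion masks
#'
#' The volume is background plus per-lesion signal: a plateau at
#' `peak_suv` inside the radius for `"uniform"` lesions, or a truncated
#' Gaussian falloff (SD = radius/2) for `"gaussian"` lesions.  Ground-truth
#' masks contain the voxels whose centers lie within the lesion radius.
#' Noise, when requested, is additive Gaussian clipped at zero.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `volume` (a [pet_volume()]), `masks` (list of logical
#'   arrays, one per lesion), `truth_mtv_cc` (per-lesion mask volume in cc)
#'   and `overlaps` (data.frame of lesion index pairs whose spheres
#'   intersect; empty when lesions are disjoint).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_shape
  sp <- spec$voxel_spacing_mm
  suv <- array(spec$background_suv, dim = dims)
  # voxel-center physical coordinates along each axis
  ax <- lapply(1:3, function(k) (seq_len(dims[k]) - 1) * sp[k])
  masks <- vector("list", length(spec$lesions))
  for (i in seq_along(spec$lesions)) {
    les <- spec$lesions[[i]]
    profile <- if (is.null(les$profile)) "uniform" else les$profile
    cen <- (as.numeric(les$center) - 1) * sp
    d2 <- outer(outer((ax[[1]] - cen[1])^2, (ax[[2]] - cen[2])^2, `+`),
                (ax[[3]] - cen[3])^2, `+`)
    inside <- d2 <= les$radius_mm^2
    amp <- les$peak_suv - spec$background_suv
    if (profile == "uniform") {
      suv[inside] <- suv[inside] + amp
    } else {
      sd_mm <- les$radius_mm / 2
      suv[inside] <- suv[inside] + amp * exp(-d2[inside] / (2 * sd_mm^2))
    }
    masks[[i]] <- inside
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    suv <- suv + array(stats::rnorm(prod(dims), 0, spec$noise_sd), dim = dims)
    suv[suv < 0] <- 0
  }
  overlaps <- data.frame(lesion_a = integer(), lesion_b = integer())
  les <- spec$lesions
  if (length(les) > 1) {
    for (a in seq_len(length(les) - 1)) for (b in (a + 1):length(les)) {
      dist <- sqrt(sum(((as.numeric(les[[a]]$center) -
                           as.numeric(les[[b]]$center)) * sp)^2))
      if (dist < les[[a]]$radius_mm + les[[b]]$radius_mm)
        overlaps <- rbind(overlaps, data.frame(lesion_a = a, lesion_b = b))
    }
  }
  list(volume = pet_volume(suv, sp), masks = masks,
       truth_mtv_cc = vapply(masks, function(m) sum(m) * prod(sp) / 1000,
                             numeric(1)),
       overlaps = overlaps)
}
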